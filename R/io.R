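#' Read and write cine series and segmentations as NIfTI-1
#'
#' A [cine_series()] is stored as a 4D float32 NIfTI-1 file with the voxel
#' spacing in the header; a [seg_set()] as 4D uint8. Round trips preserve the
#' spacing exactly and the data to float32 precision.
#'
#' @param series A [cine_series()].
#' @param seg A [seg_set()].
#' @param path File path, conventionally ending in `.nii.gz`.
#' @param n_phases Optional expected phase count; reading errors if the file
#'   disagrees.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "cine_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$spacing, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# drop NIfTI header attributes, keeping a plain array
strip_nifti <- function(img) {
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' @rdname nifti_io
#' @export
read_series <- function(path, n_phases = NULL) {
  img <- RNifti::readNifti(path)
  arr <- strip_nifti(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D cine series in ", path, call. = FALSE)
  if (!is.null(n_phases) && dim(arr)[4] != n_phases)
    stop(sprintf("%s has %d phases but %d were expected",
                 path, dim(arr)[4], n_phases), call. = FALSE)
  cine_series(pmax(arr, 0), RNifti::pixdim(img)[1:3])
}

#' @rdname nifti_io
#' @export
write_seg <- function(seg, path) {
  stopifnot(inherits(seg, "seg_set"))
  img <- RNifti::asNifti(seg$labels)
  RNifti::pixdim(img) <- c(seg$spacing, 1)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_seg <- function(path, n_phases = NULL) {
  img <- RNifti::readNifti(path)
  arr <- strip_nifti(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D label map in ", path, call. = FALSE)
  if (!is.null(n_phases) && dim(arr)[4] != n_phases)
    stop(sprintf("%s has %d phases but %d were expected",
                 path, dim(arr)[4], n_phases), call. = FALSE)
  seg_set(arr, RNifti::pixdim(img)[1:3])
}

#' Check that a series and a segmentation share one grid
#'
#' @param series A [cine_series()].
#' @param seg A [seg_set()].
#' @return Invisibly `TRUE`; errors on shape or spacing mismatch.
#' @export
check_series_seg <- function(series, seg) {
  stopifnot(inherits(series, "cine_series"), inherits(seg, "seg_set"))
  if (!identical(dim(series$data), dim(seg$labels)))
    stop("series and segmentation shapes differ", call. = FALSE)
  if (max(abs(series$spacing - seg$spacing)) > 1e-6)
    stop("series and segmentation voxel spacings differ", call. = FALSE)
  invisible(TRUE)
}

#' Write phantom ground-truth scalars as a flat key-value text file
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param path Output text file.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  tf <- truth$true_function
  kv <- c(
    edv_ul = tf$edv_ul, esv_ul = tf$esv_ul, ef_pct = tf$ef_pct,
    lvm_mg = tf$lvm_mg, ed_phase = tf$ed_phase, es_phase = tf$es_phase,
    sigma = truth$sigma,
    r_ed_mm = truth$config$r_ed, r_es_mm = truth$config$r_es,
    myo_volume_mm3 = truth$config$myo_volume
  )
  writeLines(sprintf("%s\t%.10g", names(kv), as.numeric(kv)), path)
  invisible(path)
}
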