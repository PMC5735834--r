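#' Signal-to-noise ratio of a region of interest
#'
#' SNR is the mean signal intensity inside the ROI divided by the standard
#' deviation (denominator n - 1) of the signal in the background region —
#' deliberately the raw, uncorrected background SD, as is conventional when
#' the tissue SNR is high enough (> 4) for the Rician distribution to be
#' approximated by a Gaussian. The Rayleigh-corrected channel noise lives in
#' [estimate_sigma()] and is used only by the Rician bias correction.
#'
#' @param slice_image 2D numeric matrix (one slice of one phase).
#' @param roi_mask,background_mask Logical masks on the slice; nonempty and
#'   disjoint.
#' @return Dimensionless SNR.
#' @export
#' @examples
#' img <- matrix(c(rep(10, 4), c(1, 3, 1, 3)), 2, 4)
#' compute_snr(img, matrix(c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 4)), 2),
#'             matrix(c(rep(FALSE, 4), rep(TRUE, 4)), 2))
compute_snr <- function(slice_image, roi_mask, background_mask) {
  if (!is.matrix(slice_image)) stop("`slice_image` must be a matrix", call. = FALSE)
  if (!any(roi_mask) || !any(background_mask))
    stop("ROI and background masks must be nonempty", call. = FALSE)
  if (any(roi_mask & background_mask))
    stop("ROI and background masks must be disjoint", call. = FALSE)
  s <- stats::sd(slice_image[background_mask])
  if (!is.finite(s) || s == 0)
    stop("background SD is zero; SNR undefined on a uniform background",
         call. = FALSE)
  mean(slice_image[roi_mask]) / s
}

#' Contrast-to-noise ratio
#'
#' The difference between the SNR of the blood pool and the SNR of the
#' myocardium.
#'
#' @param snr_blood,snr_myo Finite SNR values.
#' @return Dimensionless CNR.
#' @export
#' @examples
#' compute_cnr(82, 39)   # 43
compute_cnr <- function(snr_blood, snr_myo) {
  if (!is.finite(snr_blood) || !is.finite(snr_myo))
    stop("SNR inputs must be finite", call. = FALSE)
  snr_blood - snr_myo
}

#' Regions of interest for image-quality metrics
#'
#' Bundles blood-pool, myocardial and background masks on one designated 2D
#' slice of one phase. Masks must be pairwise disjoint and nonempty.
#'
#' @param blood_mask,myo_mask,background_mask Logical 2D masks.
#' @param slice_index,phase_index 1-based indices of the slice and phase the
#'   masks refer to.
#' @return A `roi_set` list.
#' @export
roi_set <- function(blood_mask, myo_mask, background_mask,
                    slice_index, phase_index) {
  masks <- list(blood_mask, myo_mask, background_mask)
  if (!all(vapply(masks, is.matrix, logical(1))))
    stop("masks must be 2D logical matrices", call. = FALSE)
  if (!all(vapply(masks, any, logical(1))))
    stop("every mask must be nonempty", call. = FALSE)
  if (any(blood_mask & myo_mask) || any(blood_mask & background_mask) ||
      any(myo_mask & background_mask))
    stop("masks must be pairwise disjoint", call. = FALSE)
  structure(list(blood_mask = blood_mask, myo_mask = myo_mask,
                 background_mask = background_mask,
                 slice_index = as.integer(slice_index),
                 phase_index = as.integer(phase_index)),
            class = "roi_set")
}

#' Default ROIs from the phantom ground truth
#'
#' Builds the study's region-of-interest set once per phantom so the *same*
#' ROIs are reused across all filtering conditions: a disc well inside the
#' blood pool (eroded cavity), the myocardial wall, and a square background
#' region in the bottom-right corner, all on the mid-ventricular slice at
#' end-diastole.
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param bg_size Side of the square background region, voxels.
#' @return A [roi_set()].
#' @export
rois_from_truth <- function(truth, bg_size = 24L) {
  stopifnot(inherits(truth, "phantom_truth"))
  cfg <- truth$config
  ed <- truth$true_function$ed_phase
  mid <- as.integer(round((cfg$base_slice + cfg$apex_slice) / 2))
  lab <- truth$truth_seg$labels[, , mid, ed]
  cav <- lab == 1L
  # erode the cavity by ~2 voxels so the blood ROI stays clear of the wall
  blood <- as.matrix(EBImage::distmap(matrix(as.numeric(cav), nrow(cav)))) > 2
  if (!any(blood)) blood <- cav
  myo <- lab == 2L
  bg <- matrix(FALSE, cfg$nx, cfg$ny)
  bg[(cfg$nx - bg_size + 1L):cfg$nx, (cfg$ny - bg_size + 1L):cfg$ny] <- TRUE
  if (any(bg & (lab > 0L)))
    stop("background ROI intersects the ventricle; reduce bg_size", call. = FALSE)
  roi_set(blood, myo, bg, slice_index = mid, phase_index = ed)
}

#' Image-quality report for one series and one ROI set
#'
#' Computes blood and myocardial SNR and the CNR on the designated slice and
#' phase, and flags whether the Gaussian approximation of the Rician noise is
#' valid there (minimum SNR above 4).
#'
#' @param series A [cine_series()].
#' @param rois A [roi_set()].
#' @return A `quality_metrics` one-row [tibble::tibble()] with `snr_blood`,
#'   `snr_myo`, `cnr`, `gaussian_approx_valid`.
#' @export
quality_report <- function(series, rois) {
  stopifnot(inherits(series, "cine_series"), inherits(rois, "roi_set"))
  d <- dim(series$data)
  if (rois$slice_index < 1L || rois$slice_index > d[3] ||
      rois$phase_index < 1L || rois$phase_index > d[4])
    stop("ROI slice/phase indices out of range for this series", call. = FALSE)
  img <- series$data[, , rois$slice_index, rois$phase_index]
  snr_b <- compute_snr(img, rois$blood_mask, rois$background_mask)
  snr_m <- compute_snr(img, rois$myo_mask, rois$background_mask)
  out <- tibble::tibble(
    snr_blood = snr_b, snr_myo = snr_m,
    cnr = compute_cnr(snr_b, snr_m),
    gaussian_approx_valid = min(snr_b, snr_m) > 4
  )
  class(out) <- c("quality_metrics", class(out))
  out
}
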