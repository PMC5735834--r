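#' 4D cine magnitude series
#'
#' A `cine_series` holds a 4D non-negative magnitude image indexed
#' `(x, y, slice, phase)` together with its voxel spacing in mm. This is the
#' object every denoiser consumes one cardiac phase at a time.
#'
#' @param data 4D numeric array `(x, y, slice, phase)`, all values >= 0.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm, all > 0.
#'
#' @return An object of class `cine_series`: a list with elements `data`,
#'   `spacing` and `n_phases`.
#' @export
#' @examples
#' s <- cine_series(array(1, c(8, 8, 3, 2)), spacing = c(0.2, 0.2, 1))
#' dim(s$data)
cine_series <- function(data, spacing) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, slice, phase)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("`data` must be finite", call. = FALSE)
  if (any(data < 0))
    stop("magnitude data must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (dx, dy, dz) in mm",
         call. = FALSE)
  structure(
    list(data = data, spacing = spacing, n_phases = dim(data)[4L]),
    class = "cine_series"
  )
}

#' Per-phase label volumes (background / cavity / myocardium)
#'
#' A `seg_set` stores integer label maps on the same grid as a
#' [cine_series()], one 3D volume per cardiac phase, with codes
#' 0 = background, 1 = left-ventricular cavity, 2 = myocardium.
#'
#' @param labels 4D integer array with values in \{0, 1, 2\}.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm.
#'
#' @return An object of class `seg_set`.
#' @export
seg_set <- function(labels, spacing) {
  labels <- unclass(labels)
  if (!is.array(labels) || length(dim(labels)) != 4L)
    stop("`labels` must be a 4D array (x, y, slice, phase)", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(0L, 1L, 2L)))
    stop("labels must be in {0 (background), 1 (cavity), 2 (myocardium)}",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive numbers", call. = FALSE)
  structure(list(labels = labels, spacing = spacing), class = "seg_set")
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<cine_series> %d x %d x %d voxels, %d phases; spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], d[4], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.seg_set <- function(x, ...) {
  d <- dim(x$labels)
  n <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("<seg_set> %d x %d x %d voxels, %d phases\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  background %d | cavity %d | myocardium %d voxels\n",
              n[1], n[2], n[3]))
  invisible(x)
}

#' Extract one 3D phase volume from a cine series
#'
#' @param series A [cine_series()].
#' @param phase Phase index (1-based).
#' @return 3D numeric array.
#' @export
phase_volume <- function(series, phase) {
  stopifnot(inherits(series, "cine_series"))
  if (phase < 1L || phase > series$n_phases)
    stop("phase index out of range", call. = FALSE)
  series$data[, , , phase, drop = FALSE][, , , 1L]
}

# voxel volume in mm^3 (= uL)
voxel_volume <- function(spacing) prod(spacing)

# deterministic sub-seed derivation: mixes a master seed with stage indices,
# staying below 2^31 (exact in double arithmetic)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629
  s <- (abs(seed) %% m)
  for (k in seq_along(idx)) {
    s <- (s * 48271 + (abs(idx[k]) %% m) * 16807 + 101 * k) %% m
  }
  as.integer(s + 1)
}
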