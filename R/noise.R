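#' Add Rician noise to a magnitude image
#'
#' Replaces every voxel value S by `sqrt((S + n1)^2 + n2^2)` where `n1`, `n2`
#' are independent zero-mean Gaussian draws of standard deviation `sigma` —
#' the noise model of single-coil magnitude MRI. Background (S = 0) becomes
#' Rayleigh-distributed; everywhere `E[M^2] = S^2 + 2 sigma^2`. Noise is drawn
#' per cardiac phase from sub-seeds derived from `seed`, so per-phase
#' processing is reproducible independently of the other phases.
#'
#' @param x A [cine_series()] or a numeric array.
#' @param sigma Gaussian channel noise SD, intensity units (>= 0).
#' @param seed Integer seed; output is bit-reproducible given it.
#' @return Same type as `x`, everywhere >= 0.
#' @export
add_rician_noise <- function(x, sigma, seed = 1L) {
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be a non-negative number", call. = FALSE)
  if (inherits(x, "cine_series")) {
    if (sigma == 0) return(x)
    data <- x$data
    for (p in seq_len(x$n_phases)) {
      data[, , , p] <- rician_draw(data[, , , p], sigma,
                                   derive_seed(seed, 7L, p))
    }
    return(cine_series(data, x$spacing))
  }
  if (sigma == 0) return(x)
  rician_draw(x, sigma, derive_seed(seed, 7L, 1L))
}

rician_draw <- function(arr, sigma, seed) {
  d <- dim(arr)
  withr::with_seed(seed, {
    n1 <- stats::rnorm(length(arr), 0, sigma)
    n2 <- stats::rnorm(length(arr), 0, sigma)
    out <- sqrt((arr + n1)^2 + n2^2)
  })
  dim(out) <- d
  out
}

#' Estimate the noise level from a background region
#'
#' Estimates the Gaussian channel noise SD `sigma` from voxels assumed
#' signal-free. In magnitude images the background is Rayleigh-distributed
#' with SD `sigma * sqrt(2 - pi/2)`, so the default method divides the sample
#' SD by that factor to recover the channel `sigma` (the quantity the
#' Rician-bias correction of [ornlm()] needs). The `background_sd_raw` method
#' returns the uncorrected background SD — the denominator of the SNR
#' definition used by [compute_snr()].
#'
#' @param x Numeric array (or [cine_series()]; then the mask must match its
#'   full 4D grid).
#' @param background_mask Logical mask selecting signal-free voxels; at least
#'   100 voxels are expected (fewer than 2 is an error).
#' @param method `"background_sd_rayleigh"` (default) or `"background_sd_raw"`.
#' @return A `noise_estimate` list with `sigma`, `method`, `n_voxels`.
#' @export
estimate_sigma <- function(x, background_mask,
                           method = c("background_sd_rayleigh",
                                      "background_sd_raw")) {
  method <- match.arg(method)
  vals <- if (inherits(x, "cine_series")) x$data[background_mask]
          else x[background_mask]
  n <- length(vals)
  if (n < 2L) stop("background mask selects fewer than 2 voxels", call. = FALSE)
  s <- stats::sd(vals)
  m <- mean(vals)
  # Rayleigh background has mean/sd = sqrt(pi/2)/sqrt(2 - pi/2) ~ 1.91; a
  # ratio far outside that suggests the mask is not signal-free
  if (s > 0 && (m / s < 1.2 || m / s > 4.0))
    warning(sprintf(
      "background mean/sd ratio %.2f inconsistent with Rayleigh statistics (expected ~1.91); mask may contain signal",
      m / s), call. = FALSE)
  sigma <- if (method == "background_sd_rayleigh") s / sqrt(2 - pi / 2) else s
  structure(list(sigma = sigma, method = method, n_voxels = n),
            class = "noise_estimate")
}

#' Default background region of interest
#'
#' Rectangular mask in the bottom-right in-plane corner of the image (the
#' region outside the animal in the study layout), replicated across all
#' slices (and phases for 4D input).
#'
#' @param x Numeric array (2D, 3D or 4D) or [cine_series()]; the in-plane
#'   dimensions must each be at least 32 voxels.
#' @param size Side of the square corner region, voxels (default 24, i.e.
#'   576 voxels per slice).
#' @return Logical mask with the same dimensions as `x`.
#' @export
default_background_roi <- function(x, size = 24L) {
  dims <- if (inherits(x, "cine_series")) dim(x$data) else dim(x)
  if (is.null(dims)) stop("`x` must be an array", call. = FALSE)
  if (dims[1] < 32L || dims[2] < 32L)
    stop("in-plane dimensions must be at least 32 voxels", call. = FALSE)
  size <- as.integer(size)
  if (size < 2L || size > min(dims[1], dims[2]))
    stop("invalid background ROI size", call. = FALSE)
  mask <- array(FALSE, dims)
  rows <- (dims[1] - size + 1L):dims[1]
  cols <- (dims[2] - size + 1L):dims[2]
  if (length(dims) == 2L) mask[rows, cols] <- TRUE
  else if (length(dims) == 3L) mask[rows, cols, ] <- TRUE
  else if (length(dims) == 4L) mask[rows, cols, , ] <- TRUE
  else stop("`x` must be 2D, 3D or 4D", call. = FALSE)
  mask
}
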