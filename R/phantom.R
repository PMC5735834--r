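#' Configuration of the synthetic left-ventricle cine phantom
#'
#' Geometry and contrast of a short-axis cine acquisition of a rat-sized left
#' ventricle. Defaults reproduce the acquisition grid this package is designed
#' around: a 256 x 256 in-plane matrix at 0.195 mm resolution, 15 slices of
#' 1 mm, and 16 cardiac phases, with bright blood over grey myocardium as in a
#' FLASH cine. The default cavity radii and myocardial volume give mid-range
#' rat-heart function values (EDV about 550 uL, EF about 73%, LVM about
#' 735 mg).
#'
#' @param nx,ny In-plane matrix size in voxels.
#' @param n_slices Number of short-axis slices.
#' @param n_phases Number of cardiac phases.
#' @param dx,dy In-plane voxel size, mm.
#' @param dz Slice thickness, mm.
#' @param r_ed Cavity radius at end-diastole, mm.
#' @param r_es Cavity radius at end-systole, mm (must satisfy `r_ed > r_es`).
#' @param myo_volume Myocardial volume held constant across phases, mm^3
#'   (the wall thickens as the cavity contracts).
#' @param i_blood,i_myo Signal intensities of blood and myocardium, arbitrary
#'   units with `i_blood > i_myo > 0`; background is 0.
#' @param base_slice,apex_slice First and last slice (1-based, inclusive)
#'   containing the ventricle.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(nx = 256L, ny = 256L, n_slices = 15L, n_phases = 16L,
                           dx = 0.195, dy = 0.195, dz = 1.0,
                           r_ed = 4.2, r_es = 2.2, myo_volume = 700,
                           i_blood = 2.0, i_myo = 1.0,
                           base_slice = 3L, apex_slice = 12L) {
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny),
              n_slices = as.integer(n_slices), n_phases = as.integer(n_phases),
              dx = dx, dy = dy, dz = dz,
              r_ed = r_ed, r_es = r_es, myo_volume = myo_volume,
              i_blood = i_blood, i_myo = i_myo,
              base_slice = as.integer(base_slice),
              apex_slice = as.integer(apex_slice))
  with(cfg, {
    if (!(r_ed > r_es && r_es > 0))
      stop("need r_ed > r_es > 0", call. = FALSE)
    if (!(i_blood > i_myo && i_myo > 0))
      stop("need i_blood > i_myo > 0", call. = FALSE)
    if (!(base_slice >= 1L && base_slice <= apex_slice &&
          apex_slice <= n_slices))
      stop("need 1 <= base_slice <= apex_slice <= n_slices", call. = FALSE)
    if (any(c(dx, dy, dz) <= 0)) stop("spacings must be > 0", call. = FALSE)
    if (n_phases < 2L) stop("need at least 2 phases", call. = FALSE)
    if (myo_volume <= 0) stop("myo_volume must be > 0", call. = FALSE)
  })
  structure(cfg, class = "phantom_config")
}

# cavity radius at phase p (1-based): raised cosine, end-diastole at phase 1,
# end-systole half a cycle later
cavity_radius <- function(cfg, p) {
  t <- (p - 1) / cfg$n_phases
  cfg$r_es + (cfg$r_ed - cfg$r_es) * (1 + cos(2 * pi * t)) / 2
}

#' Generate a noise-free synthetic cine series with known ground truth
#'
#' The ventricle is modeled as a stack of circular discs on the interior
#' slices: a blood-filled cavity of phase-dependent radius surrounded by an
#' annular myocardium whose total volume is held constant across the cycle
#' (the wall thickens during systole). The cavity radius follows a raised
#' cosine over the cycle, so end-diastole is phase 1 and end-systole falls
#' half a cycle later. Intensities are `i_blood` in the cavity, `i_myo` in the
#' wall and 0 elsewhere. Generation is fully deterministic.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `series` (a [cine_series()]) and `truth` (a
#'   `phantom_truth`: the ground-truth [seg_set()], the true
#'   [compute_function()] values, the injected noise level `sigma` — `NA`
#'   until noise is added — and the config).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(nx = 64, ny = 64, dx = 0.78,
#'   dy = 0.78, n_slices = 6, n_phases = 4, base_slice = 2, apex_slice = 5))
#' ph$truth$true_function
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  n_vent <- cfg$apex_slice - cfg$base_slice + 1L
  myo_area <- cfg$myo_volume / (cfg$dz * n_vent)  # mm^2 per slice

  half_x <- cfg$nx * cfg$dx / 2
  half_y <- cfg$ny * cfg$dy / 2
  # ventricle axis through the center voxel's center: this alignment keeps
  # the voxel-counted disc areas closest to the analytic values
  xs <- (seq_len(cfg$nx) - cfg$nx / 2) * cfg$dx
  ys <- (seq_len(cfg$ny) - cfg$ny / 2) * cfg$dy
  dist2 <- outer(xs^2, ys^2, `+`)

  data <- array(0, dim = c(cfg$nx, cfg$ny, cfg$n_slices, cfg$n_phases))
  labels <- array(0L, dim = dim(data))
  for (p in seq_len(cfg$n_phases)) {
    r <- cavity_radius(cfg, p)
    r_epi <- sqrt(r^2 + myo_area / pi)
    if (r_epi >= min(half_x, half_y) - max(cfg$dx, cfg$dy))
      stop(sprintf(
        "phase %d: epicardial radius %.2f mm exceeds the grid half-extent %.2f mm",
        p, r_epi, min(half_x, half_y)), call. = FALSE)
    cav2d <- dist2 <= r^2
    myo2d <- dist2 <= r_epi^2 & !cav2d
    lab2d <- matrix(0L, cfg$nx, cfg$ny)
    lab2d[cav2d] <- 1L
    lab2d[myo2d] <- 2L
    img2d <- matrix(0, cfg$nx, cfg$ny)
    img2d[cav2d] <- cfg$i_blood
    img2d[myo2d] <- cfg$i_myo
    for (z in cfg$base_slice:cfg$apex_slice) {
      data[, , z, p] <- img2d
      labels[, , z, p] <- lab2d
    }
  }
  spacing <- c(cfg$dx, cfg$dy, cfg$dz)
  series <- cine_series(data, spacing)
  truth_seg <- seg_set(labels, spacing)
  truth <- structure(
    list(truth_seg = truth_seg,
         true_function = compute_function(truth_seg),
         sigma = NA_real_,
         config = cfg),
    class = "phantom_truth")
  list(series = series, truth = truth)
}

#' Simulated human observer
#'
#' Parameters of an imperfect manual segmentation: boundary contours are
#' displaced radially by a systematic `dilation_bias` (positive = outward)
#' plus smooth zero-mean angular noise with pointwise standard deviation
#' `jitter_scale`, both in voxel units.
#'
#' @param jitter_scale SD of the random radial boundary displacement, voxels.
#' @param dilation_bias Systematic outward boundary shift, voxels (signed).
#' @param seed Integer seed; the observer is bit-reproducible given it.
#' @return An `observer_model` list.
#' @export
observer_model <- function(jitter_scale, dilation_bias = 0, seed = 1L) {
  if (jitter_scale < 0) stop("jitter_scale must be >= 0", call. = FALSE)
  structure(list(jitter_scale = jitter_scale,
                 dilation_bias = dilation_bias,
                 seed = as.integer(seed)),
            class = "observer_model")
}

# smooth periodic radial displacement field over polar angle theta:
# bias + 4 random Fourier harmonics with total pointwise variance jitter^2
radial_displacement <- function(theta, jitter, bias, n_harm = 4L) {
  delta <- rep(bias, length(theta))
  coef_sd <- jitter / sqrt(n_harm)
  for (k in seq_len(n_harm)) {
    a <- stats::rnorm(1, 0, coef_sd)
    b <- stats::rnorm(1, 0, coef_sd)
    delta <- delta + a * cos(k * theta) + b * sin(k * theta)
  }
  delta
}

# signed Euclidean distance to the boundary of a binary 2D mask:
# negative inside, positive outside (pixel units)
signed_distance <- function(mask) {
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  d_in <- EBImage::distmap(m)         # distance of foreground to background
  d_out <- EBImage::distmap(1 - m)    # distance of background to foreground
  as.matrix(d_out) - as.matrix(d_in)
}

#' Simulate an imperfect manual segmentation
#'
#' Displaces each slice's endocardial and epicardial contours radially by the
#' observer's systematic bias plus smooth random jitter (independent
#' smooth angular fields per contour and slice), then re-rasterizes to label
#' maps. Implemented as a level-set perturbation of the signed distance to
#' each contour, so displaced contours can never self-intersect; if a
#' perturbation would make the cavity vanish entirely on a slice where the
#' truth has one, the displacement is clamped back to the true contour and a
#' warning is issued. Deterministic given `model$seed`.
#'
#' @param truth A ground-truth [seg_set()].
#' @param model An [observer_model()].
#' @return A [seg_set()] with the same grid and label codes.
#' @export
simulate_observer <- function(truth, model) {
  stopifnot(inherits(truth, "seg_set"), inherits(model, "observer_model"))
  dims <- dim(truth$labels)
  out <- array(0L, dims)
  n_clamped <- 0L
  withr::with_seed(model$seed, {
    for (p in seq_len(dims[4])) {
      for (z in seq_len(dims[3])) {
        lab <- truth$labels[, , z, p]
        epi <- lab >= 1L
        if (!any(epi)) next
        cav <- lab == 1L
        idx <- which(epi, arr.ind = TRUE)
        cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
        theta <- atan2(
          matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1]) - cy,
          matrix(rep(seq_len(dims[1]), dims[2]), dims[1]) - cx)
        d_endo <- radial_displacement(theta, model$jitter_scale,
                                      model$dilation_bias)
        d_epi <- radial_displacement(theta, model$jitter_scale,
                                     model$dilation_bias)
        new_epi <- signed_distance(epi) <= d_epi
        if (!any(new_epi)) { new_epi <- epi; n_clamped <- n_clamped + 1L }
        if (any(cav)) {
          new_cav <- (signed_distance(cav) <= d_endo) & new_epi
          if (!any(new_cav)) {
            new_cav <- cav & new_epi
            if (!any(new_cav)) { new_cav <- cav; new_epi <- new_epi | cav }
            n_clamped <- n_clamped + 1L
          }
        } else {
          new_cav <- matrix(FALSE, dims[1], dims[2])
        }
        sl <- matrix(0L, dims[1], dims[2])
        sl[new_epi] <- 2L
        sl[new_cav] <- 1L
        out[, , z, p] <- sl
      }
    }
  })
  if (n_clamped > 0L)
    warning(sprintf("observer displacement clamped on %d slice(s)", n_clamped),
            call. = FALSE)
  seg_set(out, truth$spacing)
}

#' Contrast-linked observer jitter
#'
#' Maps the contrast-to-noise ratio of a (possibly filtered) image to the
#' boundary jitter of a simulated observer: `jitter = c / cnr`, so
#' higher-contrast images yield tighter, more reproducible contours.
#'
#' @param cnr Contrast-to-noise ratio (must be > 0).
#' @param c Proportionality constant, voxel units of jitter at CNR = 1.
#' @return Jitter scale in voxels.
#' @export
#' @examples
#' cnr_linked_jitter(6, c = 6)   # 1 voxel at the raw-image contrast level
cnr_linked_jitter <- function(cnr, c = 6) {
  if (!is.finite(cnr) || cnr <= 0) stop("cnr must be > 0", call. = FALSE)
  if (c <= 0) stop("c must be > 0", call. = FALSE)
  c / cnr
}
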