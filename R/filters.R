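#' Perona-Malik anisotropic diffusion of a 3D volume
#'
#' Explicit flux-form integration of the anisotropic diffusion heat equation
#' with the exponential conduction function `c(g) = exp(-(g/kappa)^2)`:
#' smoothing proceeds along structures and is shut down across strong
#' gradients. Fluxes are computed once per face and differenced, with
#' zero-flux (Neumann) boundaries, so the discrete intensity sum is conserved
#' exactly up to rounding.
#'
#' @param volume 3D numeric array, finite values.
#' @param kappa Conduction threshold in intensity-gradient units (> 0);
#'   gradients well below `kappa` diffuse freely, gradients above it are
#'   preserved.
#' @param n_iter Number of explicit time steps (default 10).
#' @param dt Time step (default 1/14). Must satisfy `dt <= 1/(2 * 3)` in
#'   voxel units (or the spacing-aware analogue) for stability.
#' @param spacing Voxel spacing, mm; only used when `spacing_aware = TRUE`.
#' @param spacing_aware If `TRUE`, gradients are taken per mm instead of per
#'   voxel. Default `FALSE`: plain voxel-unit diffusion.
#' @return Filtered 3D array, same shape.
#' @export
anisotropic_diffusion <- function(volume, kappa, n_iter = 10L, dt = 1 / 14,
                                  spacing = c(1, 1, 1), spacing_aware = FALSE) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("`volume` must be a 3D array", call. = FALSE)
  if (any(!is.finite(volume))) stop("`volume` must be finite", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  inv_h2 <- if (spacing_aware) 1 / spacing^2 else c(1, 1, 1)
  bound <- 1 / (2 * sum(inv_h2))
  if (dt <= 0 || dt > bound)
    stop(sprintf("dt = %g violates the stability bound dt <= %g", dt, bound),
         call. = FALSE)
  u <- volume
  d <- dim(u)
  for (it in seq_len(n_iter)) {
    upd <- array(0, d)
    for (ax in 1:3) {
      g <- array_diff(u, ax)                      # face differences
      if (spacing_aware) g <- g / spacing[ax]
      flux <- exp(-(g / kappa)^2) * g * inv_h2[ax]
      upd <- upd + flux_divergence(flux, ax, d)
    }
    u <- u + dt * upd
  }
  u
}

# forward difference along axis `ax`: x[i+1] - x[i], length n-1 slabs
array_diff <- function(x, ax) {
  d <- dim(x)
  n <- d[ax]
  i_hi <- lapply(seq_along(d), function(k) if (k == ax) 2:n else seq_len(d[k]))
  i_lo <- lapply(seq_along(d), function(k) if (k == ax) 1:(n - 1) else seq_len(d[k]))
  do.call(`[`, c(list(x), i_hi, list(drop = FALSE))) -
    do.call(`[`, c(list(x), i_lo, list(drop = FALSE)))
}

# divergence contribution of face fluxes along axis `ax`, zero flux at the
# two boundary faces: out[i] = flux[i] - flux[i-1]
flux_divergence <- function(flux, ax, d) {
  out <- array(0, d)
  n <- d[ax]
  idx <- function(rng) lapply(seq_along(d), function(k)
    if (k == ax) rng else seq_len(d[k]))
  lo <- idx(1:(n - 1)); hi <- idx(2:n)
  out_lo <- do.call(`[`, c(list(out), lo, list(drop = FALSE))) + flux
  out <- do.call(`[<-`, c(list(out), lo, list(value = out_lo)))
  out_hi <- do.call(`[`, c(list(out), hi, list(drop = FALSE))) - flux
  do.call(`[<-`, c(list(out), hi, list(value = out_hi)))
}

#' Total-variation (ROF) denoising of a 3D volume
#'
#' Approximately minimizes `TV(u) + 1/(2 * weight) * ||u - f||^2` (isotropic
#' total variation, forward differences) by Chambolle's dual projection
#' algorithm with fixed dual step `1/(2 * ndim)`. Larger `weight` smooths
#' more; `weight = 0` returns the input unchanged.
#'
#' @param volume 3D numeric array, finite values.
#' @param weight Denoising strength (>= 0), intensity units.
#' @param max_iter Maximum dual iterations (default 200).
#' @param tol Stop when the relative L2 change of the primal iterate falls
#'   below this (default 1e-4).
#' @return Filtered 3D array, same shape.
#' @export
total_variation <- function(volume, weight, max_iter = 200L, tol = 1e-4) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("`volume` must be a 3D array", call. = FALSE)
  if (any(!is.finite(volume))) stop("`volume` must be finite", call. = FALSE)
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (weight == 0) return(volume)
  .tv_core(as.double(volume), as.integer(dim(volume)), weight,
           as.integer(max_iter), tol)
}

# forward-difference gradient, zero in the last slab of each axis
gradient_fwd <- function(x) {
  d <- dim(x)
  lapply(1:3, function(ax) {
    g <- array(0, d)
    n <- d[ax]
    lo <- lapply(seq_along(d), function(k) if (k == ax) 1:(n - 1) else seq_len(d[k]))
    do.call(`[<-`, c(list(g), lo, list(value = array_diff(x, ax))))
  })
}

#' Discrete isotropic total variation of a volume
#'
#' Sum over voxels of the Euclidean norm of the forward-difference gradient —
#' the regularizer minimized by [total_variation()].
#'
#' @param volume 3D numeric array.
#' @return Scalar TV value.
#' @export
tv_norm <- function(volume) {
  g <- gradient_fwd(volume)
  sum(sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2))
}

#' ORNLM parameter set
#'
#' Resolves the parameters of the optimized Rician non-local means filter and
#' reports the derived window sizes: with the defaults, the search volume
#' spans `(2*5+1)^3 = 1331` voxels and a patch has `(2*1+1)^3 - 1 = 26`
#' neighbors around its central voxel.
#'
#' @param search_radius Search window radius, voxels (default 5).
#' @param patch_radius Patch radius, voxels (default 1).
#' @param h Smoothing parameter in intensity units; default `1.0 * sigma`
#'   once `sigma` is resolved (patch distances are weighted means of squared
#'   intensity differences, whose noise scale is set by `sigma`).
#' @param sigma Gaussian channel noise SD, or `"auto"` to estimate it from a
#'   background region at filter time.
#' @param patch_sigma SD of the Gaussian patch-distance weighting, voxels
#'   (default 1).
#' @return An `ornlm_params` list with fields `search_radius`, `patch_radius`,
#'   `h`, `sigma`, `patch_sigma`, `n_search` (total search-window voxels) and
#'   `n_patch_neighbors` (patch voxels excluding the center).
#' @export
#' @examples
#' ornlm_params()$n_search            # 1331
#' ornlm_params()$n_patch_neighbors   # 26
ornlm_params <- function(search_radius = 5L, patch_radius = 1L,
                         h = NULL, sigma = "auto", patch_sigma = 1.0) {
  search_radius <- as.integer(search_radius)
  patch_radius <- as.integer(patch_radius)
  if (patch_radius < 1L || search_radius < patch_radius)
    stop("need search_radius >= patch_radius >= 1", call. = FALSE)
  if (patch_sigma <= 0) stop("patch_sigma must be > 0", call. = FALSE)
  structure(list(
    search_radius = search_radius, patch_radius = patch_radius,
    h = h, sigma = sigma, patch_sigma = patch_sigma,
    n_search = as.integer((2L * search_radius + 1L)^3),
    n_patch_neighbors = as.integer((2L * patch_radius + 1L)^3 - 1L)
  ), class = "ornlm_params")
}

#' Optimized Rician non-local means denoising
#'
#' Voxelwise non-local means with Rician bias correction. Each voxel of the
#' squared image is replaced by a patch-similarity-weighted average over its
#' search window (weights `w = exp(-d^2/h^2)` where `d^2` is the
#' Gaussian-weighted mean squared difference between the two magnitude-image
#' patches, self weight 1 included), then the Rician bias is removed:
#' `out = sqrt(max(NLM(u^2) - 2 sigma^2, 0))`, which is unbiased for the true
#' squared signal since `E[M^2] = S^2 + 2 sigma^2`. Patch reads beyond the
#' volume border use edge replication; the search window is clipped at the
#' border.
#'
#' @param volume 3D non-negative numeric array (magnitude image).
#' @param params An [ornlm_params()].
#' @param background_mask Optional logical mask of signal-free voxels used to
#'   resolve `sigma = "auto"` via [estimate_sigma()]; if omitted, the
#'   [default_background_roi()] is tried.
#' @return Filtered 3D array, everywhere >= 0.
#' @export
ornlm <- function(volume, params = ornlm_params(), background_mask = NULL) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("`volume` must be a 3D array", call. = FALSE)
  if (any(!is.finite(volume)) || any(volume < 0))
    stop("`volume` must be a finite non-negative magnitude image", call. = FALSE)
  stopifnot(inherits(params, "ornlm_params"))
  sigma <- params$sigma
  if (identical(sigma, "auto")) {
    if (is.null(background_mask)) {
      background_mask <- tryCatch(default_background_roi(volume),
                                  error = function(e) NULL)
      if (is.null(background_mask))
        stop("sigma = \"auto\" but no background mask is resolvable for this volume",
             call. = FALSE)
    }
    sigma <- estimate_sigma(volume, background_mask)$sigma
  }
  if (!is.numeric(sigma) || !is.finite(sigma) || sigma < 0)
    stop("sigma must be a non-negative number or \"auto\"", call. = FALSE)
  h <- if (is.null(params$h)) 1.0 * max(sigma, .Machine$double.eps) else params$h
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  .ornlm_core(as.double(volume), as.integer(dim(volume)),
              params$search_radius, params$patch_radius,
              h, sigma, params$patch_sigma)
}

#' Apply a 3D denoiser to every cardiac phase of a cine series
#'
#' Splits the 4D series into its per-phase 3D volumes and filters each one
#' independently — never across the phase axis — preserving the spacing
#' metadata. Parameters not supplied are resolved per phase: the noise level
#' `sigma` is estimated from the default background corner
#' (Rayleigh-corrected), the diffusion threshold defaults to
#' `kappa = 2 * sigma_hat` and the TV strength to `weight = sigma_hat`.
#'
#' @param series A [cine_series()].
#' @param method One of `"aniso"`, `"tv"`, `"ornlm"`.
#' @param params Named list of parameters forwarded to the filter
#'   ([anisotropic_diffusion()], [total_variation()] or [ornlm()]).
#' @param quiet Suppress the one-line log of resolved parameters.
#' @return A filtered [cine_series()]; the per-phase resolved parameters are
#'   attached as attribute `"resolved_params"` (a tibble).
#' @export
denoise_series <- function(series, method, params = list(), quiet = FALSE) {
  stopifnot(inherits(series, "cine_series"))
  methods <- c("aniso", "tv", "ornlm")
  if (!is.character(method) || length(method) != 1L || !method %in% methods)
    stop(sprintf("unknown method %s; valid methods: %s",
                 deparse(substitute(method)), paste(methods, collapse = ", ")),
         call. = FALSE)
  data <- series$data
  resolved <- vector("list", series$n_phases)
  for (p in seq_len(series$n_phases)) {
    vol <- series$data[, , , p, drop = FALSE][, , , 1L]
    sigma_hat <- NA_real_
    needs_sigma <- (method == "aniso" && is.null(params$kappa)) ||
      (method == "tv" && is.null(params$weight)) || method == "ornlm"
    if (needs_sigma) {
      bg <- if (is.null(params$background_mask))
        default_background_roi(vol) else params$background_mask
      sigma_hat <- estimate_sigma(vol, bg)$sigma
    }
    out <- switch(method,
      aniso = {
        kappa <- params$kappa %||% (2 * sigma_hat)
        anisotropic_diffusion(vol, kappa = kappa,
                              n_iter = params$n_iter %||% 10L,
                              dt = params$dt %||% (1 / 14))
      },
      tv = {
        weight <- params$weight %||% sigma_hat
        total_variation(vol, weight = weight,
                        max_iter = params$max_iter %||% 200L,
                        tol = params$tol %||% 1e-4)
      },
      ornlm = {
        op <- ornlm_params(
          search_radius = params$search_radius %||% 5L,
          patch_radius = params$patch_radius %||% 1L,
          h = params$h,
          sigma = params$sigma %||% sigma_hat,
          patch_sigma = params$patch_sigma %||% 1.0)
        ornlm(vol, op, background_mask = params$background_mask)
      })
    data[, , , p] <- out
    resolved[[p]] <- tibble::tibble(phase = p, method = method,
                                    sigma_hat = sigma_hat)
  }
  resolved <- dplyr::bind_rows(resolved)
  if (!quiet)
    message(sprintf("denoise_series: method=%s, %d phases, sigma_hat %s",
                    method, series$n_phases,
                    if (all(is.na(resolved$sigma_hat))) "(given)"
                    else sprintf("%.4g-%.4g", min(resolved$sigma_hat),
                                 max(resolved$sigma_hat))))
  out_series <- cine_series(pmax(data, 0), series$spacing)
  attr(out_series, "resolved_params") <- resolved
  out_series
}

`%||%` <- function(a, b) if (is.null(a)) b else a
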