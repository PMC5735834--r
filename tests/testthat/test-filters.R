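test_that("anisotropic diffusion is an identity on constant volumes and conserves intensity", {
  const <- array(3.7, c(12, 10, 8))
  expect_equal(anisotropic_diffusion(const, kappa = 1), const)
  vol <- array(stats::runif(12 * 10 * 8), c(12, 10, 8))
  out <- anisotropic_diffusion(vol, kappa = 0.5, n_iter = 15)
  expect_lt(abs(sum(out) - sum(vol)) / abs(sum(vol)), 1e-6)
})

test_that("anisotropic diffusion preserves strong edges while smoothing noise", {
  set.seed(101)
  d <- c(24, 16, 16)
  vol <- array(0, d)
  vol[13:24, , ] <- 10                      # step edge of height 10
  noise <- array(stats::rnorm(prod(d), 0, 0.3), d)
  noisy <- vol + noise
  out <- anisotropic_diffusion(noisy, kappa = 1)
  # edge-adjacent gradient keeps >= 90% of the step height
  edge_height <- mean(out[13, 5:12, 5:12] - out[12, 5:12, 5:12])
  expect_gt(edge_height, 9)
  # flat-region noise variance drops by >= 50%
  var_before <- stats::var(as.vector(noisy[3:10, 5:12, 5:12] -
                                       vol[3:10, 5:12, 5:12]))
  var_after <- stats::var(as.vector(out[3:10, 5:12, 5:12] -
                                      vol[3:10, 5:12, 5:12]))
  expect_lt(var_after / var_before, 0.5)
})

test_that("unstable diffusion time steps are rejected with the admissible bound", {
  vol <- array(1, c(4, 4, 4))
  expect_error(anisotropic_diffusion(vol, kappa = 1, dt = 0.2), "bound")
})

test_that("zero-weight TV is the identity and TV never increases total variation", {
  set.seed(7)
  vol <- array(stats::runif(16^3), c(16, 16, 16))
  expect_identical(total_variation(vol, weight = 0), vol)
  for (w in c(0.01, 0.1, 0.5)) {
    out <- total_variation(vol, weight = w)
    expect_lte(tv_norm(out), tv_norm(vol) + 1e-8)
  }
  expect_error(total_variation(vol * NA, weight = 0.1), "finite")
})

test_that("TV denoising matches the reference implementation on a noisy cube", {
  set.seed(42)
  vol <- array(0, c(16, 16, 16))
  vol[5:12, 5:12, 5:12] <- 1
  vol <- vol + array(stats::rnorm(16^3, 0, 0.2), dim(vol))
  w <- 0.15
  mine <- total_variation(vol, weight = w, max_iter = 2000, tol = 1e-12)
  ref <- tv_reference(vol, weight = w, max_iter = 2000, eps = 1e-14)
  expect_lt(sqrt(mean((mine - ref)^2)), 1e-3)
})

test_that("ORNLM default windows span 1331 search voxels and 26 patch neighbors", {
  p <- ornlm_params()
  expect_identical(p$n_search, 1331L)
  expect_identical(p$n_patch_neighbors, 26L)
  expect_error(ornlm_params(search_radius = 1, patch_radius = 2), "search_radius")
})

test_that("ORNLM with vanishing h and sigma leaves an all-distinct volume unchanged", {
  set.seed(3)
  vol <- array(stats::runif(5^3, 1, 2), c(5, 5, 5))
  out <- ornlm(vol, ornlm_params(search_radius = 2, h = 1e-8, sigma = 0))
  expect_lt(max(abs(out - vol)), 1e-10)
  # constant volume: exact idempotence at sigma = 0
  const <- array(4, c(6, 6, 6))
  expect_equal(max(abs(ornlm(const, ornlm_params(search_radius = 2,
                                                 sigma = 0, h = 1)) - const)),
               0, tolerance = 1e-12)
})

test_that("optimized ORNLM agrees with the brute-force oracle", {
  set.seed(12)
  vol <- array(0, c(9, 9, 9))
  vol[3:7, 3:7, 3:7] <- 2
  vol <- abs(vol + array(stats::rnorm(9^3, 0, 0.3), dim(vol)))
  sigma <- 0.3
  mine <- ornlm(vol, ornlm_params(sigma = sigma))
  ref <- ornlm_oracle(vol, search_radius = 5L, patch_radius = 1L,
                      h = sigma, sigma = sigma)
  expect_lt(max(abs(mine - ref)), 1e-10)
})

test_that("the Rician bias correction moves the mean toward the true signal", {
  a_true <- 10; sigma <- 2
  noisy <- add_rician_noise(array(a_true, c(24, 24, 24)), sigma, seed = 77L)
  out <- ornlm(noisy, ornlm_params(sigma = sigma))
  expect_lt(abs(mean(out) - a_true), abs(mean(noisy) - a_true))
  expect_true(all(out >= 0))
})

test_that("ORNLM resolves sigma automatically or fails informatively", {
  x <- noisy_small_phantom(seed = 19L, n_phases = 2L)
  vol <- phase_volume(x$noisy, 1L)
  auto <- ornlm(vol, ornlm_params())   # default background corner
  given <- ornlm(vol, ornlm_params(sigma = x$sigma))
  expect_lt(mean(abs(auto - given)), 0.02)
  expect_error(ornlm(array(0.5, c(8, 8, 8)), ornlm_params()), "background")
})

test_that("each filter strictly reduces RMSE on the noisy phantom", {
  x <- noisy_small_phantom(seed = 23L, n_phases = 2L)
  clean <- phase_volume(x$phantom$series, 1L)
  vol <- phase_volume(x$noisy, 1L)
  rmse <- function(a) sqrt(mean((a - clean)^2))
  base <- rmse(vol)
  expect_lt(rmse(anisotropic_diffusion(vol, kappa = 2 * x$sigma)), base)
  expect_lt(rmse(total_variation(vol, weight = x$sigma)), base)
  expect_lt(rmse(ornlm(vol, ornlm_params(sigma = x$sigma))), base)
})

test_that("series denoising is per phase: shapes kept, phases independent", {
  x <- noisy_small_phantom(seed = 29L, n_phases = 3L, nx = 48L)
  out <- denoise_series(x$noisy, "aniso", quiet = TRUE)
  expect_identical(dim(out$data), dim(x$noisy$data))
  expect_identical(out$spacing, x$noisy$spacing)
  # permuting phases before filtering equals permuting after
  perm <- c(2L, 3L, 1L)
  permuted <- cine_series(x$noisy$data[, , , perm], x$noisy$spacing)
  out_perm <- denoise_series(permuted, "aniso", quiet = TRUE)
  expect_equal(out_perm$data, out$data[, , , perm])
  # altering one phase leaves the other phases' output untouched
  tweaked_data <- x$noisy$data
  tweaked_data[, , , 2] <- tweaked_data[, , , 2] + 0.5
  out_tweak <- denoise_series(cine_series(tweaked_data, x$noisy$spacing),
                              "aniso", quiet = TRUE)
  expect_equal(out_tweak$data[, , , c(1, 3)], out$data[, , , c(1, 3)])
  expect_false(isTRUE(all.equal(out_tweak$data[, , , 2], out$data[, , , 2])))
  expect_error(denoise_series(x$noisy, "median"), "valid methods")
})
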