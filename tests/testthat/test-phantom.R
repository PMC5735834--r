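test_that("default configuration reproduces the acquisition grid", {
  cfg <- phantom_config()
  expect_identical(c(cfg$nx, cfg$ny, cfg$n_slices, cfg$n_phases),
                   c(256L, 256L, 15L, 16L))
  expect_equal(c(cfg$dx, cfg$dy, cfg$dz), c(0.195, 0.195, 1.0))
  # cheap 2-phase variant with default geometry: full series shape contract
  cfg2 <- phantom_config(n_phases = 2L)
  ph <- generate_phantom(cfg2)
  expect_identical(dim(ph$series$data), c(256L, 256L, 15L, 2L))
})

test_that("phantom geometry, volumes and ground-truth round trip", {
  ph <- generate_phantom(small_phantom())
  # intensity model: exactly three levels, blood brightest
  expect_setequal(unique(as.vector(ph$series$data)), c(0, 1, 2))
  # round trip: recomputing function from truth labels reproduces truth exactly
  expect_identical(compute_function(ph$truth$truth_seg),
                   ph$truth$true_function)
  # deterministic generation
  ph2 <- generate_phantom(small_phantom())
  expect_identical(ph$series$data, ph2$series$data)
})

test_that("myocardial volume is conserved across the full 16-phase cycle", {
  # native in-plane resolution, where voxelization error is at the study level
  ph <- generate_phantom(phantom_config())
  myo <- phase_volumes(ph$truth$truth_seg, 2L)
  expect_lt((max(myo) - min(myo)) / mean(myo), 0.03)
})

test_that("equal end-diastolic and end-systolic radii give zero ejection fraction", {
  cfg <- small_phantom()
  cfg$r_es <- cfg$r_ed - 1e-9  # constructor requires r_ed > r_es
  cfg <- do.call(phantom_config, unclass(cfg))
  ph <- generate_phantom(cfg)
  expect_equal(ph$truth$true_function$ef_pct, 0)
})

test_that("cavity volume matches the analytic cylinder at fine resolution", {
  # r = 3 mm cavity over a 10-slice (1 mm) ventricle at 0.195 mm in-plane:
  # EDV should sit within voxelization error of pi * r^2 * h = 282.74 uL
  cfg <- phantom_config(nx = 128, ny = 128, n_slices = 12, n_phases = 2,
                        dz = 1.0, r_ed = 3, r_es = 1.5, myo_volume = 300,
                        base_slice = 2, apex_slice = 11)
  ph <- generate_phantom(cfg)
  expect_equal(ph$truth$true_function$edv_ul, pi * 3^2 * 10,
               tolerance = 0.02)
})

test_that("an epicardium larger than the grid is rejected with the phase named", {
  cfg <- small_phantom()
  cfg$r_ed <- 25   # grid half-extent is 25 mm
  cfg <- do.call(phantom_config, unclass(cfg))
  expect_error(generate_phantom(cfg), "phase 1")
})

test_that("a zero-perturbation observer reproduces the truth exactly", {
  ph <- generate_phantom(small_phantom(n_phases = 2L))
  obs <- simulate_observer(ph$truth$truth_seg,
                           observer_model(0, 0, seed = 3L))
  expect_identical(obs$labels, ph$truth$truth_seg$labels)
})

test_that("observer output keeps valid label codes and is seed-reproducible", {
  ph <- generate_phantom(small_phantom(n_phases = 2L))
  model <- observer_model(1.5, 0.5, seed = 21L)
  a <- suppressWarnings(simulate_observer(ph$truth$truth_seg, model))
  b <- suppressWarnings(simulate_observer(ph$truth$truth_seg, model))
  expect_true(all(a$labels %in% 0:2))
  expect_identical(a$labels, b$labels)
  # a different seed gives a different segmentation
  c <- suppressWarnings(simulate_observer(ph$truth$truth_seg,
                                          observer_model(1.5, 0.5, seed = 22L)))
  expect_false(identical(a$labels, c$labels))
})

test_that("cavity Dice against truth decays as observer jitter grows", {
  ph <- generate_phantom(small_phantom(n_phases = 2L))
  truth_cav <- ph$truth$truth_seg$labels == 1L
  dice <- function(seg) {
    cav <- seg$labels == 1L
    2 * sum(cav & truth_cav) / (sum(cav) + sum(truth_cav))
  }
  mean_dice <- vapply(c(0.5, 1, 2), function(jit) {
    mean(vapply(1:20, function(s) {
      dice(suppressWarnings(simulate_observer(
        ph$truth$truth_seg, observer_model(jit, 0, seed = s))))
    }, numeric(1)))
  }, numeric(1))
  expect_true(mean_dice[1] > mean_dice[2])
  expect_true(mean_dice[2] > mean_dice[3])
})

test_that("contrast-linked jitter follows its defining proportionality", {
  expect_equal(cnr_linked_jitter(6, c = 6), 1.0)
  expect_equal(cnr_linked_jitter(20, c = 6), 2 * cnr_linked_jitter(40, c = 6))
  expect_error(cnr_linked_jitter(0), "cnr")
  expect_error(cnr_linked_jitter(-3), "cnr")
  expect_error(cnr_linked_jitter(5, c = 0), "c must")
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(r_ed = 2, r_es = 3), "r_ed > r_es")
  expect_error(phantom_config(i_blood = 1, i_myo = 2), "i_blood")
  expect_error(phantom_config(base_slice = 10, apex_slice = 4), "base_slice")
  expect_error(phantom_config(dz = 0), "spacings")
})
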