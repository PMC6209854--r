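test_that("synthetic ROI spheres match brute-force voxel counts", {
  expect_equal(attr(make_synthetic_roi(c(9, 9, 9), c(5, 5, 5), 0), "n_voxels"), 1L)
  # oracle: brute-force enumeration of the discrete ball
  for (r in c(1, 2, 3)) {
    roi <- make_synthetic_roi(c(11, 11, 11), c(6, 6, 6), r)
    grid <- expand.grid(x = 1:11, y = 1:11, z = 1:11)
    brute <- sum((grid$x - 6)^2 + (grid$y - 6)^2 + (grid$z - 6)^2 <= r^2)
    expect_equal(attr(roi, "n_voxels"), brute)
  }
  a <- make_synthetic_roi(c(12, 12, 12), c(3, 3, 3), 2)
  b <- make_synthetic_roi(c(12, 12, 12), c(9, 9, 9), 2)
  expect_false(any(a & b))
  expect_error(make_synthetic_roi(c(10, 10, 10), c(1, 5, 5), 2), "fit")
  expect_error(make_synthetic_roi(c(10, 10, 10), c(12, 5, 5), 1), "outside")
})

test_that("noise-free forward model equals baseline plus convolved regressor", {
  td <- make_task_schedule()
  grid <- c(5, 5, 5)
  roi <- make_synthetic_roi(grid, c(3, 3, 3), 1)
  ns <- noise_spec(sigma_white = 0, drift_amplitude = 0, physio_amplitude = 0,
                   seed = 2)
  run <- simulate_subject_bold(td, roi, c(sad = 1, happy = 0, neutral = 0),
                               ns, grid, 2, 100, baseline = 100)
  reg <- fmriresp:::condition_regressors(td, 2, 100)
  inside <- run$data[3, 3, 3, ]
  expect_equal(inside, 100 + reg[, "sad"], tolerance = 1e-12)
  outside <- run$data[1, 1, 1, ]
  expect_equal(outside, rep(100, 100), tolerance = 1e-12)
})

test_that("the BOLD generator is deterministic in its seed", {
  td <- make_task_schedule()
  roi <- make_synthetic_roi(c(5, 5, 5), c(3, 3, 3), 1)
  ns <- noise_spec(seed = 42)
  r1 <- simulate_subject_bold(td, roi, noise = ns, grid_shape = c(5, 5, 5),
                              n_volumes = 50)
  r2 <- simulate_subject_bold(td, roi, noise = ns, grid_shape = c(5, 5, 5),
                              n_volumes = 50)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_subject_bold(td, roi, noise = noise_spec(seed = 43),
                              grid_shape = c(5, 5, 5), n_volumes = 50)
  expect_false(identical(r1$data, r3$data))
})

test_that("equal amplitudes give a null sad-happy contrast", {
  td <- make_task_schedule()
  grid <- c(4, 4, 4)
  roi <- make_synthetic_roi(grid, c(2, 2, 2), 1)
  X <- build_design_matrix(td, 2, 96, include_derivatives = FALSE,
                           cutoff_s = NULL)
  cv <- contrast_vector(X)
  effects <- vapply(1:50, function(s) {
    ns <- noise_spec(sigma_white = 0.5, ar1_rho = 0, drift_amplitude = 0,
                     physio_amplitude = 0, seed = s)
    run <- simulate_subject_bold(td, roi, c(sad = 1, happy = 1, neutral = 0.5),
                                 ns, grid, 2, 96)
    cm <- compute_contrast(fit_glm(run, X, prewhiten = "none"), cv)
    mean(cm$effect[roi])
  }, numeric(1))
  se <- sd(effects) / sqrt(length(effects))
  expect_lt(abs(mean(effects)), 3 * se + 1e-12)
})

test_that("cohort labels and planted effects honour the generator contract", {
  co <- simulate_cohort(4, 4, effect_delta = 1.0,
                        noise = noise_spec(sigma_white = 0.1),
                        seed = 9, grid_shape = c(4, 4, 4), n_volumes = 8,
                        design = make_task_schedule(),
                        roi = make_synthetic_roi(c(4, 4, 4), c(2, 2, 2), 1))
  rec <- co$records
  expect_equal(sum(rec$responder), 4L)
  expect_identical(classify_response(rec$hamd_baseline, rec$hamd_week6),
                   rec$responder)
  gap <- mean(rec$true_effect[rec$responder]) -
    mean(rec$true_effect[!rec$responder])
  expect_lt(abs(gap - 1.0), 0.1)
  # null configuration: group means exactly equal
  co0 <- simulate_cohort(3, 3, effect_delta = 0, seed = 2,
                         grid_shape = c(4, 4, 4), n_volumes = 8,
                         roi = make_synthetic_roi(c(4, 4, 4), c(2, 2, 2), 1))
  expect_equal(mean(co0$records$true_effect[co0$records$responder]),
               mean(co0$records$true_effect[!co0$records$responder]))
  expect_error(simulate_cohort(2, 2, clinical_params = list(hamd_baseline_mean = 0)),
               "baseline")
})

test_that("nuisance regressors are zero-mean, reproducible, Nyquist-guarded", {
  nu <- simulate_nuisance_regressors(256, 2, c(0.2, 0.1), 33, seed = 3)
  expect_equal(dim(nu), c(256L, 33L))
  expect_true(all(abs(colMeans(nu)) < 1e-10))
  expect_identical(nu, simulate_nuisance_regressors(256, 2, c(0.2, 0.1), 33,
                                                    seed = 3))
  expect_error(simulate_nuisance_regressors(256, 2, 0.3, 33), "Nyquist")
})

test_that("map-level generator plants the requested group difference", {
  sim <- simulate_effect_maps(8, 8, effect_delta = 0.6, between_sd = 0.05,
                              noise_sd = 0.05, seed = 5)
  roi_means <- vapply(sim$maps, function(m) mean(m[sim$roi]), numeric(1))
  gap <- mean(roi_means[sim$labels]) - mean(roi_means[!sim$labels])
  expect_lt(abs(gap - 0.6), 0.1)
  expect_identical(sim$maps,
                   simulate_effect_maps(8, 8, effect_delta = 0.6,
                                        between_sd = 0.05, noise_sd = 0.05,
                                        seed = 5)$maps)
})
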