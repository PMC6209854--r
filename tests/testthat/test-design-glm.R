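test_that("paper-faithful design matrix has 3+3+33+1 columns in order", {
  td <- make_task_schedule()
  nu <- simulate_nuisance_regressors(165, 2, c(0.2, 0.1), 33, seed = 1)
  X <- build_design_matrix(td, 2, 165, include_derivatives = TRUE,
                           nuisance = nu)
  expect_equal(ncol(X$matrix), 40L)
  expect_equal(X$task_columns, 1:3)
  expect_equal(X$derivative_columns, 4:6)
  expect_equal(X$nuisance_columns, 7:39)
  expect_equal(X$intercept_column, 40L)
  expect_equal(X$column_names[1:3], c("sad", "happy", "neutral"))
})

test_that("degenerate designs are rejected", {
  td <- make_task_schedule()
  # run window shorter than the first sad block -> all-zero sad column
  expect_error(build_design_matrix(td, 2, 8), "no task blocks")
  nu_bad <- matrix(rnorm(10), 5, 2)
  expect_error(build_design_matrix(td, 2, 165, nuisance = nu_bad), "rows")
})

test_that("convolved regressor peaks lag a brief block by the HRF mode", {
  td <- task_design(c(0, 40), c(1, 1), c("sad", "happy"),
                    total_duration_s = 120)
  reg <- fmriresp:::condition_regressors(td, 2, 60)
  peak_t <- (which.max(reg[, "sad"]) - 1) * 2
  expect_lt(abs(peak_t - (0 + 4.5)), 2 + 1e-9)   # HRF mode 4.5 s, +/- TR
})

test_that("noise-free GLM recovers planted amplitudes exactly", {
  fx <- noise_free_run(sad = 1.5, happy = 0.5)
  X <- build_design_matrix(fx$design, 2, 128, include_derivatives = FALSE,
                           cutoff_s = NULL)
  fit <- fit_glm(fx$run, X, prewhiten = "none")
  cm <- compute_contrast(fit, contrast_vector(X))
  expect_lt(max(abs(cm$effect[fx$roi] - 1.0)), 1e-6)
  expect_lt(max(abs(cm$effect[!fx$roi])), 1e-6)
  # linearity: all-zero contrast gives the zero map
  cz <- compute_contrast(fit, numeric(ncol(X$matrix)))
  expect_true(all(cz$effect == 0))
})

test_that("duplicated design columns are rejected at fit time", {
  fx <- noise_free_run()
  X <- build_design_matrix(fx$design, 2, 128, include_derivatives = FALSE)
  X$matrix <- cbind(X$matrix, dup = X$matrix[, "sad"])
  X$column_names <- colnames(X$matrix)
  expect_error(fit_glm(fx$run, X), "rank deficient")
})

test_that("AR(1) rho estimates are unbiased on white noise", {
  td <- make_task_schedule()
  X <- build_design_matrix(td, 2, 128, include_derivatives = FALSE,
                           cutoff_s = NULL)
  rhos <- unlist(lapply(1:20, function(s) {
    set.seed(s)
    Y <- matrix(rnorm(128 * 100), 128, 100)
    fit_glm(Y, X, prewhiten = "ar1")$rho
  }))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("t statistics on null data follow the t distribution", {
  td <- make_task_schedule()
  X <- build_design_matrix(td, 2, 64, include_derivatives = FALSE,
                           cutoff_s = NULL)
  cv <- contrast_vector(X)
  tvals <- unlist(lapply(1:20, function(s) {
    set.seed(100 + s)
    Y <- matrix(rnorm(64 * 200), 64, 200)
    compute_contrast(fit_glm(Y, X, prewhiten = "none"), cv)$t
  }))
  df <- 64 - ncol(X$matrix)
  theo_sd <- sqrt(df / (df - 2))
  expect_lt(abs(sd(tvals) - theo_sd) / theo_sd, 0.1)
})

test_that("nuisance columns orthogonal to the task leave the contrast alone", {
  fx <- noise_free_run()
  X0 <- build_design_matrix(fx$design, 2, 128, include_derivatives = FALSE,
                            cutoff_s = NULL)
  base <- compute_contrast(fit_glm(fx$run, X0, prewhiten = "none"),
                           contrast_vector(X0))
  # project random noise off the task+intercept space to get orthogonal columns
  set.seed(3)
  raw <- matrix(rnorm(128 * 2), 128, 2)
  ortho <- qr.resid(qr(X0$matrix), raw)
  X1 <- build_design_matrix(fx$design, 2, 128, include_derivatives = FALSE,
                            nuisance = ortho, cutoff_s = NULL)
  with_n <- compute_contrast(fit_glm(fx$run, X1, prewhiten = "none"),
                             contrast_vector(X1))
  expect_lt(max(abs(with_n$effect - base$effect)), 1e-8)
})

test_that("full pipeline recovers planted contrasts with low bias under noise", {
  td <- make_task_schedule()
  grid <- c(4, 4, 4)
  roi <- make_synthetic_roi(grid, c(2, 2, 2), 1)
  ests <- vapply(1:25, function(s) {
    ns <- noise_spec(sigma_white = 0.1, ar1_rho = 0.3, drift_amplitude = 0.5,
                     physio_amplitude = 0.2, seed = s)
    run <- simulate_subject_bold(td, roi, c(sad = 1.3, happy = 0.5, neutral = 0.5),
                                 ns, grid, 2, 128)
    cm <- fit_first_level(run, td, fwhm_mm = 0, cutoff_s = 120)
    mean(cm$effect[roi])
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.8) / 0.8, 0.02)
})
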