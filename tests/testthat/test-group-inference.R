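test_that("second-level Z maps are calibrated on identical groups", {
  # identical effect maps in both groups: null rejections ~5% at |Z| > 1.96
  rates <- vapply(1:12, function(s) {
    sim <- simulate_effect_maps(8, 8, effect_delta = 0, smooth_fwhm_vox = 0,
                                seed = 500 + s)
    m <- group_model(sim$maps, sim$labels, sim$covariates)
    z <- second_level_z(m)
    mean(abs(z) > 1.96)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
  expect_true(all(rates < 0.12))
})

test_that("a strongly planted effect produces a suprathreshold ROI peak", {
  sim <- simulate_effect_maps(20, 12, effect_delta = 0.7, seed = 21)
  m <- group_model(sim$maps, sim$labels, sim$covariates)
  z <- second_level_z(m)
  expect_gt(max(z[sim$roi]), 2.3)
})

test_that("an identically-zero covariate leaves the Z map unchanged", {
  sim <- simulate_effect_maps(5, 5, effect_delta = 0.3, seed = 31)
  m0 <- group_model(sim$maps, sim$labels)
  m1 <- group_model(sim$maps, sim$labels, covariates = rep(0, 10))
  expect_identical(second_level_z(m0), second_level_z(m1))
  expect_error(group_model(sim$maps, sim$labels, covariates = rep(2, 10)),
               "rank deficient")
  expect_error(group_model(sim$maps, rep(TRUE, 10)), "2 subjects")
})

test_that("permutation cluster correction flags a planted effect and is deterministic", {
  sim <- simulate_effect_maps(10, 8, effect_delta = 0.8, seed = 41)
  m <- group_model(sim$maps, sim$labels, sim$covariates)
  cfg <- inference_config(n_permutations = 300, seed = 5)
  r1 <- small_volume_correct(m, sim$roi, cfg)
  expect_gt(nrow(r1$clusters), 0)
  expect_lt(min(r1$clusters$corrected_p), 0.05)
  r2 <- small_volume_correct(m, sim$roi, cfg)
  expect_identical(r1$clusters$corrected_p, r2$clusters$corrected_p)
  # ROI = whole grid reproduces the whole-brain call
  whole_roi <- roi_mask(array(1, c(16, 16, 16)))
  a <- small_volume_correct(m, whole_roi, cfg)
  b <- permutation_cluster_correct(m, mask = whole_roi, cfg = cfg)
  expect_identical(a$clusters$corrected_p, b$clusters$corrected_p)
})

test_that("negating all maps swaps the inference direction exactly", {
  sim <- simulate_effect_maps(6, 6, effect_delta = 0.6, seed = 51)
  cfg <- inference_config(n_permutations = 200, seed = 9)
  m_pos <- group_model(sim$maps, sim$labels, sim$covariates)
  m_neg <- group_model(lapply(sim$maps, function(x) -x), !sim$labels,
                       sim$covariates)
  r_pos <- small_volume_correct(m_pos, sim$roi, cfg)
  r_neg <- small_volume_correct(m_neg, sim$roi, cfg)
  expect_equal(r_pos$clusters$size_voxels, r_neg$clusters$size_voxels)
  expect_equal(r_pos$clusters$corrected_p, r_neg$clusters$corrected_p)
})

test_that("corrected p granularity follows the add-one estimator", {
  sim <- simulate_effect_maps(6, 5, effect_delta = 0.7, seed = 61)
  m <- group_model(sim$maps, sim$labels)
  p1 <- small_volume_correct(m, sim$roi,
                             inference_config(n_permutations = 100, seed = 3))
  p2 <- small_volume_correct(m, sim$roi,
                             inference_config(n_permutations = 101, seed = 3))
  expect_lt(abs(p1$clusters$corrected_p[1] - p2$clusters$corrected_p[1]),
            2 / 101 + 1e-12)
})

test_that("TFCE permutation correction detects the planted ROI effect", {
  sim <- simulate_effect_maps(10, 8, effect_delta = 0.8, seed = 71)
  m <- group_model(sim$maps, sim$labels, sim$covariates)
  cfg <- inference_config(n_permutations = 300, seed = 13)
  r <- tfce_permutation_correct(m, mask = sim$roi, cfg = cfg)
  expect_lt(min(r$corrected_p, na.rm = TRUE), 0.05)
  expect_true(all(is.na(r$corrected_p[!sim$roi])))
  r2 <- tfce_permutation_correct(m, mask = sim$roi, cfg = cfg)
  expect_identical(r$corrected_p, r2$corrected_p)
})

test_that("GRF corrected p tracks the permutation reference on smooth data", {
  # cross-method consistency: corrected p for the largest cluster, compared
  # in the mid p range. The Euler-characteristic formula omits boundary
  # resel terms, so on a 16^3 lattice individual datasets can deviate a few-
  # fold; require every dataset within 4x and the typical (median) agreement
  # within 2x.
  ratios <- c()
  for (s in 1:12) {
    sim <- simulate_effect_maps(9, 9, effect_delta = 0.10, between_sd = 0.1,
                                noise_sd = 0.1, smooth_fwhm_vox = 3,
                                seed = 800 + s)
    m <- group_model(sim$maps, sim$labels)
    roi <- roi_mask(array(1, c(16, 16, 16)))
    perm <- small_volume_correct(m, roi, inference_config(n_permutations = 400,
                                                          seed = s), "perm")
    grf <- small_volume_correct(m, roi, inference_config(seed = s), "grf")
    if (!nrow(perm$clusters)) next
    pp <- perm$clusters$corrected_p[1]
    pg <- grf$clusters$corrected_p[1]
    if (pp < 0.01 || pp > 0.5) next
    ratios <- c(ratios, pp / pg)
    expect_lt(max(pp / pg, pg / pp), 4)
  }
  expect_gt(length(ratios), 2)   # several datasets actually compared
  expect_lt(max(median(ratios), 1 / median(ratios)), 2)
})

test_that("small permutation spaces are enumerated with a warning", {
  maps <- lapply(1:4, function(i) array(rnorm(27, mean = i %% 2), c(3, 3, 3)))
  m <- group_model(maps, c(TRUE, FALSE, TRUE, FALSE))
  cfg <- inference_config(n_permutations = 100, seed = 1)
  expect_warning(permutation_cluster_correct(m, cfg = cfg), "distinct")
})
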