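test_that("response rule is the 50%-reduction boundary, inclusive", {
  expect_true(classify_response(23, 11))     # 52.2% reduction
  expect_true(classify_response(20, 10))     # exactly 50%
  expect_false(classify_response(20, 11))    # 45%
  expect_error(classify_response(0, 0), "baseline")
  expect_error(classify_response(20, -1), "non-negative")
  expect_error(classify_response(60, 10), "at most 52")
  # monotone: lowering week-6 never flips responder -> nonresponder
  set.seed(3)
  for (i in 1:50) {
    b <- sample(10:40, 1); w <- sample(0:b, 1)
    if (classify_response(b, w) && w > 0)
      expect_true(classify_response(b, w - 1))
  }
})

test_that("gender-table chi-square reproduces the reported statistic", {
  res <- chi_square_2x2(matrix(c(10, 10, 8, 4), 2, byrow = TRUE))
  expect_equal(round(res$statistic, 3), 0.847)
  expect_equal(round(res$p, 3), 0.358)
  expect_equal(res$dof, 1L)
  # proportional table
  expect_equal(chi_square_2x2(matrix(c(10, 10, 5, 5), 2, byrow = TRUE))$statistic,
               0, tolerance = 1e-12)
  # fully separated table: E = 10 everywhere, chi2 = 4 * 100/10 = 40
  expect_equal(chi_square_2x2(matrix(c(20, 0, 0, 20), 2, byrow = TRUE))$statistic,
               40)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("chi-square equals the sum((O-E)^2/E) oracle on random tables", {
  set.seed(11)
  for (i in 1:1000) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((tab - E)^2 / E)
    expect_equal(chi_square_2x2(tab)$statistic, oracle, tolerance = 1e-10)
  }
})

test_that("two-sample t matches closed forms", {
  same <- list(mean = 5, sd = 2, n = 10)
  res <- two_sample_t(same, same)
  expect_equal(res$t, 0); expect_equal(res$p, 1)
  # pooled closed form: delta / (s sqrt(2/n))
  res2 <- two_sample_t(list(mean = 1, sd = 1, n = 10),
                       list(mean = 0, sd = 1, n = 10), "pooled")
  expect_equal(res2$t, 1 / sqrt(2 / 10), tolerance = 1e-12)
  expect_equal(res2$t, 2.2360679, tolerance = 1e-6)
  # welch == pooled when n and SD match
  resw <- two_sample_t(list(mean = 1, sd = 1, n = 10),
                       list(mean = 0, sd = 1, n = 10), "welch")
  expect_equal(resw$t, res2$t)
  expect_equal(resw$dof, res2$dof)
  # raw-vector interface agrees with stats::t.test
  set.seed(7)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  ours <- two_sample_t(x, y, "welch")
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("demographics table mirrors the clinical report layout", {
  rec <- simulate_cohort(20, 12, effect_delta = 0, seed = 6,
                         grid_shape = c(4, 4, 4), n_volumes = 8,
                         roi = make_synthetic_roi(c(4, 4, 4), c(2, 2, 2), 1))$records
  tab <- demographics_table(rec)
  expect_equal(tab$responders[tab$variable == "n"], "20")
  expect_equal(tab$nonresponders[tab$variable == "n"], "12")
  expect_true(all(c("sex", "age_years", "hamd_baseline") %in% tab$variable))
  # identical groups: t statistics 0, p = 1; balanced sexes: chi2 = 0
  rec2 <- data.frame(responder = rep(c(TRUE, FALSE), each = 4),
                     sex = rep(c("F", "M"), 4),
                     age_years = rep(c(30, 40), 4),
                     hamd_baseline = rep(c(20, 24), 4))
  tab2 <- demographics_table(rec2)
  expect_equal(tab2$statistic[tab2$variable == "sex"], 0)
  expect_equal(tab2$p[tab2$variable == "age_years"], 1)
  expect_equal(tab2$p[tab2$variable == "hamd_baseline"], 1)
  expect_error(demographics_table(rec, variables = "missing_col"), "missing")
  expect_error(demographics_table(rec[rec$responder, ]), "non-empty")
})
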