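test_that("ROC construction matches rank-pair counting", {
  roc <- build_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))   # passes through (0, 1)
  # brute-force pair-counting oracle for the AUC
  pair_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- expand.grid(p = pos, n = neg)
    mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  }
  expect_equal(attr(roc, "auc"), 1.0)
  set.seed(5)
  for (i in 1:10) {
    sc <- sample(1:6, 8, replace = TRUE)    # ties included
    lb <- c(0, 1, sample(0:1, 6, replace = TRUE))
    expect_equal(attr(build_roc(sc, lb), "auc"), pair_auc(sc, lb))
  }
  expect_error(build_roc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("random scores give chance-level AUC", {
  set.seed(9)
  aucs <- replicate(40, {
    attr(build_roc(rnorm(60), rep(c(TRUE, FALSE), 30)), "auc")
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("optimal cut-off maximises TPR - FPR with the documented tie-break", {
  # exhaustive enumeration oracle over all candidate thresholds
  scores <- 1:6; labels <- c(0, 0, 1, 0, 1, 1)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    mean(scores[labels == 1] >= t) - mean(scores[labels == 0] >= t)
  }, numeric(1))
  best <- max(cand[j >= max(j) - 1e-12])   # tie-break toward higher threshold
  expect_equal(best, 5)
  expect_equal(optimal_cutoff(build_roc(scores, labels)), best)
  # perfect separation: chosen cut-off classifies the training data perfectly
  roc <- build_roc(c(1, 2, 10, 11), c(0, 0, 1, 1))
  cut <- optimal_cutoff(roc)
  expect_true(cut > 2 && cut <= 10)
  expect_equal(max(roc$tpr - roc$fpr), 1)
  # degenerate: all scores equal -> J = 0 at the single threshold
  roc0 <- build_roc(rep(2, 4), c(0, 1, 0, 1))
  expect_equal(optimal_cutoff(roc0), 2)
  expect_equal(max(roc0$tpr - roc0$fpr), 0)
})

test_that("mean cluster activity extraction is an arithmetic mean", {
  m <- array(4.2, c(4, 4, 2))
  cl <- roi_mask(array(rep(c(1, 0), 16), c(4, 4, 2)))
  expect_equal(extract_mean_activity(m, cl), 4.2)
  single <- roi_mask(array(c(1, rep(0, 31)), c(4, 4, 2)))
  m[1, 1, 1] <- -7
  expect_equal(extract_mean_activity(m, single), -7)
  checker <- array(rep(c(1, -1), 16), c(4, 4, 2))
  expect_equal(extract_mean_activity(checker, roi_mask(array(1, c(4, 4, 2)))), 0)
  expect_error(extract_mean_activity(m, roi_mask(array(0, c(4, 4, 2)))), "empty")
})

test_that("training clusters recover a planted effect and fall back sensibly", {
  cfg <- inference_config(n_permutations = 200, seed = 3)
  sim <- simulate_effect_maps(8, 6, effect_delta = 0.8, seed = 91)
  cl <- define_training_cluster(sim$maps, sim$labels, sim$covariates,
                                sim$roi, cfg)
  dice <- 2 * sum(cl & sim$roi) / (sum(cl) + sum(sim$roi))
  expect_gt(dice, 0.3)
  expect_equal(attr(cl, "fallback"), "significant")
  # pure noise: fallback still yields a usable nonempty mask
  null <- simulate_effect_maps(5, 5, effect_delta = 0, seed = 92)
  cl0 <- define_training_cluster(null$maps, null$labels, NULL, null$roi, cfg)
  expect_gt(sum(cl0), 0)
  expect_true(attr(cl0, "fallback") %in% c("suprathreshold", "roi"))
  # reversed effect: no responder > nonresponder cluster is significant
  rev <- simulate_effect_maps(6, 6, effect_delta = -0.8, seed = 93)
  clr <- define_training_cluster(rev$maps, rev$labels, NULL, rev$roi, cfg)
  expect_true(attr(clr, "fallback") != "significant")
  expect_error(define_training_cluster(rev$maps, rep(TRUE, 12), NULL,
                                       rev$roi, cfg), "both classes")
})

test_that("LOO predicts a strong planted effect and never leaks the held-out map", {
  sim <- simulate_effect_maps(8, 6, effect_delta = 0.8, seed = 101)
  cfg <- inference_config(n_permutations = 200, seed = 17)
  rep1 <- run_loo(sim$maps, sim$labels, sim$covariates, sim$roi, cfg)
  expect_gt(rep1$accuracy, 0.8)
  expect_equal(sum(rep1$confusion), 14)
  expect_equal(rep1$accuracy,
               (rep1$confusion[["tp"]] + rep1$confusion[["tn"]]) / 14)
  # leakage guard: replacing the held-out subject's map changes neither the
  # fold's cluster nor its cut-off
  for (i in c(1, 8, 14)) {
    mangled <- sim$maps
    mangled[[i]] <- array(1000 * sin(seq_len(16^3)), c(16, 16, 16))
    f_orig <- fmriresp:::loo_fold(sim$maps, sim$labels, sim$covariates,
                                  sim$roi, cfg, i)
    f_mang <- fmriresp:::loo_fold(mangled, sim$labels, sim$covariates,
                                  sim$roi, cfg, i)
    expect_identical(unclass(f_orig$cluster_mask), unclass(f_mang$cluster_mask))
    expect_identical(f_orig$cutoff, f_mang$cutoff)
  }
  # reproducibility: identical report on a rerun
  rep2 <- run_loo(sim$maps, sim$labels, sim$covariates, sim$roi, cfg)
  expect_identical(rep1$folds, rep2$folds)
})

test_that("label swap with map negation leaves LOO accuracy invariant", {
  sim <- simulate_effect_maps(6, 6, effect_delta = 0.6, seed = 111)
  cfg <- inference_config(n_permutations = 150, seed = 23)
  a <- run_loo(sim$maps, sim$labels, NULL, sim$roi, cfg)
  b <- run_loo(lapply(sim$maps, function(x) -x), !sim$labels, NULL,
               sim$roi, cfg)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("confusion summaries reproduce the printed classification rates", {
  m <- summarize_confusion(c(tp = 15, fn = 5, tn = 8, fp = 4))
  expect_equal(m$accuracy_pct, 71.875)
  expect_equal(m$sensitivity_pct, 75.0)
  expect_equal(m$specificity_pct, 66.7)
  expect_equal(m$ppv_pct, 78.9)
  expect_equal(m$npv_pct, 61.5)
  expect_equal(summarize_confusion(c(tp = 1, tn = 1, fp = 0, fn = 0))$accuracy, 1)
  und <- summarize_confusion(c(tp = 0, fn = 0, tn = 3, fp = 2))
  expect_true(is.na(und$sensitivity))
  expect_false(is.na(und$specificity))
  expect_error(summarize_confusion(c(tp = -1, fn = 0, tn = 1, fp = 0)),
               "non-negative")
})

test_that("exact binomial accuracy test uses the doubled smaller tail", {
  expect_equal(round(binomial_accuracy_test(23, 32), 2), 0.02)
  expect_equal(binomial_accuracy_test(16, 32), 1.0)
  expect_equal(binomial_accuracy_test(5, 5), 2 * (1 / 32))
  # symmetric around the centre
  expect_equal(binomial_accuracy_test(10, 32), binomial_accuracy_test(22, 32))
})
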