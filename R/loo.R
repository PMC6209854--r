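# Leave-one-out predictive analysis: per-fold training cluster, mean-activity
# scores, ROC cut-off, held-out classification, accuracy inference.

#' Define the responder > nonresponder cluster on training data
#'
#' Runs small-volume correction (cluster-forming Z, familywise alpha from
#' `cfg`) on the training subjects only and returns the largest significant
#' cluster as a mask. If no cluster is significant, falls back to the largest
#' suprathreshold cluster; if nothing is suprathreshold, to the whole ROI.
#' The fallback level is recorded in attribute `fallback`
#' (`"significant"`, `"suprathreshold"` or `"roi"`).
#'
#' @param train_maps List of training [contrast_map()]s / 3D arrays.
#' @param train_labels Responder flags for the training subjects.
#' @param train_covariates Optional covariates (e.g. baseline HAM-D).
#' @param roi The analysis [roi_mask()].
#' @param cfg An [inference_config()].
#' @param union_significant Return the union of all significant clusters
#'   instead of the largest one (default `FALSE`).
#' @return A [roi_mask()] subset of `roi`.
#' @export
define_training_cluster <- function(train_maps, train_labels,
                                    train_covariates = NULL, roi,
                                    cfg = inference_config(),
                                    union_significant = FALSE) {
  labels <- as.logical(train_labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present in the training data")
  model <- group_model(train_maps, labels, train_covariates)
  res <- small_volume_correct(model, roi, cfg, method = "perm")
  cl <- res$clusters
  labarr <- attr(cl, "labels")
  pick <- function(ids) {
    m <- array(FALSE, dim(labarr))
    m[labarr %in% ids] <- TRUE
    roi_mask(m)
  }
  sig <- cl$cluster_id[!is.na(cl$corrected_p) & cl$corrected_p < cfg$alpha_fwe]
  if (length(sig)) {
    ids <- if (union_significant) sig else sig[1L]  # largest (table is sorted)
    out <- pick(ids)
    attr(out, "fallback") <- "significant"
  } else if (nrow(cl)) {
    out <- pick(cl$cluster_id[1L])                        # largest by size
    attr(out, "fallback") <- "suprathreshold"
  } else {
    out <- if (inherits(roi, "roi_mask")) roi else roi_mask(roi)
    attr(out, "fallback") <- "roi"
  }
  out
}

#' Mean activity within a cluster
#'
#' @param map A [contrast_map()] or 3D effect array.
#' @param cluster A non-empty [roi_mask()] (or logical array).
#' @return Scalar mean of the effect values over the cluster voxels.
#' @export
extract_mean_activity <- function(map, cluster) {
  eff <- as_effect_array(map)
  m <- as.logical(cluster)
  if (!identical(dim(cluster), dim(eff))) stop("cluster shape mismatch")
  if (!any(m)) stop("cluster is empty")
  mean(eff[m])
}

# One LOO fold: everything derived from the training subjects only.
loo_fold <- function(maps, labels, covariates, roi, cfg, holdout) {
  train <- setdiff(seq_along(maps), holdout)
  if (!any(labels[train]) || all(labels[train]))
    stop("degenerate fold: a training class is empty when holding out ",
         holdout)
  fold_cfg <- cfg
  fold_cfg$seed <- derive_seed(cfg$seed, holdout)
  tc <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[train, , drop = FALSE]
  cluster <- define_training_cluster(maps[train], labels[train], tc, roi,
                                     fold_cfg)
  train_scores <- vapply(maps[train], extract_mean_activity, numeric(1),
                         cluster = cluster)
  roc <- build_roc(train_scores, labels[train])
  cutoff <- optimal_cutoff(roc)
  held_score <- extract_mean_activity(maps[[holdout]], cluster)
  list(held_out = holdout, cluster_mask = cluster,
       fallback = attr(cluster, "fallback"),
       cluster_size = attr(cluster, "n_voxels"),
       cutoff = cutoff, held_out_score = held_score,
       predicted_responder = held_score >= cutoff)
}

#' Leave-one-out response prediction
#'
#' For each subject: define the responder > nonresponder training cluster in
#' the ROI from the other n-1 subjects, extract mean cluster activity for
#' everyone, pick the training-ROC cut-off furthest from the diagonal, and
#' classify the held-out subject as a responder when their score is at or
#' above the cut-off (higher activity = predicted responder, fixed a priori).
#' The held-out subject's map never enters its own cluster or cut-off.
#'
#' @param all_maps List of per-subject [contrast_map()]s / 3D arrays.
#' @param labels True responder flags.
#' @param covariates Optional second-level covariates (baseline HAM-D).
#' @param roi The analysis [roi_mask()].
#' @param cfg An [inference_config()]; `cfg$seed` drives each fold's
#'   permutation stream.
#' @return A `loo_report`: per-fold table, confusion counts
#'   (positive = responder), accuracy, and the exact two-sided binomial p
#'   against chance.
#' @export
run_loo <- function(all_maps, labels, covariates = NULL, roi,
                    cfg = inference_config()) {
  labels <- as.logical(labels)
  n <- length(all_maps)
  stopifnot(n >= 4, sum(labels) >= 2, sum(!labels) >= 2)
  folds <- lapply(seq_len(n), function(i)
    loo_fold(all_maps, labels, covariates, roi, cfg, i))
  pred <- vapply(folds, `[[`, logical(1), "predicted_responder")
  tab <- data.frame(
    held_out = seq_len(n),
    actual = labels, predicted = pred,
    score = vapply(folds, `[[`, numeric(1), "held_out_score"),
    cutoff = vapply(folds, `[[`, numeric(1), "cutoff"),
    cluster_size = vapply(folds, `[[`, numeric(1), "cluster_size"),
    fallback = vapply(folds, `[[`, character(1), "fallback"))
  confusion <- c(tp = sum(pred & labels), fp = sum(pred & !labels),
                 tn = sum(!pred & !labels), fn = sum(!pred & labels))
  n_correct <- confusion[["tp"]] + confusion[["tn"]]
  structure(list(folds = tab, cluster_masks = lapply(folds, `[[`, "cluster_mask"),
                 confusion = confusion, accuracy = n_correct / n,
                 binomial_p = binomial_accuracy_test(n_correct, n),
                 cfg = cfg),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  n <- sum(x$confusion)
  cat(sprintf("Leave-one-out prediction: %d subjects, accuracy %.1f%% (%d/%d), binomial p = %.3g\n",
              n, 100 * x$accuracy, x$confusion[["tp"]] + x$confusion[["tn"]],
              n, x$binomial_p))
  cat(sprintf("  confusion: TP %d, FP %d, TN %d, FN %d (positive = responder)\n",
              x$confusion[["tp"]], x$confusion[["fp"]], x$confusion[["tn"]],
              x$confusion[["fn"]]))
  fb <- table(x$folds$fallback)
  cat("  cluster definition:",
      paste(sprintf("%s x%d", names(fb), fb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.loo_report <- function(object, ...) {
  m <- summarize_confusion(object$confusion)
  print(object)
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              m$sensitivity_pct, m$specificity_pct, m$ppv_pct, m$npv_pct))
  invisible(m)
}

#' @export
plot.loo_report <- function(x, ...) {
  graphics::hist(x$folds$cutoff, breaks = "FD", col = "grey80",
                 main = "Per-fold classification cut-offs",
                 xlab = "Cut-off (mean cluster activity)", ...)
  invisible(x)
}

#' Confusion-matrix summary metrics
#'
#' @param counts Named counts `tp`, `fp`, `tn`, `fn` (positive = responder).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   as fractions (NA when the denominator is zero) and the same as
#'   percentages rounded to one decimal (`*_pct`), except `accuracy_pct`
#'   which is reported at full precision.
#' @examples
#' summarize_confusion(c(tp = 15, fp = 4, tn = 8, fn = 5))
#' @export
summarize_confusion <- function(counts) {
  counts <- as.list(counts)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(accuracy = (tp + tn) / total,
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              ppv = ratio(tp, tp + fp),
              npv = ratio(tn, tn + fn))
  pct <- lapply(out, function(x) round(100 * x, 1))
  names(pct) <- paste0(names(out), "_pct")
  pct$accuracy_pct <- 100 * out$accuracy
  c(out, pct)
}

#' Exact binomial test of classifier accuracy against chance
#'
#' Two-sided exact binomial p-value for `n_correct` successes in `n_total`
#' trials against `p0`, computed as the doubled smaller tail, capped at 1.
#'
#' @param n_correct,n_total Correct classifications and total cases.
#' @param p0 Chance probability (default 0.5).
#' @return The p-value.
#' @examples
#' binomial_accuracy_test(23, 32)  # ~ 0.02
#' @export
binomial_accuracy_test <- function(n_correct, n_total, p0 = 0.5) {
  stopifnot(n_correct >= 0, n_correct <= n_total, n_total >= 1)
  lower <- pbinom(n_correct, n_total, p0)
  upper <- pbinom(n_correct - 1, n_total, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}
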