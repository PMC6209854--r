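# ROC curve construction and cut-off selection.

#' Build an ROC curve from scores and labels
#'
#' Sweeps thresholds over the unique scores (plus +Inf), predicting positive
#' (responder) when `score >= threshold`; tied scores share one threshold.
#'
#' @param scores Numeric scores (higher = more responder-like).
#' @param labels Logical (or 0/1) true labels; both classes must be present.
#' @return A `roc_curve` data frame with columns `threshold`, `fpr`, `tpr`,
#'   ordered from (0, 0) to (1, 1), with attribute `auc` (trapezoidal area).
#' @examples
#' build_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' @export
build_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!any(labels) || all(labels))
    stop("both classes must be present to build an ROC curve")
  np <- sum(labels); nn <- sum(!labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1))
  out <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(out, auc = auc, class = c("roc_curve", "data.frame"))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.3f\n",
              nrow(x), attr(x, "auc")))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "b", pch = 16,
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Optimal ROC cut-off (furthest from the diagonal)
#'
#' Returns the threshold maximising `TPR - FPR` (Youden's J; the perpendicular
#' distance from the leading diagonal is `(TPR - FPR)/sqrt(2)`, so the argmax
#' coincides). Ties are broken toward the higher threshold, i.e. the more
#' conservative responder call.
#'
#' @param roc A [build_roc()] result.
#' @return The selected finite threshold (a value attained by the scores).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  cand <- roc[is.finite(roc$threshold), , drop = FALSE]
  j <- cand$tpr - cand$fpr
  best <- which(j >= max(j) - 1e-12)
  max(cand$threshold[best])
}
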