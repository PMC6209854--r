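# Clinical-side statistics: response classification and the demographic
# comparison table.

#' Classify treatment response from HAM-D scores
#'
#' Response is a reduction in HAM-D of 50% or more from baseline at week 6:
#' `(baseline - week6) / baseline >= 0.5`.
#'
#' @param hamd_baseline,hamd_week6 Numeric vectors of 17-item HAM-D scores in
#'   `[0, 52]`; baseline must be positive.
#' @return Logical vector, `TRUE` = responder.
#' @examples
#' classify_response(20, 10)   # exactly 50% -> responder
#' classify_response(20, 11)   # 45% -> nonresponder
#' @export
classify_response <- function(hamd_baseline, hamd_week6) {
  if (any(hamd_baseline < 0 | hamd_week6 < 0))
    stop("HAM-D scores must be non-negative")
  if (any(hamd_baseline > 52 | hamd_week6 > 52))
    stop("HAM-D scores must be at most 52")
  if (any(hamd_baseline == 0))
    stop("baseline HAM-D of 0 cannot be classified (division by zero)")
  (hamd_baseline - hamd_week6) / hamd_baseline >= 0.5
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of counts (rows = group, columns = category), or a
#'   length-4 vector `c(a, b, c, d)` filled by row.
#' @param continuity_correction Apply the Yates correction (default `FALSE`;
#'   the uncorrected statistic is the conventional report for these tables).
#' @return List with `statistic`, `p`, `dof` (1) and the `expected` counts.
#' @examples
#' chi_square_2x2(matrix(c(10, 10, 8, 4), 2, byrow = TRUE))  # chi2 = 0.847
#' @export
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  if (!is.matrix(table)) table <- matrix(table, 2L, 2L, byrow = TRUE)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined with a zero marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = continuity_correction))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value), dof = 1L,
       expected = ct$expected)
}

#' Two-sample t test from raw values or summaries
#'
#' @param group1,group2 Either numeric vectors of raw values, or lists
#'   `list(mean =, sd =, n =)` of group summaries.
#' @param variant `"pooled"` (equal variances) or `"welch"`.
#' @return List with `t`, `p` (two-sided) and `dof`.
#' @export
two_sample_t <- function(group1, group2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  summarise <- function(g) {
    if (is.list(g)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(g)))
      g
    } else list(mean = mean(g), sd = sd(g), n = length(g))
  }
  g1 <- summarise(group1); g2 <- summarise(group2)
  stopifnot(g1$n >= 2, g2$n >= 2)
  if (g1$sd == 0 && g2$sd == 0 && g1$mean != g2$mean)
    stop("zero variance in both groups")
  if (variant == "pooled") {
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2)
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    dof <- g1$n + g2$n - 2
  } else {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    dof <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  tval <- if (se == 0) 0 else (g1$mean - g2$mean) / se
  list(t = tval, p = 2 * pt(abs(tval), dof, lower.tail = FALSE), dof = dof)
}

#' Demographic comparison table for responders vs nonresponders
#'
#' Mirrors the conventional baseline table: per-group n, mean +/- SE for each
#' continuous variable with a two-sample t test, and a chi-square test for
#' sex.
#'
#' @param records Data frame of subject records with columns `responder`
#'   (logical), `sex` (`"F"`/`"M"`), and numeric columns to compare (default:
#'   every numeric column except identifiers).
#' @param variables Character vector of numeric columns to summarise;
#'   defaults to `age_years` and `hamd_baseline` when present, else all
#'   numeric columns.
#' @param variant t-test variant (default pooled).
#' @return A `demographics_table` data frame with columns `variable`,
#'   `responders`, `nonresponders`, `statistic`, `p`, `test`.
#' @export
demographics_table <- function(records, variables = NULL,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(records), "responder" %in% names(records))
  grp <- as.logical(records$responder)
  if (!any(grp) || all(grp)) stop("both responder groups must be non-empty")
  if (is.null(variables)) {
    default <- intersect(c("age_years", "hamd_baseline"), names(records))
    variables <- if (length(default)) default else
      names(records)[vapply(records, is.numeric, logical(1))]
    variables <- setdiff(variables, c("responder", "true_effect"))
  }
  miss <- setdiff(variables, names(records))
  if (length(miss)) stop("missing field(s): ", paste(miss, collapse = ", "))
  rows <- list()
  rows[[1]] <- data.frame(variable = "n", responders = sum(grp),
                          nonresponders = sum(!grp), statistic = NA_real_,
                          p = NA_real_, test = "")
  if ("sex" %in% names(records)) {
    tab <- table(factor(grp, c(TRUE, FALSE)),
                 factor(records$sex, c("F", "M")))
    cs <- chi_square_2x2(unclass(tab))
    fmt <- function(g) sprintf("%dF/%dM", sum(records$sex[g] == "F"),
                               sum(records$sex[g] == "M"))
    rows[[length(rows) + 1]] <- data.frame(
      variable = "sex", responders = fmt(grp), nonresponders = fmt(!grp),
      statistic = cs$statistic, p = cs$p, test = "chi-square")
  }
  for (v in variables) {
    x1 <- records[[v]][grp]; x2 <- records[[v]][!grp]
    tt <- two_sample_t(x1, x2, variant = variant)
    fmt <- function(x) sprintf("%.2f±%.2f", mean(x), sd(x) / sqrt(length(x)))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, responders = fmt(x1), nonresponders = fmt(x2),
      statistic = abs(tt$t), p = tt$p, test = "t")
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    r$responders <- as.character(r$responders)
    r$nonresponders <- as.character(r$nonresponders)
    r
  }))
  structure(out, class = c("demographics_table", "data.frame"))
}

#' @export
print.demographics_table <- function(x, digits = 3, ...) {
  cat("Demographics: responders vs nonresponders (mean±SE)\n")
  y <- as.data.frame(x)
  y$statistic <- ifelse(is.na(y$statistic), "", formatC(y$statistic, digits = digits))
  y$p <- ifelse(is.na(y$p), "", formatC(y$p, digits = digits))
  print(y, row.names = FALSE)
  invisible(x)
}
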