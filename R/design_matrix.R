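# First-level design matrix: boxcars convolved with the gamma HRF on a fine
# grid, sampled at the TR, high-pass filtered, plus temporal derivatives,
# nuisance columns and an intercept.

# Convolved condition regressors sampled at volume acquisition times.
# Returns a n_volumes x 3 matrix with columns sad, happy, neutral.
condition_regressors <- function(design, tr_s, n_volumes, hrf = hrf_spec()) {
  stopifnot(inherits(design, "task_design"))
  dt <- hrf$dt_s
  run_len <- n_volumes * tr_s
  tg <- seq(0, run_len, by = dt)
  k <- hrf_kernel(hrf)
  conds <- c("sad", "happy", "neutral")
  out <- matrix(0, n_volumes, length(conds), dimnames = list(NULL, conds))
  vol_idx <- round((0:(n_volumes - 1)) * tr_s / dt) + 1L
  for (j in seq_along(conds)) {
    rows <- design$condition == conds[j]
    box <- numeric(length(tg))
    for (i in which(rows)) {
      on <- design$onset[i]; off <- on + design$duration[i]
      if (on >= run_len) next                      # design truncated to run
      box[tg >= on - dt / 2 & tg < min(off, run_len) - dt / 2] <- 1
    }
    conv <- convolve(box, rev(k$weights), type = "open")[seq_along(tg)]
    out[, j] <- conv[vol_idx]
  }
  out
}

#' Build a first-level design matrix
#'
#' One column per task condition (`sad`, `happy`, `neutral`): the condition
#' boxcar convolved with the gamma HRF on a fine grid, sampled at the TR and
#' high-pass filtered with the same filter as the data. Optionally adds
#' finite-difference temporal derivatives (zero-padded at the start, also
#' filtered), then nuisance columns, then an intercept.
#'
#' @param design A [task_design()]. Blocks beyond the run length are dropped.
#' @param tr_s Repetition time (seconds).
#' @param n_volumes Number of volumes in the run.
#' @param hrf An [hrf_spec()].
#' @param include_derivatives Add temporal derivative columns (default TRUE).
#' @param nuisance Optional matrix of nuisance regressors (rows = volumes).
#' @param cutoff_s High-pass cutoff applied to task columns; `NULL` disables
#'   filtering (useful for exact-recovery checks on unfiltered data).
#' @return A `design_matrix`: list with `matrix`, `column_names`, and index
#'   sets `task_columns`, `derivative_columns`, `nuisance_columns`,
#'   `intercept_column`.
#' @examples
#' td <- make_task_schedule()
#' X <- build_design_matrix(td, 2, 165, include_derivatives = FALSE)
#' @export
build_design_matrix <- function(design, tr_s, n_volumes, hrf = hrf_spec(),
                                include_derivatives = TRUE, nuisance = NULL,
                                cutoff_s = 120) {
  stop_if_not_scalar_pos(tr_s, "tr_s")
  stopifnot(n_volumes >= 3L)
  task <- condition_regressors(design, tr_s, n_volumes, hrf)
  zero_col <- apply(task, 2L, function(x) all(abs(x) < 1e-12))
  if (any(zero_col))
    stop("no task blocks fall inside the run window for condition(s): ",
         paste(colnames(task)[zero_col], collapse = ", "))
  deriv <- NULL
  if (include_derivatives) {
    deriv <- apply(task, 2L, function(x) c(0, diff(x)))
    colnames(deriv) <- paste0(colnames(task), "_deriv")
  }
  if (!is.null(cutoff_s)) {
    op <- highpass_operator(n_volumes, cutoff_s, tr_s)
    task <- highpass_filter(task, op = op)
    if (!is.null(deriv)) deriv <- highpass_filter(deriv, op = op)
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes)
      stop("nuisance matrix has ", nrow(nuisance), " rows; expected ", n_volumes)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
  }
  X <- cbind(task, deriv, nuisance, intercept = 1)
  nt <- ncol(task)
  ndv <- if (is.null(deriv)) 0L else ncol(deriv)
  nnu <- if (is.null(nuisance)) 0L else ncol(nuisance)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (", ncol(X), " columns, rank ",
         qr(X)$rank, ")")
  structure(list(matrix = X, column_names = colnames(X),
                 task_columns = seq_len(nt),
                 derivative_columns = if (ndv) nt + seq_len(ndv) else integer(0),
                 nuisance_columns = if (nnu) nt + ndv + seq_len(nnu) else integer(0),
                 intercept_column = ncol(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d volumes x %d columns (%d task, %d derivative, %d nuisance, 1 intercept)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$task_columns),
              length(x$derivative_columns), length(x$nuisance_columns)))
  invisible(x)
}

#' Contrast weights by column name
#'
#' Builds a contrast vector over a design matrix, e.g. `sad - happy`.
#'
#' @param X A [build_design_matrix()] result.
#' @param plus,minus Column names weighted +1 and -1.
#' @return Numeric contrast vector of length `ncol(X$matrix)`.
#' @export
contrast_vector <- function(X, plus = "sad", minus = "happy") {
  stopifnot(inherits(X, "design_matrix"))
  cv <- setNames(numeric(ncol(X$matrix)), X$column_names)
  if (!all(c(plus, minus) %in% X$column_names))
    stop("contrast names not found in design columns")
  cv[plus] <- cv[plus] + 1
  cv[minus] <- cv[minus] - 1
  cv
}
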