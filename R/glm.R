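# Voxelwise first-level GLM with optional AR(1) prewhitening, and contrasts.

#' Fit the first-level GLM to a BOLD run
#'
#' Voxelwise least squares of each (already filtered/smoothed) voxel time
#' series on the design matrix. With `prewhiten = "ar1"` a single-pass
#' Cochrane–Orcutt transform is applied: residual lag-1 autocorrelation is
#' estimated per voxel from the OLS fit, voxels are grouped into rho bins of
#' width 0.01, data and design are quasi-differenced with the bin's rho
#' (dropping the first volume, so dof falls by one) and refit.
#'
#' @param run A [bold_run()], or a numeric matrix (time x voxels) with
#'   attribute-free data for testing.
#' @param X A [build_design_matrix()] result.
#' @param prewhiten `"ar1"` (default) or `"none"`.
#' @return A `glm_fit`: coefficients (`beta`, columns = voxels), residual
#'   variance `sigma2`, residual `dof`, per-voxel `rho`, and per-rho-bin
#'   `(X'X)^-1` blocks used for contrast variances.
#' @export
fit_glm <- function(run, X, prewhiten = c("ar1", "none")) {
  prewhiten <- match.arg(prewhiten)
  stopifnot(inherits(X, "design_matrix"))
  if (inherits(run, "bold_run")) {
    d <- dim(run$data)
    Y <- t(matrix(run$data, nrow = prod(d[1:3]), ncol = d[4]))
    dims3 <- d[1:3]
  } else {
    Y <- as.matrix(run)
    dims3 <- NULL
  }
  Xm <- X$matrix
  if (nrow(Y) != nrow(Xm))
    stop("design has ", nrow(Xm), " rows but run has ", nrow(Y), " volumes")
  p <- ncol(Xm)
  qrX <- qr(Xm)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, Y)
  resid <- qr.resid(qrX, Y)
  n <- nrow(Y)
  if (prewhiten == "none") {
    dof <- n - p
    sigma2 <- colSums(resid^2) / dof
    XtXinv <- chol2inv(chol(crossprod(Xm)))
    bins <- list(list(idx = seq_len(ncol(Y)), XtXinv = XtXinv))
    rho <- rep(0, ncol(Y))
  } else {
    num <- colSums(resid[-1L, , drop = FALSE] * resid[-n, , drop = FALSE])
    den <- colSums(resid^2)
    rho <- ifelse(den > 0, num / den, 0)
    rho <- pmin(pmax(rho, -0.95), 0.95)
    rbin <- round(rho, 2L)
    dof <- (n - 1L) - p
    sigma2 <- numeric(ncol(Y))
    bins <- list()
    for (r in unique(rbin)) {
      idx <- which(rbin == r)
      Xs <- Xm[-1L, , drop = FALSE] - r * Xm[-n, , drop = FALSE]
      Ys <- Y[-1L, idx, drop = FALSE] - r * Y[-n, idx, drop = FALSE]
      qs <- qr(Xs)
      if (qs$rank < p) stop("prewhitened design is rank deficient at rho = ", r)
      beta[, idx] <- qr.coef(qs, Ys)
      es <- qr.resid(qs, Ys)
      sigma2[idx] <- colSums(es^2) / dof
      bins[[length(bins) + 1L]] <- list(idx = idx,
                                        XtXinv = chol2inv(chol(crossprod(Xs))))
    }
  }
  structure(list(beta = beta, sigma2 = sigma2, dof = dof, rho = rho,
                 dims = dims3, column_names = X$column_names,
                 design = X, bins = bins, prewhiten = prewhiten,
                 subject_id = if (inherits(run, "bold_run")) run$subject_id else NA_character_),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("First-level GLM fit: %d voxels, %d regressors, dof %d, prewhiten %s\n",
              ncol(x$beta), nrow(x$beta), x$dof, x$prewhiten))
  invisible(x)
}

#' Contrast of GLM parameter estimates
#'
#' Computes `effect = c' beta` per voxel with variance
#' `sigma^2 c' (X'X)^-1 c` (using each voxel's prewhitened design block) and
#' the voxelwise t statistic.
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Numeric contrast vector (length = number of columns; should
#'   be zero on nuisance columns) or the result of [contrast_vector()].
#' @param subject_id Optional identifier carried into the map.
#' @return A [contrast_map()] with an extra `t` array when the fit has voxel
#'   geometry, otherwise a list of vectors.
#' @export
compute_contrast <- function(fit, contrast, subject_id = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  if (length(contrast) != nrow(fit$beta))
    stop("contrast length ", length(contrast), " does not match ",
         nrow(fit$beta), " design columns")
  effect <- drop(crossprod(contrast, fit$beta))
  cXXc <- numeric(length(effect))
  for (b in fit$bins)
    cXXc[b$idx] <- drop(t(contrast) %*% b$XtXinv %*% contrast)
  variance <- fit$sigma2 * cXXc
  tval <- ifelse(variance > 0, effect / sqrt(variance), 0)
  sid <- subject_id %||% fit$subject_id
  if (is.null(fit$dims)) {
    return(list(effect = effect, variance = variance, t = tval, dof = fit$dof,
                contrast_vector = contrast, subject_id = sid))
  }
  cm <- contrast_map(array(effect, fit$dims), array(variance, fit$dims),
                     fit$dof, contrast, subject_id = sid %||% "sub-??")
  cm$t <- array(tval, fit$dims)
  cm
}

#' Full single-subject first-level analysis
#'
#' Convenience wrapper: spatially smooths the run, high-pass filters every
#' voxel time series, builds the design matrix (same filter), fits the GLM and
#' returns the requested contrast map.
#'
#' @param run A [bold_run()].
#' @param design A [task_design()].
#' @param nuisance Optional nuisance matrix (rows = volumes).
#' @param fwhm_mm Spatial smoothing FWHM (mm); 0 disables.
#' @param cutoff_s High-pass cutoff (seconds); `NULL` disables.
#' @param hrf An [hrf_spec()].
#' @param include_derivatives Include temporal derivatives.
#' @param prewhiten Passed to [fit_glm()].
#' @param plus,minus Conditions contrasted (default sad - happy).
#' @return A [contrast_map()].
#' @export
fit_first_level <- function(run, design, nuisance = NULL, fwhm_mm = 5,
                            cutoff_s = 120, hrf = hrf_spec(),
                            include_derivatives = TRUE,
                            prewhiten = c("ar1", "none"),
                            plus = "sad", minus = "happy") {
  stopifnot(inherits(run, "bold_run"))
  prewhiten <- match.arg(prewhiten)
  d <- dim(run$data)
  data <- run$data
  if (fwhm_mm > 0)
    data <- spatial_smooth(data, fwhm_mm, run$voxel_size_mm)
  Y <- t(matrix(data, nrow = prod(d[1:3]), ncol = d[4]))
  if (!is.null(cutoff_s)) {
    op <- highpass_operator(d[4], cutoff_s, run$tr_s)
    Y <- highpass_filter(Y, op = op)
  }
  X <- build_design_matrix(design, run$tr_s, d[4], hrf = hrf,
                           include_derivatives = include_derivatives,
                           nuisance = nuisance, cutoff_s = cutoff_s)
  fit <- fit_glm(Y, X, prewhiten = prewhiten)
  fit$dims <- d[1:3]
  fit$subject_id <- run$subject_id
  compute_contrast(fit, contrast_vector(X, plus, minus))
}
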