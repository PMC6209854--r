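# Second-level (between-subject) inference: voxelwise Z maps, cluster-extent
# and TFCE permutation correction, small-volume correction.

#' Inference configuration
#'
#' @param cluster_forming_z Voxelwise Z threshold forming clusters (2.3).
#' @param alpha_fwe Familywise alpha (0.05).
#' @param n_permutations Number of label permutations (5000).
#' @param connectivity Neighbourhood: 6, 18 or 26 (default 26).
#' @param tfce_E,tfce_H TFCE extent and height exponents (0.5, 2).
#' @param tfce_dh TFCE height step; `NULL` uses max(z)/100 per map.
#' @param two_sided Test both directions? Default `FALSE`: one-sided,
#'   responders > nonresponders.
#' @param seed Seed for the permutation stream.
#' @return An `inference_config` list.
#' @export
inference_config <- function(cluster_forming_z = 2.3, alpha_fwe = 0.05,
                             n_permutations = 5000, connectivity = 26,
                             tfce_E = 0.5, tfce_H = 2, tfce_dh = NULL,
                             two_sided = FALSE, seed = 1) {
  stopifnot(alpha_fwe > 0, alpha_fwe < 1, n_permutations >= 100,
            connectivity %in% c(6, 18, 26))
  structure(list(cluster_forming_z = cluster_forming_z, alpha_fwe = alpha_fwe,
                 n_permutations = as.integer(n_permutations),
                 connectivity = as.integer(connectivity), tfce_E = tfce_E,
                 tfce_H = tfce_H, tfce_dh = tfce_dh, two_sided = two_sided,
                 seed = seed),
            class = "inference_config")
}

#' Second-level group model
#'
#' Holds one contrast map per subject, the responder labels, and covariates.
#' The second-level design is `[group indicator, mean-centred covariates,
#' intercept]`; the group coefficient is the responder - nonresponder
#' difference.
#'
#' @param maps List of per-subject [contrast_map()]s or 3D effect arrays.
#' @param group_labels Logical (or 0/1) responder flags, one per subject.
#' @param covariates Optional numeric vector or matrix (e.g. baseline HAM-D),
#'   one row per subject. All-zero columns are dropped.
#' @return A `group_model` with the stacked data matrix (subjects x voxels),
#'   design, and geometry.
#' @export
group_model <- function(maps, group_labels, covariates = NULL) {
  stopifnot(is.list(maps), length(maps) == length(group_labels))
  labels <- as.logical(group_labels)
  if (any(is.na(labels))) stop("group labels must be binary")
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("need at least 2 subjects per group")
  arrs <- lapply(maps, as_effect_array)
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1))))
    stop("all subject maps must share one grid")
  Y <- t(vapply(arrs, as.numeric, numeric(prod(d))))   # n x V
  n <- length(labels)
  X <- cbind(group = as.numeric(labels))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("covariates must have one row per subject")
    if (any(!is.finite(cv))) stop("covariates must be finite")
    keep <- colSums(abs(cv)) > 0
    cv <- cv[, keep, drop = FALSE]
    if (ncol(cv)) {
      cv <- sweep(cv, 2L, colMeans(cv))
      if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
      X <- cbind(X, cv)
    }
  }
  X <- cbind(X, intercept = 1)
  if (qr(X)$rank < ncol(X))
    stop("second-level design is rank deficient (constant covariate ",
         "collinear with the intercept?)")
  structure(list(Y = Y, X = X, labels = labels, dims = d, n = n),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("Group model: %d subjects (%d responders), grid %s, design [%s]\n",
              x$n, sum(x$labels), paste(x$dims, collapse = "x"),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

# t -> Z via matched tail probabilities, numerically stable in the tails.
t_to_z <- function(t, df) {
  s <- sign(t)
  s[s == 0] <- 1
  s * qnorm(pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
            lower.tail = FALSE, log.p = TRUE)
}

# Core second-level OLS: returns effect, t, z, residuals over mask voxels.
second_level_fit <- function(model, mask = NULL) {
  stopifnot(inherits(model, "group_model"))
  idx <- mask_indices(model$dims, mask)
  Y <- model$Y[, idx, drop = FALSE]
  X <- model$X
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[1, 1])
  t <- ifelse(se > 0, beta[1, ] / se, 0)
  list(effect = beta[1, ], t = t, z = t_to_z(t, df), resid = res, df = df,
       idx = idx)
}

mask_indices <- function(dims, mask) {
  if (is.null(mask)) return(seq_len(prod(dims)))
  if (!identical(dim(mask), as.integer(dims)) && !identical(dim(mask), dims))
    stop("mask shape does not match map grid")
  idx <- which(as.logical(mask))
  if (!length(idx)) stop("mask is empty")
  idx
}

#' Voxelwise second-level Z map
#'
#' Ordinary least squares of the per-subject contrast estimates on the
#' second-level design; the group-difference t statistic is converted to Z
#' through matched tail probabilities.
#'
#' @param model A [group_model()].
#' @param mask Optional [roi_mask()]; voxels outside are NA.
#' @return 3D Z array with attribute `df`.
#' @export
second_level_z <- function(model, mask = NULL) {
  fit <- second_level_fit(model, mask)
  z <- array(NA_real_, model$dims)
  z[fit$idx] <- fit$z
  attr(z, "df") <- fit$df
  z
}

# Permutation matrix (nperm x n of row indices), enumerating all n!
# permutations when fewer distinct ones exist than requested.
make_permutations <- function(n, nperm, seed) {
  nfact <- if (n <= 12) factorial(n) else Inf
  if (nfact <= nperm) {
    warning("only ", nfact, " distinct permutations exist; using all of them")
    perms <- all_permutations(n)
  } else {
    perms <- with_seed(seed,
      t(vapply(seq_len(nperm), function(i) sample.int(n), integer(n))))
  }
  perms
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Shared Freedman-Lane setup: residualise against the reduced design
# (covariates + intercept, group column removed) and run the C++ engine.
perm_engine <- function(model, mask, cfg, do_cluster, do_tfce) {
  idx <- mask_indices(model$dims, mask)
  Y <- model$Y[, idx, drop = FALSE]
  X <- model$X
  Xr <- X[, -1L, drop = FALSE]
  qrr <- qr(Xr)
  resid_r <- qr.resid(qrr, Y)
  fitted_r <- Y - resid_r
  perms <- make_permutations(model$n, cfg$n_permutations, cfg$seed)
  contrast <- c(1, numeric(ncol(X) - 1L))
  z_thr <- cfg$cluster_forming_z
  res <- cpp_perm_maxstat(fitted_r, resid_r, X, contrast, perms - 1L,
                          as.integer(model$dims), as.integer(idx - 1L),
                          z_thr, cfg$connectivity, do_cluster, do_tfce,
                          cfg$tfce_E, cfg$tfce_H, cfg$tfce_dh %||% -1,
                          isTRUE(cfg$two_sided))
  res$nperm <- nrow(perms)
  res
}

#' Permutation cluster-extent correction
#'
#' Familywise-corrected cluster p-values from the permutation null of the
#' maximum suprathreshold cluster size. Group labels are permuted
#' Freedman-Lane style: the reduced model (covariates + intercept) is fitted,
#' its residuals permuted and its fitted part restored, and the full model
#' refit, so covariates are respected. The corrected p uses the add-one
#' estimator `(1 + #{null max >= observed}) / (n_perm + 1)`.
#'
#' @param model A [group_model()].
#' @param mask Optional [roi_mask()] search region (default: whole grid).
#' @param cfg An [inference_config()].
#' @return A `group_result`: Z map, [find_clusters()] table with
#'   `corrected_p`, the null maxima, and the configuration.
#' @export
permutation_cluster_correct <- function(model, mask = NULL,
                                        cfg = inference_config()) {
  z <- second_level_z(model, mask)
  zt <- if (isTRUE(cfg$two_sided)) abs(z) else z
  clusters <- find_clusters(zt, cfg$cluster_forming_z, cfg$connectivity, mask)
  null <- perm_engine(model, mask, cfg, do_cluster = TRUE, do_tfce = FALSE)
  if (nrow(clusters))
    clusters$corrected_p <- vapply(clusters$size_voxels, function(s)
      (1 + sum(null$max_cluster >= s)) / (null$nperm + 1), numeric(1))
  structure(list(method = "permutation_cluster", zmap = z, clusters = clusters,
                 null_max = null$max_cluster, n_permutations = null$nperm,
                 cfg = cfg, mask = mask),
            class = "group_result")
}

#' TFCE permutation correction
#'
#' Voxelwise familywise-corrected p-values from the permutation null of the
#' maximum TFCE score (same Freedman-Lane scheme as
#' [permutation_cluster_correct()]).
#'
#' @inheritParams permutation_cluster_correct
#' @return A `group_result` with the observed TFCE map and a voxelwise
#'   corrected-p array (`NA` outside the mask).
#' @export
tfce_permutation_correct <- function(model, mask = NULL,
                                     cfg = inference_config()) {
  z <- second_level_z(model, mask)
  zt <- if (isTRUE(cfg$two_sided)) abs(z) else z
  tf <- tfce_transform(zt, cfg, mask)
  null <- perm_engine(model, mask, cfg, do_cluster = FALSE, do_tfce = TRUE)
  idx <- mask_indices(model$dims, mask)
  pmap <- array(NA_real_, model$dims)
  nm <- sort(null$max_tfce)
  cnt <- length(nm) - findInterval(tf[idx] - 1e-12, nm)  # #{null >= obs}
  pmap[idx] <- (1 + cnt) / (null$nperm + 1)
  structure(list(method = "tfce_permutation", zmap = z, tfce = tf,
                 corrected_p = pmap, null_max = null$max_tfce,
                 n_permutations = null$nperm, cfg = cfg, mask = mask),
            class = "group_result")
}

#' Small-volume correction within an ROI
#'
#' Runs the whole-brain correction machinery with the search space (and the
#' permutation null) restricted to the ROI.
#'
#' @param model A [group_model()].
#' @param roi A non-empty [roi_mask()].
#' @param cfg An [inference_config()].
#' @param method `"perm"` (permutation cluster extent, default) or `"grf"`
#'   (Gaussian random field approximation with smoothness estimated from the
#'   standardized second-level residuals).
#' @return A `group_result`.
#' @export
small_volume_correct <- function(model, roi, cfg = inference_config(),
                                 method = c("perm", "grf")) {
  method <- match.arg(method)
  if (is.null(roi) || sum(roi != 0) == 0) stop("ROI mask is empty")
  if (!inherits(roi, "roi_mask")) roi <- roi_mask(roi)
  if (method == "perm")
    return(permutation_cluster_correct(model, mask = roi, cfg = cfg))
  fit <- second_level_fit(model, roi)
  z <- array(NA_real_, model$dims)
  z[fit$idx] <- fit$z
  attr(z, "df") <- fit$df
  zt <- if (isTRUE(cfg$two_sided)) abs(z) else z
  clusters <- find_clusters(zt, cfg$cluster_forming_z, cfg$connectivity, roi)
  resid_maps <- lapply(seq_len(model$n), function(i) {
    a <- array(0, model$dims); a[fit$idx] <- fit$resid[i, ]; a
  })
  sm <- estimate_smoothness(resid_maps, roi)
  if (nrow(clusters))
    clusters$corrected_p <- grf_cluster_pvalue(clusters$size_voxels,
                                               cfg$cluster_forming_z,
                                               sm$resels_per_voxel,
                                               length(fit$idx))
  structure(list(method = "grf_cluster", zmap = z, clusters = clusters,
                 smoothness = sm, cfg = cfg, mask = roi),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("Group inference (%s)", x$method))
  if (!is.null(x$n_permutations))
    cat(sprintf(", %d permutations", x$n_permutations))
  cat("\n")
  if (!is.null(x$clusters)) {
    print(x$clusters)
  } else if (!is.null(x$corrected_p)) {
    cat(sprintf("min corrected p = %.4g over %d voxels\n",
                min(x$corrected_p, na.rm = TRUE), sum(!is.na(x$corrected_p))))
  }
  invisible(x)
}
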