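# Suprathreshold cluster extraction and Gaussian-random-field cluster
# p-values.

#' Connected suprathreshold clusters of a Z map
#'
#' Labels connected components of `{z > threshold}` (optionally intersected
#' with a mask) under 6-, 18- or 26-neighbour connectivity and tabulates
#' them.
#'
#' @param zmap 3D numeric array (NA treated as background).
#' @param threshold Cluster-forming threshold (default 2.3).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param mask Optional [roi_mask()] restricting the search.
#' @return A `cluster_table` data frame with columns `cluster_id`,
#'   `size_voxels`, `peak_z`, `peak_x`, `peak_y`, `peak_z_coord`,
#'   `corrected_p` (NA until a correction step fills it), sorted by size
#'   descending; the 3D label array is attached as attribute `labels`.
#' @export
find_clusters <- function(zmap, threshold = 2.3, connectivity = 26, mask = NULL) {
  stopifnot(length(dim(zmap)) == 3L, is.finite(threshold))
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  z <- zmap
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(zmap)))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match zmap ", paste(dim(zmap), collapse = "x"))
    z[!mask] <- -Inf
  }
  z[is.na(z)] <- -Inf
  lab <- cpp_label_components(as.numeric(z), dim(zmap), threshold,
                              as.integer(connectivity))
  sizes <- attr(lab, "sizes")
  labels <- array(lab, dim(zmap))
  if (length(sizes) == 0L) {
    tab <- data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      peak_z = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z_coord = integer(0),
                      corrected_p = numeric(0))
  } else {
    rows <- lapply(seq_along(sizes), function(k) {
      idx <- which(labels == k)
      peak <- idx[which.max(zmap[idx])]
      co <- arrayInd(peak, dim(zmap))
      data.frame(cluster_id = k, size_voxels = sizes[k],
                 peak_z = zmap[peak], peak_x = co[1], peak_y = co[2],
                 peak_z_coord = co[3], corrected_p = NA_real_)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$size_voxels, tab$cluster_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, labels = labels, threshold = threshold,
            connectivity = connectivity,
            class = c("cluster_table", "data.frame"))
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("Cluster table: %d cluster(s) above z > %.3g (%d-connectivity)\n",
              nrow(x), attr(x, "threshold"), attr(x, "connectivity")))
  if (nrow(x)) print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Smoothness of a random field from standardized residuals
#'
#' Estimates per-axis smoothness of a stationary Gaussian field from the
#' lag-1 spatial autocorrelation of voxelwise-standardized residual maps,
#' assuming a Gaussian autocorrelation function: with lag-1 correlation `r`,
#' `FWHM = sqrt(-2 log 2 / log r)` voxels. This is an approximation used by
#' the parametric (random field) branch and is cross-checked against
#' permutation inference in the package tests.
#'
#' @param resid_maps List of 3D residual arrays (one per subject), or a
#'   single 3D array.
#' @param mask Optional [roi_mask()]; only voxel pairs fully inside the mask
#'   contribute.
#' @return List with `fwhm_vox` (length 3) and `resels_per_voxel`.
#' @export
estimate_smoothness <- function(resid_maps, mask = NULL) {
  if (is.array(resid_maps) && length(dim(resid_maps)) == 3L)
    resid_maps <- list(resid_maps)
  d <- dim(resid_maps[[1]])
  stack <- vapply(resid_maps, as.numeric, numeric(prod(d)))   # V x n
  sds <- apply(stack, 1L, sd)
  sds[sds == 0] <- 1
  stack <- stack / sds
  inmask <- if (is.null(mask)) array(TRUE, d) else array(as.logical(mask), d)
  lambda <- numeric(3)
  for (ax in 1:3) {
    idx_lo <- slice.index(array(0, d), ax) < d[ax]
    sel <- which(inmask & idx_lo)
    step <- c(1, d[1], d[1] * d[2])[ax]
    sel <- sel[inmask[sel + step]]
    if (!length(sel)) stop("mask too thin to estimate smoothness along axis ", ax)
    dif <- stack[sel + step, , drop = FALSE] - stack[sel, , drop = FALSE]
    lambda[ax] <- mean(dif^2)
  }
  r <- 1 - lambda / 2
  if (any(r <= 0))
    stop("smoothness estimate <= 0 (residuals rougher than white noise)")
  fwhm <- sqrt(-2 * log(2) / log(r))
  list(fwhm_vox = fwhm, resels_per_voxel = 1 / prod(fwhm))
}

#' Gaussian-random-field corrected cluster p-value
#'
#' Expected-Euler-characteristic approximation for the familywise-corrected
#' p-value of a cluster of given extent: with `u` the cluster-forming Z
#' threshold, expected cluster count
#' `E[m] = S (2 pi)^-2 (4 log 2)^{3/2} rpv (u^2 - 1) exp(-u^2/2)`, expected
#' suprathreshold volume `E[N] = S Phi(-u)`, tail
#' `P(extent >= k) = exp(-beta k^{2/3})` with
#' `beta = (Gamma(5/2) E[m]/E[N])^{2/3}`, and
#' `p = 1 - exp(-E[m] P(extent >= k))`. Documented as an approximation; the
#' permutation branch is the reference.
#'
#' @param cluster_size_voxels Observed extent(s) in voxels.
#' @param cluster_forming_z Z threshold used to form clusters (> 1).
#' @param smoothness_resels_per_voxel Resels per voxel from
#'   [estimate_smoothness()].
#' @param search_volume_voxels Number of voxels searched.
#' @return Corrected p-value(s), same length as `cluster_size_voxels`.
#' @export
grf_cluster_pvalue <- function(cluster_size_voxels, cluster_forming_z,
                               smoothness_resels_per_voxel,
                               search_volume_voxels) {
  if (smoothness_resels_per_voxel <= 0) stop("smoothness estimate <= 0")
  stopifnot(cluster_forming_z > 1, search_volume_voxels > 0,
            all(cluster_size_voxels > 0))
  u <- cluster_forming_z
  S <- search_volume_voxels
  Em <- S * (2 * pi)^-2 * (4 * log(2))^(3 / 2) * smoothness_resels_per_voxel *
    (u^2 - 1) * exp(-u^2 / 2)
  EN <- S * pnorm(u, lower.tail = FALSE)
  beta <- (gamma(5 / 2) * Em / EN)^(2 / 3)
  ptail <- exp(-beta * cluster_size_voxels^(2 / 3))
  1 - exp(-Em * ptail)
}
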