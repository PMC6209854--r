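# Core data containers: BOLD runs, ROI masks, contrast maps.

#' Construct a BOLD run
#'
#' @param data 4D numeric array (x, y, z, time) of signal intensities.
#' @param voxel_size_mm Length-3 positive numeric, voxel edges in mm.
#' @param tr_s Repetition time in seconds.
#' @param subject_id Identifier string.
#' @return A `bold_run` object (list with `data`, `voxel_size_mm`, `tr_s`,
#'   `subject_id`).
#' @export
bold_run <- function(data, voxel_size_mm = c(3, 3, 3), tr_s = 2,
                     subject_id = "sub-01") {
  if (length(dim(data)) != 4L)
    stop("BOLD data must be 4D (x, y, z, time); got ",
         length(dim(data)), " dimensions")
  if (!all(is.finite(data))) stop("BOLD intensities must all be finite")
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  stop_if_not_scalar_pos(tr_s, "tr_s")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = tr_s, subject_id = as.character(subject_id)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run %s: %dx%dx%d voxels x %d volumes, TR %.3g s, voxels %s mm\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_s,
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param data 3D array, nonzero entries mark in-mask voxels.
#' @return A `roi_mask`: logical 3D array with attribute `n_voxels`.
#' @export
roi_mask <- function(data) {
  if (length(dim(data)) != 3L) stop("ROI mask must be a 3D array")
  m <- array(as.logical(data != 0), dim = dim(data))
  structure(m, n_voxels = sum(m), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("ROI mask: %d voxels in a %dx%dx%d grid\n",
              attr(x, "n_voxels"), d[1], d[2], d[3]))
  invisible(x)
}

#' Spherical synthetic ROI
#'
#' Binary sphere of voxels whose centre-to-centre Euclidean distance from
#' `center` is at most `radius_vox`.
#'
#' @param grid_shape Length-3 integer grid dimensions.
#' @param center Length-3 voxel coordinates (1-based) of the sphere centre.
#' @param radius_vox Radius in voxel units (>= 0).
#' @return A [roi_mask()].
#' @examples
#' roi <- make_synthetic_roi(c(10, 10, 10), c(5, 5, 5), 2)
#' attr(roi, "n_voxels")  # 33
#' @export
make_synthetic_roi <- function(grid_shape, center, radius_vox) {
  stopifnot(length(grid_shape) == 3L, length(center) == 3L, radius_vox >= 0)
  if (any(center < 1) || any(center > grid_shape))
    stop("ROI center outside the grid")
  if (any(center - radius_vox < 1) || any(center + radius_vox > grid_shape))
    stop("sphere of radius ", radius_vox, " does not fit in the grid")
  dx <- (seq_len(grid_shape[1]) - center[1])^2
  dy <- (seq_len(grid_shape[2]) - center[2])^2
  dz <- (seq_len(grid_shape[3]) - center[3])^2
  d2 <- outer(outer(dx, dy, `+`), dz, `+`)
  roi_mask(d2 <= radius_vox^2 + 1e-9)
}

#' Construct a contrast map
#'
#' Per-subject 3D effect map for a named contrast of GLM coefficients, with
#' its voxelwise variance and residual degrees of freedom.
#'
#' @param effect 3D array of contrast estimates (signal units).
#' @param variance 3D array of contrast variances (>= 0).
#' @param dof Residual degrees of freedom of the first-level fit.
#' @param contrast_vector The contrast weights used.
#' @param subject_id Identifier.
#' @return A `contrast_map` object.
#' @export
contrast_map <- function(effect, variance, dof, contrast_vector,
                         subject_id = "sub-01") {
  stopifnot(length(dim(effect)) == 3L, identical(dim(effect), dim(variance)))
  if (any(variance < -1e-12, na.rm = TRUE)) stop("contrast variance must be >= 0")
  structure(list(effect = effect, variance = pmax(variance, 0), dof = dof,
                 contrast_vector = contrast_vector,
                 subject_id = as.character(subject_id)),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  d <- dim(x$effect)
  cat(sprintf("Contrast map %s: %dx%dx%d, dof %.1f, effect range [%.3g, %.3g]\n",
              x$subject_id, d[1], d[2], d[3], x$dof,
              min(x$effect), max(x$effect)))
  invisible(x)
}

# Extract the 3D effect array from a contrast_map or plain array.
as_effect_array <- function(x) {
  if (inherits(x, "contrast_map")) return(x$effect)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a contrast_map or 3D array")
}
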