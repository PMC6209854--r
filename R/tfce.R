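# Threshold-free cluster enhancement.

#' TFCE transform of a Z map
#'
#' For each voxel p, integrates `e(h, p)^E * h^H * dh` over the height grid
#' `h = dh, 2 dh, ..., <= z(p)`, where `e(h, p)` is the extent of the
#' connected component containing p at threshold h. Only positive values are
#' enhanced; NA and masked-out voxels are background.
#'
#' @param zmap 3D numeric array.
#' @param cfg An [inference_config()] supplying `tfce_E` (0.5), `tfce_H`
#'   (2), `tfce_dh` (`NULL` = max(z)/100) and `connectivity`.
#' @param mask Optional [roi_mask()].
#' @return 3D array of TFCE scores (0 where z <= 0 or outside the mask).
#' @examples
#' z <- array(0, c(4, 4, 1)); z[2, 2, 1] <- 3
#' tfce_transform(z, inference_config(tfce_dh = 0.01))[2, 2, 1]  # ~ 3^3/3
#' @export
tfce_transform <- function(zmap, cfg = inference_config(), mask = NULL) {
  stopifnot(length(dim(zmap)) == 3L)
  dh <- cfg$tfce_dh %||% -1
  if (!is.null(cfg$tfce_dh) && cfg$tfce_dh <= 0) stop("tfce_dh must be positive")
  z <- zmap
  z[is.na(z)] <- 0
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(zmap))) stop("mask shape mismatch")
    z[!mask] <- 0
  }
  out <- cpp_tfce(as.numeric(z), dim(zmap), cfg$tfce_E, cfg$tfce_H, dh,
                  as.integer(cfg$connectivity))
  array(out, dim(zmap))
}
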