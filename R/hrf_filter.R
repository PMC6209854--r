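# Hemodynamic response kernel, temporal high-pass filter, spatial smoothing.

#' Gamma hemodynamic response specification
#'
#' The HRF is a single gamma density parametrised by its mean (`delay_s`) and
#' standard deviation (`sd_s`); by moment matching the gamma shape is
#' `k = (delay_s/sd_s)^2` and scale `theta = sd_s^2/delay_s` (defaults give
#' k = 4, theta = 1.5).
#'
#' @param delay_s Mean of the kernel in seconds (default 6).
#' @param sd_s Standard deviation in seconds (default 3).
#' @param dt_s Sampling step of the convolution grid in seconds (default 0.1,
#'   fine enough for both sub-second events and 10 s blocks).
#' @return An `hrf_spec` list with the parameters plus derived `shape` and
#'   `scale`.
#' @export
hrf_spec <- function(delay_s = 6, sd_s = 3, dt_s = 0.1) {
  stop_if_not_scalar_pos(delay_s, "delay_s")
  stop_if_not_scalar_pos(sd_s, "sd_s")
  stop_if_not_scalar_pos(dt_s, "dt_s")
  structure(list(delay_s = delay_s, sd_s = sd_s, dt_s = dt_s,
                 shape = (delay_s / sd_s)^2, scale = sd_s^2 / delay_s),
            class = "hrf_spec")
}

#' Sampled HRF kernel
#'
#' Samples the gamma density of an [hrf_spec()] on `[0, delay_s + 5 sd_s]` at
#' step `dt_s` and normalises the weights to unit sum, so convolving a unit
#' boxcar leaves its plateau at 1.
#'
#' @param spec An [hrf_spec()].
#' @return List with `time` (seconds) and `weights` (unit sum).
#' @examples
#' k <- hrf_kernel(hrf_spec(6, 3))
#' k$time[which.max(k$weights)]  # mode near (shape-1)*scale = 4.5 s
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  tt <- seq(0, spec$delay_s + 5 * spec$sd_s, by = spec$dt_s)
  w <- dgamma(tt, shape = spec$shape, scale = spec$scale)
  list(time = tt, weights = w / sum(w))
}

#' Gaussian running-lines high-pass smoother matrix
#'
#' Builds the n x n linear operator of a Gaussian-weighted local linear
#' regression (running lines) over the time index. The Gaussian weight SD is
#' `cutoff_s / 4` seconds (`cutoff_s / (4 tr_s)` volumes), which places the
#' filter's half-power (3 dB) point at the cutoff period. The high-pass
#' filter subtracts this smoother's fit from the data.
#'
#' @param n Number of time points.
#' @param cutoff_s High-pass cutoff in seconds (default 120).
#' @param tr_s Repetition time in seconds.
#' @return An n x n matrix `S` with `S %*% x` the low-frequency trend of `x`.
#' @export
highpass_operator <- function(n, cutoff_s = 120, tr_s = 2) {
  stopifnot(n >= 3L)
  stop_if_not_scalar_pos(cutoff_s, "cutoff_s")
  stop_if_not_scalar_pos(tr_s, "tr_s")
  if (cutoff_s <= 2 * tr_s) stop("cutoff_s must exceed 2*tr_s")
  sigma <- cutoff_s / (4 * tr_s)
  idx <- seq_len(n)
  S <- matrix(0, n, n)
  for (t in idx) {
    d <- idx - t
    w <- exp(-d^2 / (2 * sigma^2))
    s0 <- sum(w); s1 <- sum(w * d); s2 <- sum(w * d^2)
    # weighted linear fit evaluated at t (local coordinate 0)
    S[t, ] <- w * (s2 - s1 * d) / (s0 * s2 - s1^2)
  }
  S
}

#' High-pass filter a time series
#'
#' Subtracts a Gaussian-weighted running-lines (local linear) trend from each
#' series and restores the original mean. Linear in the input up to the mean
#' restoration.
#'
#' @param series Numeric vector, or matrix with one series per column.
#' @param cutoff_s 3-dB cutoff in seconds (default 120).
#' @param tr_s Repetition time.
#' @param op Optional precomputed [highpass_operator()] (reused across many
#'   series of the same length).
#' @return Filtered series, same shape as the input.
#' @export
highpass_filter <- function(series, cutoff_s = 120, tr_s = 2, op = NULL) {
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1L) else as.matrix(series)
  if (nrow(x) < 3L) stop("series must have at least 3 samples")
  S <- op %||% highpass_operator(nrow(x), cutoff_s, tr_s)
  mu <- colMeans(x)
  out <- x - S %*% x
  out <- sweep(out, 2L, mu, `+`)
  if (vec) drop(out) else out
}

# Row-normalised 1D Gaussian convolution matrix (truncated at 4 sigma);
# row normalisation preserves constants at the edges.
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma_vox^2)), 0)
  })
  K / rowSums(K)
}

#' Spatial Gaussian smoothing
#'
#' Separable per-axis Gaussian convolution of a 3D volume (or each volume of a
#' 4D run) with `sigma_mm = fwhm_mm / sqrt(8 log 2)` converted to voxels per
#' axis. Edge kernels are renormalised so constant volumes are preserved.
#' `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm_mm Full width at half maximum in mm (default 5).
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return Smoothed array, same shape.
#' @export
spatial_smooth <- function(volume, fwhm_mm = 5, voxel_size_mm = c(3, 3, 3)) {
  nd <- length(dim(volume))
  if (!nd %in% c(3L, 4L)) stop("volume must be 3D or 4D")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (fwhm_mm == 0) return(volume)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  d <- dim(volume)
  out <- volume
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / voxel_size_mm[ax]
    K <- gauss_conv_matrix(d[ax], sigma_vox)
    perm <- c(ax, setdiff(seq_len(nd), ax))
    a <- aperm(out, perm)
    dm <- dim(a)
    dim(a) <- c(dm[1L], prod(dm[-1L]))
    a <- K %*% a
    dim(a) <- dm
    out <- aperm(a, order(perm))
  }
  out
}
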