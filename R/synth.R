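# Synthetic cohort generator: BOLD forward model, nuisance regressors,
# clinical records. The forward model mirrors what the first-level GLM fits
# (boxcar * gamma HRF + drift + AR(1) noise + physiological sinusoids), so
# noise-free simulations are recovered exactly by the estimator.

#' Noise specification for the BOLD forward model
#'
#' @param sigma_white SD of the AR(1) innovations (intensity units).
#' @param ar1_rho Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param drift_amplitude Scale of the random per-voxel linear + quadratic
#'   drift (intensity units over the run).
#' @param physio_frequencies_hz Frequencies of pseudo-physiological
#'   sinusoids. Defaults to 0.2 and 0.1 Hz (aliased respiratory/cardiac
#'   rhythms representable at TR = 2 s).
#' @param physio_amplitude Amplitude of the sinusoids (intensity units).
#' @param n_nuisance Number of nuisance regressors emitted for the first-level
#'   model (default 33).
#' @param seed Integer seed making the generator deterministic.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sigma_white = 1, ar1_rho = 0.3, drift_amplitude = 2,
                       physio_frequencies_hz = c(0.2, 0.1),
                       physio_amplitude = 0.5, n_nuisance = 33, seed = 1) {
  stopifnot(sigma_white >= 0, ar1_rho >= 0, ar1_rho < 1,
            drift_amplitude >= 0, physio_amplitude >= 0, n_nuisance >= 0)
  structure(list(sigma_white = sigma_white, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 physio_frequencies_hz = physio_frequencies_hz,
                 physio_amplitude = physio_amplitude,
                 n_nuisance = as.integer(n_nuisance), seed = seed),
            class = "noise_spec")
}

#' Simulate physiological-noise nuisance regressors
#'
#' Emulates a physiological-noise-modelling output table: sine/cosine pairs at
#' the supplied frequencies, padded with independent random smooth series
#' (white noise through a Gaussian kernel of 4 volumes). Every column is
#' exactly zero-mean.
#'
#' @param n_volumes Number of time points.
#' @param tr_s Repetition time (seconds).
#' @param physio_frequencies_hz Sinusoid frequencies; must not exceed the
#'   Nyquist frequency `1/(2 tr_s)`.
#' @param n_nuisance Number of columns (default 33).
#' @param seed Integer seed.
#' @return `n_volumes x n_nuisance` matrix.
#' @export
simulate_nuisance_regressors <- function(n_volumes, tr_s = 2,
                                         physio_frequencies_hz = c(0.2, 0.1),
                                         n_nuisance = 33, seed = 1) {
  stopifnot(n_nuisance >= 1, n_volumes >= 3)
  nyq <- 1 / (2 * tr_s)
  if (any(physio_frequencies_hz > nyq + 1e-12))
    stop("physiological frequency above the Nyquist limit of ", nyq, " Hz")
  tt <- (0:(n_volumes - 1)) * tr_s
  cols <- list()
  for (f in physio_frequencies_hz) {
    cols[[length(cols) + 1L]] <- sin(2 * pi * f * tt)
    cols[[length(cols) + 1L]] <- cos(2 * pi * f * tt)
  }
  cols <- cols[seq_len(min(length(cols), n_nuisance))]
  n_rand <- n_nuisance - length(cols)
  if (n_rand > 0) {
    # independent smooth series: white noise through a 4-volume Gaussian
    # kernel (linearly independent, unlike a shared low-order basis)
    K <- gauss_conv_matrix(n_volumes, 4)
    sm <- K %*% with_seed(seed, matrix(rnorm(n_volumes * n_rand),
                                       n_volumes, n_rand))
    for (j in seq_len(n_rand)) cols[[length(cols) + 1L]] <- sm[, j]
  }
  out <- do.call(cbind, cols)
  out <- sweep(out, 2L, colMeans(out))
  colnames(out) <- paste0("nuisance", seq_len(ncol(out)))
  out
}

#' Simulate one subject's BOLD run
#'
#' Forward model per voxel:
#' `baseline + sum_c amplitude_c (boxcar_c * HRF) + drift + AR(1) noise +
#' physio sinusoids`, with the condition amplitudes applied only inside the
#' ROI (outside, task amplitudes are zero). Deterministic given
#' `noise$seed`.
#'
#' @param design A [task_design()]; truncated if longer than the run.
#' @param roi A [roi_mask()] on the simulation grid.
#' @param amplitudes Named vector of condition response amplitudes, e.g.
#'   `c(sad = 1, happy = 0.5, neutral = 0.5)` (signal units).
#' @param noise A [noise_spec()].
#' @param grid_shape Length-3 grid dimensions.
#' @param tr_s Repetition time (default 2 s).
#' @param n_volumes Number of volumes (default 256).
#' @param baseline Mean intensity (default 100).
#' @param hrf An [hrf_spec()].
#' @param subject_id Identifier.
#' @return A [bold_run()].
#' @export
simulate_subject_bold <- function(design, roi,
                                  amplitudes = c(sad = 1, happy = 0.5, neutral = 0.5),
                                  noise = noise_spec(), grid_shape = c(16, 16, 16),
                                  tr_s = 2, n_volumes = 256, baseline = 100,
                                  hrf = hrf_spec(), subject_id = "sub-01") {
  stopifnot(inherits(roi, "roi_mask"))
  if (!identical(dim(roi), as.integer(grid_shape)))
    stop("ROI shape ", paste(dim(roi), collapse = "x"),
         " does not match grid ", paste(grid_shape, collapse = "x"))
  reg <- condition_regressors(design, tr_s, n_volumes, hrf)
  amps <- setNames(numeric(3), colnames(reg))
  amps[names(amplitudes)] <- amplitudes
  task_ts <- drop(reg %*% amps)            # time course inside the ROI
  V <- prod(grid_shape)
  tt_norm <- seq(-1, 1, length.out = n_volumes)
  dat <- with_seed(noise$seed, {
    sig <- matrix(baseline, n_volumes, V)
    sig[, which(roi)] <- sig[, which(roi)] + task_ts
    if (noise$drift_amplitude > 0) {
      c1 <- runif(V, -1, 1) * noise$drift_amplitude
      c2 <- runif(V, -1, 1) * noise$drift_amplitude
      sig <- sig + outer(tt_norm, c1) + outer(tt_norm^2, c2)
    }
    if (length(noise$physio_frequencies_hz) && noise$physio_amplitude > 0) {
      tt <- (0:(n_volumes - 1)) * tr_s
      for (f in noise$physio_frequencies_hz) {
        ph <- runif(V, 0, 2 * pi)
        sig <- sig + noise$physio_amplitude *
          sin(outer(2 * pi * f * tt, ph, `+`))
      }
    }
    if (noise$sigma_white > 0) {
      eps <- matrix(rnorm(n_volumes * V, sd = noise$sigma_white), n_volumes, V)
      if (noise$ar1_rho > 0)
        eps <- apply(eps, 2L, function(e)
          as.numeric(stats::filter(e, noise$ar1_rho, method = "recursive")))
      sig <- sig + eps
    }
    sig
  })
  bold_run(array(t(dat), dim = c(grid_shape, n_volumes)),
           voxel_size_mm = c(3, 3, 3), tr_s = tr_s, subject_id = subject_id)
}

# Default analysis ROI: a central sphere of radius ~1/4 of the grid
# (radius 4 on the default 16^3 grid).
default_roi <- function(grid_shape) {
  make_synthetic_roi(grid_shape, round(grid_shape / 2),
                     max(1, floor(min(grid_shape) / 4)))
}

# HAM-D trajectories constructed so the >=50%-reduction rule reproduces the
# intended labels exactly even after integer rounding.
simulate_hamd <- function(responder, baseline_mean, baseline_sd) {
  n <- length(responder)
  baseline <- round(rnorm(n, baseline_mean, baseline_sd))
  baseline <- pmin(pmax(baseline, 15), 35)
  red <- ifelse(responder, runif(n, 0.5, 0.9), runif(n, 0.05, 0.45))
  week6 <- ifelse(responder,
                  floor(baseline * (1 - red)),    # reduction >= drawn >= 50%
                  ceiling(baseline * (1 - red)))  # reduction <= drawn < 50%
  week6 <- pmin(pmax(week6, 0), 52)
  data.frame(hamd_baseline = baseline, hamd_week6 = week6)
}

#' Simulate a full treatment-response cohort
#'
#' Generates per-subject BOLD runs with a planted responder > nonresponder
#' sad-vs-happy amplitude difference inside the ROI, clinical HAM-D records
#' whose >=50%-reduction rule reproduces the intended labels exactly, and the
#' ROI mask. Subject deviations from the group mean amplitude are centred
#' within group, so the sample mean planted difference equals `effect_delta`
#' exactly.
#'
#' @param n_responders,n_nonresponders Group sizes (defaults 20 and 12).
#' @param effect_delta Planted responder - nonresponder sad-happy amplitude
#'   difference (signal units).
#' @param noise A [noise_spec()]; per-subject seeds are derived from `seed`.
#' @param clinical_params List with `hamd_baseline_mean` (23),
#'   `hamd_baseline_sd` (2), `between_subject_sd` (0.2), `happy_amp` (0.5),
#'   `neutral_amp` (0.5), `base_effect` (0; nonresponder mean sad-happy
#'   amplitude).
#' @param seed Master seed.
#' @param grid_shape,tr_s,n_volumes,design,roi,hrf Forward-model settings;
#'   `roi` defaults to a radius-4 sphere at the grid centre.
#' @return List with `runs` (list of [bold_run()]), `records` (data frame of
#'   subject records incl. `true_effect` ground truth), and `roi`.
#' @export
simulate_cohort <- function(n_responders = 20, n_nonresponders = 12,
                            effect_delta = 1, noise = noise_spec(),
                            clinical_params = list(), seed = 1,
                            grid_shape = c(16, 16, 16), tr_s = 2,
                            n_volumes = 256, design = make_task_schedule(),
                            roi = NULL, hrf = hrf_spec()) {
  stopifnot(n_responders >= 2, n_nonresponders >= 2)
  cp <- utils::modifyList(list(hamd_baseline_mean = 23, hamd_baseline_sd = 2,
                               between_subject_sd = 0.2, happy_amp = 0.5,
                               neutral_amp = 0.5, base_effect = 0),
                          clinical_params)
  if (cp$hamd_baseline_mean <= 0)
    stop("clinical_params$hamd_baseline_mean must be positive: a zero ",
         "baseline cannot realise the response rule")
  roi <- roi %||% default_roi(grid_shape)
  n <- n_responders + n_nonresponders
  responder <- rep(c(TRUE, FALSE), c(n_responders, n_nonresponders))
  rec <- with_seed(seed, {
    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- round(runif(n, 18, 55))
    ham <- simulate_hamd(responder, cp$hamd_baseline_mean, cp$hamd_baseline_sd)
    dev <- rnorm(n, 0, cp$between_subject_sd)
    dev[responder] <- dev[responder] - mean(dev[responder])
    dev[!responder] <- dev[!responder] - mean(dev[!responder])
    true_effect <- cp$base_effect + effect_delta * responder + dev
    data.frame(subject_id = sprintf("sub-%02d", seq_len(n)), sex = sex,
               age_years = age, ham, responder = responder,
               true_effect = true_effect, stringsAsFactors = FALSE)
  })
  stopifnot(identical(classify_response(rec$hamd_baseline, rec$hamd_week6),
                      responder))
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    ni <- noise
    ni$seed <- derive_seed(seed, i)
    amps <- c(sad = cp$happy_amp + rec$true_effect[i],
              happy = cp$happy_amp, neutral = cp$neutral_amp)
    runs[[i]] <- simulate_subject_bold(design, roi, amps, ni, grid_shape,
                                       tr_s, n_volumes, hrf = hrf,
                                       subject_id = rec$subject_id[i])
  }
  list(runs = runs, records = rec, roi = roi)
}

#' Simulate second-level contrast maps directly
#'
#' Generates per-subject sad-happy effect maps without the BOLD forward model:
#' each subject's map is their scalar ROI amplitude (group mean +
#' `effect_delta` for responders, between-subject SD `between_sd`) inside the
#' ROI, plus spatially smoothed Gaussian noise rescaled to per-voxel SD
#' `noise_sd`. Used for group-inference calibration and power studies where
#' the first-level stage is not under test.
#'
#' @param n_responders,n_nonresponders Group sizes.
#' @param effect_delta Planted group difference of the ROI amplitude.
#' @param between_sd Between-subject SD of the ROI amplitude.
#' @param noise_sd Per-voxel SD of the map noise.
#' @param smooth_fwhm_vox Spatial FWHM (voxels) of the map noise.
#' @param grid_shape Grid dimensions.
#' @param roi ROI mask (default: radius-4 sphere at the grid centre).
#' @param seed Integer seed.
#' @return List with `maps` (list of 3D arrays), `labels` (responder
#'   logical), `covariates` (baseline HAM-D draws), `amplitudes` (ground
#'   truth) and `roi`.
#' @export
simulate_effect_maps <- function(n_responders, n_nonresponders, effect_delta = 0,
                                 between_sd = 0.1, noise_sd = 0.1,
                                 smooth_fwhm_vox = 2, grid_shape = c(16, 16, 16),
                                 roi = NULL, seed = 1) {
  roi <- roi %||% default_roi(grid_shape)
  n <- n_responders + n_nonresponders
  labels <- rep(c(TRUE, FALSE), c(n_responders, n_nonresponders))
  sigma_vox <- smooth_fwhm_vox / sqrt(8 * log(2))
  with_seed(seed, {
    amp <- rnorm(n, 0, between_sd) + effect_delta * labels
    covariates <- round(rnorm(n, 23, 2))
    maps <- lapply(seq_len(n), function(i) {
      eps <- array(rnorm(prod(grid_shape)), grid_shape)
      if (smooth_fwhm_vox > 0) {
        eps <- spatial_smooth(eps, fwhm_mm = smooth_fwhm_vox,
                              voxel_size_mm = c(1, 1, 1))
        eps <- eps / sd(as.numeric(eps))
      }
      amp[i] * roi + noise_sd * eps
    })
    list(maps = maps, labels = labels, covariates = covariates,
         amplitudes = amp, roi = roi)
  })
}
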