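---
title: "Methods: predicting SSRI response from pretreatment task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting SSRI response from pretreatment task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmriresp)
```

`fmriresp` implements a complete analysis chain for testing whether
pretreatment anterior-cingulate BOLD responses to masked sad versus happy
faces predict clinical response to six weeks of SSRI treatment. This
vignette is the package's own account of the models it fits, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical decisions taken where the design was open.

## The experiment being modelled

Subjects view blocks of briefly presented, backward-masked emotional
faces: 9 neutral, 4 sad and 4 happy blocks, alternating
neutral–emotion–neutral with the emotions interleaved (sad first or happy
first) and a 10 s fixation cross between consecutive blocks.
`make_task_schedule()` emits exactly this 17-task-block layout; block
duration is not dictated by the stimulus timing (individual face pairs
last 100 ms), so it is a parameter with default 20 s, chosen as a typical
block length that is divisible by the TR. Acquisition defaults are TR = 2 s
and 256 volumes. (A 256-volume, TR = 2 s run lasts 512 s; the generator
takes `n_volumes` and `tr_s` independently and truncates the design to the
run, so both printed acquisition figures are honoured without guessing
which was intended.) Clinical response is a reduction of the 17-item HAM-D
score of at least 50% from baseline at week 6, boundary inclusive
(`classify_response()`).

## First-level model

Each voxel's time series $y$ is regressed on

$$y = X\beta + \varepsilon,\qquad
X = [\,x_\text{sad},\, x_\text{happy},\, x_\text{neutral},\,
     \dot x_\text{sad},\, \dot x_\text{happy},\, \dot x_\text{neutral},\,
     N,\, 1\,]$$

where each task regressor is the condition boxcar convolved with a gamma
HRF, $\dot x$ are temporal derivatives, and $N$ holds nuisance regressors
(33 by default, emulating a physiological-noise-modelling table). Fixation
is the implicit baseline: it spans every inter-block interval, so an
explicit fixation regressor would be collinear with the intercept.

**HRF.** A single gamma density parametrised by its mean (6 s) and SD
(3 s); by moment matching the shape is $k = (6/3)^2 = 4$ and the scale
$\theta = 3^2/6 = 1.5$, giving a mode at $(k-1)\theta = 4.5$ s. No
undershoot term is included: the modelled response is a single gamma.
Convolution runs on a 0.1 s grid — fine enough for sub-second events and
10 s blocks alike — and is then sampled at the TR. The kernel is
normalised to unit sum so a sustained block plateaus at its amplitude,
which is what makes noise-free amplitude recovery exact.

**High-pass filter.** A Gaussian-weighted running-lines filter: at each
time point a weighted linear fit (Gaussian weights of SD $\sigma$ volumes)
is subtracted, and the series mean restored. We set
$\sigma = \text{cutoff}/(4\,\text{TR})$ volumes, i.e. a 30 s weight SD for
the default 120 s cutoff. This choice puts the filter's half-power point
at the cutoff period — the natural reading of a "3 dB cutoff": the
measured transfer ratio is ≈ 0.67 at a 120 s sine, 0.10 at 400 s and
> 0.99 at 20 s. (The wider convention $\sigma = \text{cutoff}/(2\,\text{TR})$
retains about a third of a 400 s drift and attenuates nothing at 3 dB
anywhere near the nominal cutoff, so it does not match the cutoff's stated
meaning.) Task regressors and their derivatives are filtered with the
same operator as the data, as required for unbiased amplitude estimates.

**Smoothing.** Separable Gaussian smoothing with
$\sigma_{mm} = \text{FWHM}/\sqrt{8\ln 2}$ per axis (FWHM 5 mm on 3 mm
voxels ⇒ $\sigma \approx 0.708$ voxels). Edge kernels are renormalised so
constants are preserved.

**Prewhitening.** BOLD noise is temporally autocorrelated; fitting by OLS
and using the nominal residual dof overstates precision. We provide a
single-pass Cochrane–Orcutt AR(1) option (default on): estimate the lag-1
residual autocorrelation per voxel from the OLS fit, clamp to
$[-0.95, 0.95]$, round to 0.01-wide bins (so the quasi-differenced design
is factorised once per bin rather than per voxel), quasi-difference data
and design, drop the first volume, and refit; the residual dof falls by
one. A full regularised autocorrelation model as used by mature fMRI
packages is deliberately out of scope — AR(1) captures the dominant lag-1
structure the generator itself produces, keeping the forward and inverse
models exactly matched for testing.

**Contrast.** The analysis contrast is sad − happy:
$\text{effect} = c^\top\beta$,
$\text{var} = \sigma^2 c^\top (X^\top X)^{-1} c$ per voxel (with the
voxel's prewhitened design block), plus $t = \text{effect}/\sqrt{\text{var}}$.

## Second-level inference

Subject contrast maps are stacked and regressed per voxel on
$[\text{group}, \text{covariates}, 1]$ with the covariates mean-centred;
baseline HAM-D is the standard covariate. The group coefficient's $t$ is
converted to $Z$ through matched tail probabilities (computed on the log
scale for tail accuracy). Inference is one-sided
(responders > nonresponders, the direction of the biomarker hypothesis);
a `two_sided` flag switches to $|Z|$.

**Permutation correction.** Clusters are connected components of
$\{Z > 2.3\}$ under 26-connectivity (the common fMRI convention; 6 and 18
are available). The familywise null is the distribution of the maximum
cluster size under Freedman–Lane permutation: the reduced model
(covariates + intercept) is fitted, its residuals are row-permuted and
added back to the reduced fit, and the full model is refit — this keeps
the covariate structure intact rather than naively permuting labels.
Corrected p-values use the add-one estimator
$(1 + \#\{\text{null max} \ge \text{observed}\})/(n_\text{perm} + 1)$,
which can never return 0. When fewer distinct permutations exist than
requested, all of them are used with a warning. The default is 5000
permutations; the package's own simulation studies use 500, which changes
p granularity but not calibration.

**TFCE.** The threshold-free alternative integrates
$e(h,p)^{E} h^{H}\,\mathrm{d}h$ over the height grid
$h = \mathrm{d}h, 2\mathrm{d}h, \dots \le z(p)$ with $E = 0.5$, $H = 2$;
$\mathrm{d}h$ defaults to $\max(z)/100$ per map. The implementation
processes thresholds from high to low with an incremental union-find, so
each permutation costs $O(\text{steps} \times \text{active voxels})$
rather than a full relabelling per step; it is verified against a
brute-force double loop to $10^{-10}$ on small fixtures (an isolated
voxel of height $z$ approaches $z^3/3$). The familywise-corrected voxel
p-map comes from the max-TFCE permutation null.

**Small-volume correction** restricts both the search space and the
permutation null to a user-supplied ROI mask — the machinery is otherwise
identical, so an ROI equal to the whole grid reproduces the whole-brain
result exactly.

**Parametric branch.** For the ROI analysis a Gaussian-random-field
approximation is also provided: the expected-Euler-characteristic cluster
count with smoothness estimated from voxelwise-standardized second-level
residuals (Gaussian-ACF assumption,
$\text{FWHM} = \sqrt{-2\ln 2/\ln r}$ from the lag-1 spatial correlation
$r$), and the $\exp(-\beta k^{2/3})$ extent tail. This is documented as an
approximation and is cross-checked against the permutation branch in the
tests: on smooth simulated data the two agree within a factor of ~2 for
typical datasets in the mid p range, with occasional few-fold deviations
on small lattices because boundary resel terms are omitted. Permutation
is the reference method; the second-level variance model is OLS
throughout.

## Leave-one-out prediction

For every subject in turn: (1) run the ROI small-volume permutation
analysis on the remaining $n-1$ subjects and take the largest significant
responder > nonresponder cluster; if none is significant fall back to the
largest suprathreshold cluster, and failing that to the whole ROI (the
loop must always classify; every fallback is recorded per fold); (2)
extract mean cluster activity for all subjects; (3) build the training
ROC (predict responder when score ≥ threshold, thresholds at the attained
scores) and choose the cut-off maximising $TPR - FPR$ — the operating
point furthest from the leading diagonal, since the perpendicular
distance is $(TPR-FPR)/\sqrt2$ — breaking ties toward the higher, more
conservative threshold; (4) classify the held-out subject by
score ≥ cut-off, with boundary equality counting as a responder call. The
classification direction (higher activity ⇒ responder) is fixed a priori,
not learned per fold. By construction the held-out map never influences
its own cluster or cut-off; the tests verify this by mangling the
held-out map and checking the fold is unchanged.

Fold results aggregate into a confusion matrix (positive = responder),
accuracy, and an exact two-sided binomial test against 0.5 computed as
the doubled smaller tail capped at 1 (e.g. 23/32 correct gives
p ≈ 0.020; the one-sided value would be ≈ 0.010).

## The synthetic cohort generator

The generator emulates exactly the statistical structure the estimator
assumes: voxel time series are baseline + amplitude-weighted convolved
boxcars (inside the ROI only) + per-voxel linear/quadratic drift + AR(1)
Gaussian noise + fixed-frequency sinusoids, with HAM-D trajectories
constructed so the ≥50% rule reproduces the intended responder labels
exactly even after integer rounding (responders' week-6 scores are
floored, nonresponders' ceilinged). Subject deviations from the group
mean amplitude are centred within group so the sample mean planted
difference equals `effect_delta` exactly, which is what the generator's
bookkeeping tests check. Default group sizes are 20 responders and 12
nonresponders. Pseudo-physiological sinusoid frequencies default to 0.2
and 0.1 Hz — aliased surrogates of respiratory and cardiac rhythms that
remain representable below the 0.25 Hz Nyquist limit of TR = 2 s; true
cardiac rates are not representable at this TR and real
pulse-oximetry processing is out of scope. The neutral condition defaults
to a nonzero amplitude shared by groups so its regressor is
non-degenerate.

For group-level studies where the first-level stage is not under test,
`simulate_effect_maps()` draws subject contrast maps directly: a scalar
ROI amplitude (between-subject SD 0.1 by default) plus spatially smoothed
Gaussian map noise (per-voxel SD 0.1, FWHM 2 voxels). A "5× between-subject
SD" planted effect therefore means
$\delta = 5\sqrt{0.1^2 + 0.1^2} \approx 0.71$.

What the generator does **not** emulate: head motion, susceptibility and
slice-timing artefacts, k-space physics, spatially varying autocorrelation,
non-Gaussian noise, anatomical variability or registration error. Passing
tests therefore demonstrate correctness of the estimator under its own
assumptions — calibration, recovery, leakage-freedom — not robustness to
everything real scanner data contains.

## Numerical choices and degenerate inputs

* All generators are pure functions of their arguments including the
  seed; the RNG state is saved and restored around every draw, and
  per-subject / per-fold seeds are derived from the master seed.
* TFCE heights include a $10^{-9}$ tolerance so values lying exactly on
  the discrete grid are counted; the brute-force oracle uses the same
  convention.
* Rank-deficient designs, all-zero task columns, empty ROIs and clusters,
  single-class training folds, zero HAM-D baselines, frequencies above
  Nyquist, overlapping event rows and shape mismatches are all rejected
  with named errors rather than propagating NaNs. An identically-zero
  covariate column is dropped (it carries no information), whereas a
  constant nonzero covariate is an error because it is collinear with the
  intercept.
* Chi-square tests are uncorrected by default: the conventional report
  for a 2×2 sex table (10F/10M vs 8F/4M ⇒ $\chi^2 = 0.847$) is the
  uncorrected Pearson statistic; a Yates flag is available. The
  demographic table's t statistics are reported with a pooled-variance
  default and a Welch option; published per-row t values for such tables
  are not always reconstructible from printed mean ± SE columns, so these
  are verified against closed forms rather than against any printed
  table.
* The LOO per-fold cluster uses the **largest** significant cluster; a
  `union_significant` option takes the union of all significant clusters
  instead.

## Problem sizes used by the package's studies

The simulation studies in the test suite and acceptance script use sizes
chosen to make the Monte-Carlo error small relative to the tolerance
being checked: familywise-error calibration over 200 null cohorts
(16³ grid, 10 subjects per group, 500 permutations, search space the
257-voxel spherical ROI of the default-scale cohort); planted-effect
recovery over 20 replicate 20 + 12 cohorts; chance-level control over 50
replicates. At nominal 5% and 200 datasets the binomial SE of the
observed familywise rate is ≈ 1.5%, matching the ±2% acceptance band.

## Known limitations

* The AR(1) prewhitener is a deliberate simplification of full
  autocorrelation modelling; residual long-memory structure in real data
  would leave some variance misestimated.
* The GRF branch omits boundary corrections and is approximate on small
  search regions — use the permutation branch for inference.
* Leave-one-out estimates of classifier accuracy are optimistic relative
  to fully held-out validation; the package reproduces the published
  validation scheme and inherits that property.
* Voxel coordinates are reported 0-based in voxel space; world-space
  affines are carried through NIfTI headers but never computed from
  atlases, and ROI masks are always user inputs (or synthetic spheres).
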