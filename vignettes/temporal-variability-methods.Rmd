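---
title: "Temporal variability of dynamic functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal variability of dynamic functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcvar)
```

## The measure

Resting-state functional connectivity (FC) between two brain regions is the
Pearson correlation of their BOLD time courses. Static FC assumes this
coupling is constant over a scan; dynamic FC asks how it fluctuates. The
statistic at the centre of this package quantifies that fluctuation. The
time courses are segmented into sliding windows of $L$ TRs advanced by one
TR, the windowed correlation $r_k$ is computed in each of the $m$ windows,
and the **FC temporal variability** is the mean squared successive
difference

$$ I = \frac{1}{m-1} \sum_{k=2}^{m} (r_k - r_{k-1})^2 . $$

$I$ is zero when coupling is perfectly stable, is bounded by 4 (each jump
of $r_k$ is at most 2), and is computed on raw correlations — no Fisher
transform, because squared *differences* of nearby correlations are already
approximately variance-stabilised and the definition above is the one the
downstream group statistics expect. High $I$ means unstable coupling.

Defaults follow the standard acquisition this pipeline targets: TR = 2 s,
255 volumes of which the first 5 are discarded (a 510 s scan), band-pass
0.01–0.08 Hz, and windows of $L = \lceil (1/f_{\min})/\mathrm{TR} \rceil =
50$ TRs so that a window spans at least one full cycle of the slowest
retained frequency ($f_{\min}=0.01$ Hz); 250 analyzed volumes then give
$m = 201$ windows. Windows are rectangular (untapered) — the statistic is
defined on plain windowed correlations — and successive differences are
taken at window-index step 1, i.e. on maximally overlapping windows.

Seeds are defined by an MNI coordinate; a seed time course averages the
seed voxel with its six face-adjacent neighbours (6-connectivity is the
natural reading of "nearest six neighbours" on a 3 mm grid). Neighbours
outside the brain mask are dropped rather than zero-filled so edge seeds
stay unbiased. Real-valued coordinates snap to the nearest voxel centre
with ties rounded away from zero, which is deterministic across platforms.

Degenerate windows (zero variance in either series) raise an error in the
ROI-wise path and mask out the voxel in the map path; silently imputing
$r_k = 0$ would bias $I$ downward. Voxel-wise maps stream over fixed-size
voxel blocks so memory stays bounded; block boundaries provably do not
change results (this is tested bit-for-bit).

## Preprocessing

The pipeline consumes spatially preprocessed volumes and applies only the
temporal steps:

* **Band-pass 0.01–0.08 Hz.** Implemented as an ideal frequency-domain
  filter: demean, Fourier transform, zero all bins outside the band,
  invert. This is the filter style of the common resting-state toolboxes;
  it is exactly zero-phase and idempotent, and its frequency response is a
  sharp indicator function of the band, which makes its behaviour on pure
  tones exactly checkable. (A causal IIR filter run forward–backward is
  zero-phase too, but it is *not* idempotent — re-filtering removes several
  percent of pass-band energy near the edges — so the ideal filter is the
  one whose contract the tests can state cleanly.)
* **Nuisance regression.** Least-squares residualisation of each series on
  an intercept, white-matter and CSF means, a linear trend and 12 motion
  parameters (6 rigid-body parameters and their backward-difference
  derivatives, first row zero). The global mean signal is deliberately
  never included: global-signal regression distorts between-group
  comparisons in clinical populations. Filtering precedes regression,
  matching the order in which these steps are conventionally listed, even
  though the two operations do not commute exactly.
* **Motion QC.** A scan is excluded when the maximum absolute translation
  exceeds 3.0 mm on any axis or the maximum rotation exceeds 3.0°
  (evaluated on raw parameters relative to the reference volume, the
  conservative reading). Framewise displacement uses the Power convention,
  $FD_t = \sum|\Delta d| + 50\,\mathrm{mm}\cdot\sum|\Delta\theta|$, and is
  reported but not used for censoring.

## Group inference

The study design is two patient groups — treated (`TSZ`, stimulation plus
medication) and medication-only (`DSZ`) — measured at baseline (`t1`) and
follow-up (`t2`), plus a baseline-only healthy reference (`HC`). The
group × time interaction is the scientific target: did treatment change the
variability differently from medication alone?

With exactly two timepoints, the repeated-measures ANCOVA interaction is
algebraically the group effect in the change-score model
$\Delta = y_{t2} - y_{t1} \sim \text{group} + \text{covariates}$
(age, sex coded 0/1, illness duration, education, antipsychotic dose —
all between-subject, entered untransformed). `rm_ancova_interaction`
therefore fits that GLM and reports the partial F for group; this is fully
specifiable, exact, and testable against hand-computed projections.
Covariates can be dropped (`covariates = NULL`) for the unadjusted
repeated-measures ANOVA variant.

Post-hoc tests report the paired t of **t1 versus t2** (so a *decrease* at
follow-up yields a *positive* t — the sign convention in which treatment
effects on variability are conventionally tabulated), two-sample t-tests
between groups at each timepoint, and comparisons against the healthy
reference. ROI-pair scans use uncorrected p < 0.005 with no correction
across pairs, mirroring the thresholding convention of the seed-based
literature this follows; all tests are two-sided.

### Cluster-extent correction

Voxel-wise statistic maps are corrected with Gaussian random-field theory:
(1) smoothness (FWHM) is estimated from the spatial derivatives of
voxel-standardised residual images, with the discrete-lattice correction
$\mathrm{FWHM} = \sqrt{-2\ln 2/\ln(1-\lambda/2)}$ where $\lambda$ is the
mean squared adjacent-voxel difference; estimates below one voxel are
clamped with a warning; (2) RESEL counts $R_0..R_3$ come from the Worsley
lattice counts of the mask (voxels, edges, faces, cubes), so boundary
contributions are included rather than assuming a large compact volume;
(3) the map is converted to z-equivalents and thresholded at the z for the
height p (0.005 default); (4) 26-connected clusters are labelled; (5) each
cluster's family-wise p follows the exponential cluster-size
approximation, $P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = (\Gamma(5/2)\,E[m]/E[N])^{2/3}$ and
$P_{\mathrm{FWE}} = 1 - \exp(-E[m]\,P(n \ge k))$, where $E[m]$ is the
expected Euler characteristic $\sum_d R_d \rho_d(u)$. A Monte-Carlo/
permutation extent threshold (`permutation_extent_threshold`) is provided
as the nonparametric cross-check; on simulated 8 mm-FWHM null fields the
two agree to within a few voxels and the family-wise false-positive rate
stays at or below nominal (the acceptance suite runs this calibration).
An optional hard minimum extent is exposed for the "volume > 600 mm³"
convention (600 mm³ at 3 mm isotropic is 22.2 voxels, so the ceiling rule
gives 23).

### Clinical linkage

Symptom change is summarised by the remission ratio
$RR = (s_{t1} - s_{t2})/s_{t1}$ per PANSS subscale (positive = improvement)
and variability change by $(I_{t2} - I_{t1})/I_{t1}$ (negative =
stabilisation). Both are scale-invariant. Brain–behaviour association uses
a partial Spearman correlation: ranks of both variables are residualised
on the (unranked) covariates and the residual Pearson correlation is
tested on $n - k - 2$ degrees of freedom; ranking first makes the test
robust to the non-normality remission ratios typically show.

The variability–connectivity coupling check correlates, across region
pairs, group-mean $I$ against group-mean windowed FC. Strongly coupled
pairs fluctuate less — the expected direction is negative, and the
synthetic model reproduces it (below).

## Treatment-response prediction

`loocv_grid_svr` predicts each subject's remission ratio from baseline
variability features with epsilon-SVR (RBF kernel; both C and the kernel
width gamma are grid-searched, which is what implies the RBF choice).
For every grid point the *entire* leave-one-out loop is run: features are
z-scored with training-fold statistics only, the held-out subject is
predicted by a model that never saw them, and the grid point with the
lowest LOOCV mean squared error wins (ties prefer the smallest C, then the
smallest gamma — smoother models). Performance is the Pearson correlation
between held-out predictions and actual values with its t-based p.

Numerical choices:

* `epsilon = 0.01` by default. The insensitivity tube must be small
  relative to the target spread; remission ratios vary on a scale of
  0.05–0.15, and a tube of 0.1 can contain the entire target range, in
  which case the SVR solution is a flat function with no support vectors.
  Should that still happen at some grid point, the implementation predicts
  the training mean (the flat fit's value) rather than erroring.
* Targets are left unscaled; outliers beyond 2 sample SDs of the target
  (mean and SD computed once, single pass) are excluded before fitting,
  with a flag to disable exclusion.
* Feature selection (which region pairs enter) happens *outside* the CV
  loop, replicating the practice of selecting pairs by the group-level
  paired test before prediction. This is optimistic — the selection has
  seen both timepoints of everyone — and single-loop LOOCV error is itself
  an optimistic estimate of generalisation; both caveats apply equally to
  the study designs this mirrors and are inherited knowingly.

## The synthetic cohort generator

No patient data ship with the package; every downstream stage is instead
validated on synthetic cohorts with planted ground truth.

**Signal model.** Each scan is drawn from a hidden two-state covariance
model: at every TR a multivariate normal sample with the active state's
covariance, plus white noise (`noise_sd = 0.3`), band-pass filtered to
0.01–0.08 Hz and standardised per region. Twelve regions are organised in
disjoint pairs: three *responsive* pairs whose correlation switches
between −0.9 and +0.9 with the hidden state, two *static* pairs fixed at
0.5, and two independent regions. The disjoint-pair structure keeps every
state covariance positive definite by construction.

The symmetric ±0.9 states are a deliberate choice: for a bivariate normal
the sampling variance of a windowed correlation depends on the correlation
through $\mathrm{Var}(xy) = 1+\rho^2$, which is equal in the two states,
so the temporal variability of a responsive pair is governed by the
*switching rate* and not by a change in marginal noise. They also give
responsive pairs near-zero mean FC while static pairs combine high FC with
low variability — which is exactly the negative variability–FC coupling
the coupling check expects to find.

**State process.** The cohort generator alternates states in fixed blocks
(`regular_state_sequence`): dwell time $1/p$ TRs, random initial state and
phase. A Markov chain of the same rate is available
(`state_process = "markov"`, and `sample_state_sequence` is exported), but
with 250 volumes and 50-TR windows a scan contains only about five
independent window spans, so Poisson variability in the Markov flip count
gives the per-scan $I$ a coefficient of variation of 25–45% and caps
per-pair effect sizes near $d \approx 0.5$ — too noisy for any fixed
sample size near the study's to recover reliably. Regular dwells make the
planted variability level tightly rate-controlled (effect sizes around 3)
while keeping the identical covariance-switching mechanism. The baseline
dwell is 60 TRs, just above the window length: switching much faster than
the window is averaged away inside windows (the rate–variability curve
turns over near dwell ≈ L), so the generator operates on the
monotone-decreasing branch where slower switching means lower $I$.

**Design and treatment effect.** Defaults: `n_per_group = 20`, `T = 250`,
TR 2 s, groups TSZ/DSZ/HC (HC baseline only). Each subject carries a
baseline switch-rate multiplier $b_s \sim N(0.9, 0.2)$ clipped to
[0.4, 1.2]. Treated subjects at follow-up switch at a rate reduced by the
planted drop $d_s = (1-\delta)\,b_s$ (clipped to [0, 0.95]) with
`effect_delta` $\delta = 0.3$; untreated and healthy subjects keep their
baseline rate. Setting $\delta = 1$ plants exactly nothing — the null
cohort is clean. Because $d_s$ grows with $b_s$, subjects with higher
baseline variability respond more, so baseline features are predictive of
response *by construction* — the property the prediction module's
validation needs, and a clinically plausible one.

**Clinical scores.** PANSS-like subscales are drawn at baseline from
distributions matched to a chronic-schizophrenia inpatient profile
(negative ≈ 23.5 ± 5.5 clipped to the instrument ranges, positive ≈ 11.7,
general ≈ 30) and integer-rounded. The treated group's negative-subscale
remission ratio is linked linearly to the planted drop,
$RR = 0.4\,d_s + N(0, 0.04)$ (treated mean RR ≈ 0.25, matching the scale
of reported treated-group improvements); untreated subjects improve by
≈ 0.07 on average with the same noise. Positive/general subscales improve
without any link to the planted drop, so only the negative subscale should
be predictable — the selectivity the prediction tests check. The synthetic
remission-ratio scatter (≈ 0.07) is tighter than real cohorts show
(≈ 0.14); the generator trades realism here for a link strong enough to
validate recovery at the design's sample size.

**Motion.** Smoothed random-walk traces rescaled to stay within QC bounds
(0.2–1.2 mm, 0.1–0.9°), except for a configurable fraction of subjects
planted to violate the 3 mm rule at baseline.

**What the generator does not emulate.** Hemodynamic convolution,
physiological (cardiac/respiratory) noise, scanner drift, spatial
autocorrelation of real volumes (the volume embedding places region
blocks in background noise), inter-regional anatomy, and realistic
between-subject covariate structure (covariates are independent of the
planted effect, so covariate adjustment is exercised but not stressed).
Passing tests therefore demonstrate that the *pipeline machinery* recovers
what was planted under its stated assumptions — not that real acquisitions
satisfy those assumptions.

## Problem sizes used in validation

The test-suite and acceptance-script problem sizes are chosen to make
Monte-Carlo error small relative to each margin while keeping a full run
on one CPU comfortable: 20 seeded default cohorts for effect recovery
(the acceptance script uses 10), 1000 smooth null fields (script: 500)
of 20³ voxels at 8 mm FWHM for cluster calibration, 1000 univariate null
replicates for interaction-test size, 50 single-group cohorts for the
coupling direction, and 50 treated-group cohorts (script: 25) for the
prediction link, with a reduced SVR grid (C ∈ {1, 100, 1000},
γ ∈ {0.01, 0.1}) in the repeated-replicate loops.

## Reproducibility

Everything that draws random numbers takes a seed; cohort generation
derives per-subject, per-stage substream seeds deterministically from the
master seed, so subsets of a cohort are individually reproducible.
`run_pipeline` validates its configuration (including the window-length
rule $L \ge \lceil (1/f_{\min})/\mathrm{TR}\rceil$) before touching data,
executes stages in a fixed order, and writes a manifest with MD5 checksums
of every output — identical configuration and seed give identical
checksums.

## Known limitations

* The two-timepoint change-score formulation is exact for this design but
  does not generalise to more timepoints; a mixed model would.
* GRF cluster p-values are asymptotic in smoothness; at FWHM below ~2
  voxels the expected-cluster-size approximation degrades (the permutation
  threshold is the fallback).
* The SVR pipeline reproduces, rather than repairs, the optimism of
  out-of-loop feature selection and single-loop LOOCV.
* Baseline group differences (treated vs untreated before treatment) are
  neither planted nor modelled.
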