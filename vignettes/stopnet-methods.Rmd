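---
title: "Models and methods behind stopnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stopnet` couples a generative model of stop-signal task behavior and
BOLD-like imaging data to the full analysis chain used to relate stopping
efficiency to brain activity and connectivity across the adult life span.
This vignette records the models, the parameters that matter, the numerical
choices, and the design decisions taken where more than one reasonable
implementation existed. Everything quantitative stated here is computed by
the package's test suite or acceptance script, not asserted from memory.

## The behavioral model

Behavior follows the independent-race account of stopping: on every trial a
go process and (on Stop trials) a stop process race, and a response is
emitted iff the go finishing time is smaller than the stop-signal delay
(SSD) plus the stop finishing time. Go finishing times are ex-Gaussian
(`go_rt_mu = 400` ms, `go_rt_sigma = 50` ms, `go_rt_tau = 100` ms, giving a
mean Go RT of 500 ms — typical adult values); stop finishing times are
normal truncated at zero (`ssrt_mu = 200` ms, `ssrt_sigma = 30` ms).
Omission (2%) and wrong-direction (2%) rates are separate Bernoulli
processes, and a trigger-failure probability (default 0) lets the stop
process fail to start. No-Go trials are treated as Stop trials with SSD
fixed at 0, so action restraint and action cancellation share one
mechanism.

The SSD staircase is one-up/one-down with 50-ms steps: SSD increases after
every successful stop and decreases after every response on a Stop trial,
clamped to [0, 900] ms with an initial value of 250 ms. The direction
convention and bounds are our choices (standard 1-up/1-down tracking
converges on 50% response cancellation; initial value and bounds sit well
inside the trial). The default design has 360 Go, 80 Stop, and 40 No-Go
trials (70/20/10%) split evenly over two runs at a 2.5-s stimulus-onset
asynchrony and a 2-s TR, which reproduces the roughly ten-minute,
~315-volume scale of a typical two-run acquisition.

## SSRT by block-based integration

SSRT is estimated per block of 30 Stop-Signal trials. Three conventions are
not fully pinned down by the usual description of the method and are made
explicit (and configurable) here:

* **Rank convention.** The critical Go RT is the `n`-th ranked Go RT with
  `n = max(1, round(p * N))` using round-half-up, where `p` is the block's
  premature-response-corrected p(respond|signal) and `N` the number of Go
  RTs after omission correction.
* **Omission correction.** Go omissions enter the ranked distribution at
  the block's maximum Go RT — the standard conservative correction; only
  the correction's existence, not its formula, is conventionally reported.
* **Remainder rule.** With 80 Stop trials and 30 per block, the package
  forms two full blocks and a final 20-stop block; a trailing remainder
  below 15 Stop trials is folded into the preceding block instead of
  standing alone. This uses all data while keeping every block estimable.

Premature responses (RT < SSD: the stop signal had not yet appeared) are
removed from both numerator and denominator of p(respond|signal) and
excluded from the block's mean SSD. Subjects with more than 10 premature
Stop responses are excluded (fewer than 70 usable Stop trials, under the
recommended minimum for the method), as are subjects whose mean
volume-to-volume head displacement lies 3.5 SD or more above the cohort
mean after an OLS regression of displacement on age (residual SD computed
on the same sample). Displacement uses the rigid-body formula
`sqrt(R^2/5 * tr(A'A) + t't)` over a solid sphere of radius 80 mm
(configurable; the radius is a modeling convention, and the tests verify
the formula against a Monte-Carlo rigid-transform oracle).

Under the staircase, the integration estimator carries a small negative
bias (the test suite measures roughly 8–10 ms at the default parameters —
a known property of the integration method under tracked SSDs and skewed
RT distributions, not a code defect); the estimator-consistency test
verifies that the bias shrinks as trial counts grow.

## The BOLD forward model

Each subject's data live on a small 3-D lattice (default 12 x 12 x 10 =
1440 voxels) carrying `n_components = 5` Gaussian-blob spatial maps with
unit L2 norm and rejection-sampled centers that keep blobs apart. Component
time courses are the sum of:

* **Evoked responses**: outcome-category onsets (what the subject actually
  did, not the nominal trial type) convolved with a double-gamma HRF
  (response peak 6 s, undershoot 16 s, peak/undershoot ratio 6, 32-s
  support), scaled by per-component, per-condition amplitudes. The HRF
  kernel is normalized to unit peak so amplitudes are expressed in units of
  the fluctuation SD; the default amplitude pattern gives two components
  higher responses on unsuccessful stops, two on successful stops, and one
  condition-indifferent component.
* **Coupled fluctuations**: per-volume Gaussian vectors with correlation
  `I + B` outside stop epochs and `I + B ± M/2` inside
  successful/unsuccessful stop epochs (`B` = base coupling, `M` = coupling
  modulation; positive-definiteness of all three matrices is checked at
  construction). An AR(1) filter (`ar_coef = 0.55` at the 2-s TR) with
  variance-preserving innovations gives the fluctuations the
  low-frequency-dominated spectrum of spontaneous BOLD while leaving
  lag-zero cross-correlations — the quantities that define coupling — at
  their configured values.
* **Epochs**: a window of `epoch_window_s = 4` s starting at each
  Stop-Signal onset, +1 after successful stops, −1 after responded stops,
  clamped where windows overlap. When, within a trial, connectivity
  modulation arises is genuinely unknown (it may accompany the stopping
  process itself or follow it); the window is an explicit free parameter,
  not a claim about physiology. The AR smoothing bleeds some modulation
  across epoch edges, so the realized epoch-wise correlation contrast is
  attenuated relative to `M` (the tests assert the direction and a
  conservative magnitude).

Voxel data are `maps' x time courses` plus a motion nuisance (the six
realignment parameters, z-scored, projected through a fixed random voxel
pattern with gain 0.5) plus i.i.d. voxel noise (SD 1). Head motion itself
is a six-parameter random walk whose step scale grows with age (0.0015
mm/year above age 18), reproducing a positive cohort-level motion-age
correlation. The generator does **not** emulate vascular or physiological
noise structure, slice-timing effects, spatial autocorrelation of the voxel
noise, nonlinear BOLD saturation, or susceptibility artifacts — so green
tests certify the statistical machinery, not robustness to every artifact
of real acquisitions.

## Cohorts and injected ground truth

Ages are uniform on [18, 88]. Per-subject parameters deviate from the group
ground truth by linear age slopes (Go RT +1.0 ms/year, SSRT +0.8 ms/year,
coupling-modulation scale −0.008/year — weakened modulation with age) plus
subject noise. Two standard-normal subject deviations carry the injected
brain-behavior structure: an activity deviation scaling the responsivity
pattern, and a modulation deviation scaling the coupling-modulation matrix.
True SSRT is `200 + 0.8*(age−53) − 30*act_dev + (−25 +
moderation_per_year*(age−53))*mod_dev + N(0,15)` ms: activity and
connectivity contribute independently, and a nonzero `moderation_per_year`
makes the connectivity link age-dependent — the dissociation the analysis
chain is meant to recover. Demographic covariates (gender, handedness,
education) are generated without injected effects, as covariates of no
interest.

`simulate_measured_features()` produces the subject-by-feature tables the
full pipeline would measure from voxel data, directly from the subject
ground truths plus measurement noise (SD 0.1). It exists because the power
and calibration studies need hundreds of cohorts of 120–300 subjects, where
voxel-level simulation of every subject would dominate runtime without
changing what is being tested; the end-to-end pipeline test covers the
voxel-level path once at a 14-subject scale.

## Decomposition

Model order is selected by classical MDL on sample-covariance eigenvalues
(`-N(p-k) log(GM/AM of trailing eigenvalues) + k(2p-k+1)/2 log N`), with
the matrix transposed so that the larger dimension is the sample dimension
and an optional effective-sample-size factor (default 1). Classical MDL
assumes N >> p; at the package's desk scale (per-subject data of ~634 time
points by 1440 voxels, p/N ≈ 0.44) the noise eigenvalues spread over the
Marchenko-Pastur bulk, so order selection is only reliable when the
component fluctuations stand well clear of the bulk edge. The
decomposition validation fixture therefore uses strong sources
(fluctuation SD 2.5, voxel noise 0.5, motion gain 0) — the "strong sources,
small noise" regime in which the MDL consistency claim is meaningful — and
order selection is run per subject with the median taken across subjects.

Group ICA concatenates subjects in time, removes voxel means, PCA-whitens
to `k` dimensions, and runs symmetric fixed-point ICA (tanh contrast,
tolerance 1e-6 on the diagonal of `W_new W'`, at most 200 iterations) from
`n_runs` random orthonormal initializations. Non-converged runs are
dropped with a warning; if all fail, an error is raised. Components from
all runs are clustered by average-linkage agglomerative clustering on
`1 − |spatial correlation|`; each cluster's centrotype (the member most
similar to the rest of its cluster) becomes a group component and the
stability index is mean intra-cluster minus mean extra-cluster similarity.
Signs follow positive map skewness, with the sign of the
largest-magnitude voxel breaking exact ties; maps and time courses are
z-scored; components are ordered by decreasing stability. Subject time
courses come from spatial regression of (voxel-centered) subject data onto
the group maps. Matching between decompositions maximizes summed absolute
correlations — exhaustively for up to 8 components, greedily beyond (all
shipped fixtures use k ≤ 8, where the greedy path is never taken).

A component is physiological/scanner noise when the ratio of spectral
power above to below `freq_cut_hz = 0.1` Hz on its group time course
exceeds 0.9, or when its map matches a designated non-neuronal reference
map better than any signal reference. The 0.9 ratio is conventional; the
0.1-Hz boundary is our explicit configuration choice (the convention's
frequency boundary is not standardized), chosen because task-evoked and
spontaneous BOLD power concentrates below 0.1 Hz while the flat part of
the spectrum lies above it. The AR(1) fluctuation model is what makes this
classification meaningful: temporally white fluctuations would place the
majority of their power above any such boundary and classify every true
component as noise.

Split-half validation reruns the decomposition within each half of a
cohort, matches components to the full-sample decomposition, and
summarizes spatial similarity, between-subject ICC (correlation of each
component's concatenated subject time courses between decompositions), and
within-subject ICC (correlation of each subject's vectorized
component-connectivity profile). All correlations are Fisher-z transformed
before averaging or testing; spatial similarities are compared across
halves by ANOVA controlling for component, between-subject ICCs by
Kruskal-Wallis, within-subject ICCs by one-way ANOVA.

## Activity

Design matrices are built per session from behavioral outcomes: up to nine
HRF-convolved delta-function regressors (correct Go, correct No-Go,
successful stop, unsuccessful stop, Go commission, Go omission, No-Go
commission, early stop response, wrong-direction stop response), the six
realignment parameters, a discrete-cosine high-pass basis spanning periods
of 128 s and longer, and an intercept. Events are modeled with zero
duration (delta functions); categories with zero events are omitted and
recorded. Component GLMs are ordinary least squares with an explicit
rank check that names collinear columns. The responsivity index is the
SuccStop − UnsuccStop beta contrast averaged over sessions (single-session
values are flagged). Group inference is a per-component one-sample t test
with Benjamini-Hochberg correction at FDR 0.01; age effects use iteratively
reweighted least squares with Huber's psi (tuning constant 1.345, at most
50 iterations) in the orientation with age as the dependent variable, the
brain measure plus covariates as predictors, BH-corrected at FDR 0.05, with
the equivalent partial correlation reported for interpretability. The
group level is deliberately more conservative than the age level because a
mean-difference test and a continuous-association test differ in kind.

## Connectivity

Context-independent (spontaneous) connectivity between components i and j
is the coefficient of `TC_j` in the regression of `TC_i` on `TC_j` plus the
full design matrix (task, motion, drift, intercept) — association that
survives removal of everything task-locked. Group tests Fisher-z transform
the per-subject values; sessions are computed separately and averaged.

Context-dependent connectivity required a genuine design decision. The
correlational-PPI construction — correlate the two interaction terms
`TC_i x psych` and `TC_j x psych` after residualizing each against
{TC_i, TC_j, task, confounds} — has the property that under **constant**
coupling rho its expectation is rho itself, re-weighted by `psych^2`: for
jointly Gaussian series with deterministic psych, `cor(s*x, s*y) = rho`
regardless of whether coupling changes between conditions, and
residualizing against x and y removes nothing (the interaction terms are
uncorrelated with them). A test in the suite demonstrates exactly this
inheritance. Because the scientific quantity of interest is the *change*
in coupling across conditions — and because the package's discriminant
validation requires a null-calibrated estimator — the default `cppi()`
uses the symmetrized PPI partial correlation,
`[pcor(s*TC_i, TC_j | TC_i, Psi, C) + pcor(s*TC_j, TC_i | TC_j, Psi, C)]/2`,
whose expectation is zero under constant coupling and which tracks the
signed coupling change when it exists. The interaction-term construction
remains available as `method = "interaction"` for comparability with the
correlational-PPI literature (where, notably, context-dependent patterns
are often reported to resemble context-independent ones — the behavior this
analysis predicts).

The psychological contrast is +1/−1 coded at SuccStop/UnsuccStop events,
mean-centered, and HRF-convolved by default; `hrf = FALSE` gives the raw
boxcar coding with a configurable event duration. Validation simulations
use the boxcar with duration equal to the generator's epoch window, the
statistically matched detector for modulation expressed at the BOLD level
in onset-locked windows; the HRF-convolved term is the right choice when
modulation is expressed neuronally and hemodynamically delayed. Per-series
inference (`cppi_inference()`) is the t test on the PPI interaction
coefficient in the directional regression, with AR(1) prewhitening: the
lag-one residual autocorrelation is estimated from an initial OLS pass and
removed by quasi-differencing, as in standard task-fMRI GLMs. Without
prewhitening the AR(1) fluctuations make the test anticonservative; the
calibration test verifies the false-positive rate against the binomial
interval at alpha = 0.05 under strong base coupling. Near-singular
nuisance matrices fall back to ridge residualization (lambda = 1e-8) with
a warning; degenerate (zero-variance) residual series yield NA with a
warning.

## Prediction and moderation

`shrinkage_mlr_fit()` replaces the sample covariance S of the predictors by
`(1−γ) S + γ ν I` with ν the mean eigenvalue and γ the analytic
well-conditioned intensity `min(b², d²)/d²`, where `d² = ||S − νI||²_F`
and `b²` is the average squared Frobenius distance of per-observation outer
products from S over n². γ = 0 reproduces OLS exactly; p > n stays finite.
The covariance-shrinkage reading of "well-conditioned shrinkage
regression" is implemented (the alternative — shrinking regression
coefficients directly — is a different estimator); the test suite verifies
the intensity against an independent direct-formula oracle and weight
recovery in the n >> p regime.

The three-stage procedure: (1) fit the shrinkage regression on each
training set of a seeded k-fold partition; (2) apply training weights to
the held-out fold to produce subject scores; (3) correlate assembled
held-out scores with the observed response. Covariates of no interest are
residualized out of the response and each feature column using parameters
estimated on the training fold only and applied to the test fold — the
covariate analogue of the no-leakage rule (a dedicated test asserts that
held-out scores are bit-identical under perturbations of held-out
responses). Permutation p-values permute the response (covariate rows move
with it), re-draw the fold partition per permutation (configurable), and
use the add-one estimator `(1 + #{r_perm >= r_obs})/(B + 1)`. Repartition
distributions repeat the CV under independent partitions.

Model comparison uses the mean difference of repartition r values against
the null distribution of the same statistic computed on jointly permuted
responses, with a **one-sided exceedance** p-value. One-sided is essential:
the null distribution absorbs the complexity difference between models (a
more complex model's cross-validated r is more negative under permuted
responses), so the null mean difference is generally nonzero and a
two-sided band around zero would be miscalibrated. Feature sets entering
the models follow the significance-mask entry rule: components and
connections with a reliable group effect (FDR 0.01) form the activity and
connectivity feature sets, and the joint model concatenates them.

The moderation model is `y ~ scores + age + scores:age + covariates` with
scores and age mean-centered before the interaction is formed; partial
correlations are `t/sqrt(t² + df)`. One subtlety the dissociation test
documents: in a cohort where a true connectivity-by-age interaction is
injected, the *activity*-score moderation model omits that term, its
residuals become heteroscedastic in age, and the activity interaction's
type-I error inflates somewhat above alpha. The calibration claim for the
activity arm is therefore checked in a cohort with no moderation injected
anywhere, while the injected arm checks detection power and the
activity/connectivity asymmetry.

## Problem sizes and runtime choices

The shipped validation studies use: 1000 Stop trials for staircase
calibration; 60 subjects at 360 Go / 80 Stop for SSRT recovery; single
sessions with 300 Stop trials for the connectivity power/null studies (60
power and 200 null simulations); 200 null datasets with 199 permutations
for CV calibration; 4-subject cohorts at the high-SNR fixture for ICA
recovery and 20 seeds for MDL consistency; a 300-subject cohort for the
model-comparison study (chosen by a design power analysis: the null spread
of the mean-difference statistic scales roughly as 1/sqrt(n), and 300
subjects give the injected activity-vs-joint gap comfortable power at
alpha = 0.05); and 150 cohorts of 120 subjects per arm for the moderation
study. The end-to-end pipeline test runs 14 subjects on a reduced lattice.
These sizes are the package's own validation design; all are configurable
upward.

## Known limitations

* The generator's noise model is deliberately simple (white voxel noise,
  AR(1) component fluctuations, linear motion nuisance); conclusions about
  robustness to structured physiological artifacts require real data.
* Classical MDL is unreliable when the sample-to-dimension ratio is small
  and sources are weak; the package caps the order at the data rank but
  does not implement random-matrix-corrected order selection.
* The integration SSRT estimator retains its small finite-sample bias
  under staircase tracking; no parametric (e.g., Bayesian ex-Gaussian)
  stop-latency model is provided.
* `cppi()`'s default construction departs from the correlational-PPI
  letter to gain null calibration; users comparing against published cPPI
  values should use `method = "interaction"` and interpret accordingly.
* Directed or deconvolution-based (neuronal-level) connectivity is out of
  scope.
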