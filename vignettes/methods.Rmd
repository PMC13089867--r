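---
title: "Models and methods: affordance RSA and gaze lateralization on a synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: affordance RSA and gaze lateralization on a synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affordrsa)
```

## The task space

The experimental design this package simulates and analyses teaches
participants a *state-action graph* projected on the number line. A module
of four states occupies four consecutive numbers and is followed by one
unused gap number, so modules tile with period 5. Each state affords exactly
two signed numerical operations:

| state | afforded actions |
|-------|------------------|
| 1     | −2, +2           |
| 2     | +1, +2           |
| 3     | −2, −1           |
| 4     | −2, +2           |

All task numbers exceed 20 so that over-learned single-digit arithmetic
plays no role, and the whole structure can be shifted along the number line
(`offset`) to counterbalance number–state assignments across participants
without changing anything at the state level.

```{r}
g <- build_graph(21, 2)
g
successors(23, g) # state 3 affords -2/-1
```

**Graph closure.** Every afforded action maps a state slot onto another
state slot, never onto the gap. We define and test closure at the state
level under period-5 tiling, i.e. `(slot + action) mod 5` must land in
slots 0–3. At the number level a finite graph necessarily has boundary
numbers whose successors fall outside the stored range; the state-level
definition is the one the repeating design actually guarantees, and it is
what licenses generalization to unseen numbers (if 29 affords 27 and 31,
then 79 affords 77 and 81).

**Link distance** is the minimum number of afforded-action steps between
two states, computed by breadth-first search on the 4-node state graph. The
action graph is formally directed, but under the canonical affordances
every edge is reciprocated, so the directed and undirected distances
coincide; we implement the undirected search and note that the distinction
is untestable in this design.

## Model dissimilarity matrices

All models are 4×4 symmetric zero-diagonal matrices, flattened everywhere
into the canonical upper-triangle order (1-2, 1-3, 1-4, 2-3, 2-4, 3-4) —
fixing one flattening project-wide is what makes every downstream
correlation reproducible.

* **Affordance** (the hypothesis): `2 − |shared signed actions|`. States 1
  and 4 share both actions (dissimilarity 0); states 2 and 3 share none
  (dissimilarity 2).
* **Link distance** (control): BFS distances. Its canonical vector
  (2, 1, 1, 1, 1, 2) has *exactly zero* Pearson correlation with the
  affordance vector (1, 1, 0, 2, 1, 1) — the design decorrelates the
  hypothesis from graph topology.
* **Action magnitude** (control): `2 − |shared unsigned magnitudes|`. The
  one-line verbal definition is ambiguous between set and multiset
  semantics; we default to **multisets** (state 1's magnitudes are
  \{2, 2\}) because that preserves the two-action count symmetry of the
  affordance model and yields the sharpest contrast (states 1≡4 and 2≡3
  both at dissimilarity 0). The set reading is available via
  `magnitude_rdm(g, multiset = FALSE)`.
* **Behavioral models**: absolute reaction-time differences per state pair,
  and 2-D Euclidean distances between per-condition median gaze positions.

A note on shared successor states: it is sometimes asserted that the
magnitude model is perfectly anticorrelated with a model counting shared
successor states. Computing both under either set reading gives a Pearson
correlation of −0.5, not −1:

```{r}
cor(rdm_vec(magnitude_rdm(g)), rdm_vec(shared_successor_rdm(g)))
```

We expose `shared_successor_rdm()` so the relation can be computed rather
than assumed, and do not force agreement.

## Trial schedules

Each recall run has 80 trials, 16 of them probe trials (so 64 analysed
stimulus trials; 8 scanner runs give 512). Conditions are serially
counterbalanced: the ordered condition-transition counts across the 63
stimulus-trial transitions differ by at most 1. Exact equality is
impossible (63 transitions over 16 ordered pairs), so the ≤1 spread *is*
the contract; we construct sequences by a greedy minimum-count walk with
random restarts, which succeeds within a handful of restarts at every size
used here. Probes attach to a quarter of the stimulus trials at uniformly
random non-adjacent positions; half show the true successor pair, the rest
a foil obtained by perturbing one member of the pair by ±1.

ISIs are truncated-exponential with mean 3 s in the scanner and 2.5 s
during eyetracking. The truncation bounds are not dictated by the design;
we use [0.5, 8] s and solve the rate numerically so the *post-truncation*
mean equals the target, which keeps the event-related design estimable. The
drawn ISIs are then permuted (up to 10,000 shuffles) until the Spearman
correlation between each ISI and the model distance of its flanking trial
pair is below 0.1 for every model — preventing temporal structure from
mimicking model structure.

## Synthetic participants

The generator's defaults are the study conditions: 8 scanner runs (4
eyetracking runs) of 80 trials, TR 1 s, an ROI of 140 voxels (the size of a
right entorhinal ROI), probe accuracy 0.827 with SD 0.12, and per-state
reaction-time means (0.75, 0.68, 0.68, 0.75) s — states 1/4 slower than
2/3, mirroring the observed pairwise RT structure.

**Pattern geometry by inverse embedding.** The true condition patterns are
constructed so that their pairwise *squared Euclidean distances* equal
`signal_scale ×` a weighted mixture of the model RDMs. The mixture is
double-centred and eigendecomposed; eigenvalues at numerical zero are the
centring null space and are dropped, negative eigenvalues beyond tolerance
mean the mixture is not a Euclidean geometry and are an error. The
low-dimensional embedding is rotated into voxel space by a seeded random
orthonormal basis, so signal is spread across voxels and recovered
distances are exact to 1e−9.

**Noise.** BOLD noise is AR(1) in time (coefficient 0.3) with an
exponential spatial covariance across voxels (range 2 voxels) — crossnobis
specifically exploits non-diagonal noise covariance, so a diagonal-only
noise option would not exercise the estimator. Run-wise pattern jitter
(SD 0.05) controls cross-run reliability. `signal_scale = 0` produces pure
null data.

**Calibration.** The default `signal_scale = 1.2` was calibrated once so
that the subject-level tie-corrected Spearman correlation between the
estimated crossnobis RDM and the affordance model averages ≈ 0.3 under the
default problem size. The down-scaled test configuration (4 runs of 20
trials, 24 voxels) is anchored on the statistic the recovery test actually
uses — the *partial* affordance correlation with link-distance and
magnitude removed — and reaches a mean partial correlation ≈ 0.4 at
`signal_scale = 6`. Both values were then frozen.

**Gaze.** Streams are binocular at 1000 Hz: slow AR(1) fixation noise
(SD 30 px), independent per-eye jitter (2 px), Poisson blinks (0.15/s,
100–300 ms) flagged rather than deleted. State-2 trials add `+shift` and
state-3 trials `−shift` on the horizontal channel inside the 899–1757 ms
post-onset window, with 100 ms linear ramps at the edges to avoid
discontinuity artifacts in the smoothing stage. Per-subject shift,
probe accuracy and BOLD signal scale are coupled through one latent trait,
so the performance and brain–gaze linking analyses have a planted effect to
recover.

What the generator does *not* emulate: saccade/fixation microstructure,
retinotopy, scanner drift and motion, learning dynamics across the session.
Passing tests therefore certify the *analysis machinery* — calibration,
unbiasedness, recovery under the stated generative model — not robustness
to every property of real recordings.

## First-level GLM

Condition regressors are stick functions at stimulus onsets convolved with
the canonical double-gamma HRF (response shape 6, undershoot 16, ratio 1/6
— conventional values, exposed as parameters) and sampled on the TR grid;
because sticks are deltas the convolution is computed exactly as a sum of
shifted HRFs. Probe events get a nuisance regressor, an intercept is always
present, and optional cosine columns model slow drift; the core fit does no
prewhitening (the upstream preprocessing of real data would handle this,
and the synthetic generator's AR(1) noise is deliberately left for the
noise-covariance stage to absorb). Rank deficiency is an error naming the
offending columns. Betas for nuisance events are estimated and discarded;
only the four condition betas and the residuals flow downstream.

## Crossnobis RDMs

For runs *m* ≠ *n* with condition betas `b` and a noise covariance Σ̂,

d(i,j) = mean over unordered run pairs of
(bᵢᵐ − bⱼᵐ)ᵀ Σ̂⁻¹ (bᵢⁿ − bⱼⁿ) / P,

with P the voxel count. Division by P makes estimates comparable across ROI
sizes (recorded in the object's metadata). Because the two factors come
from independent runs, the estimate is unbiased — zero-mean under the null
and legitimately negative sometimes; this is what makes the mean-positivity
diagnostic meaningful. Unordered pairs are used; ordered averaging is
mathematically identical.

Σ̂ comes from the GLM residuals by diagonal-target shrinkage,
`(1−γ)S + γ diag(S)`, with the analytic Schäfer–Strimmer-type weight when
`γ = "auto"`; shrinkage guarantees positive-definiteness where the sample
covariance (time points ≲ voxels) would be singular. Per-run covariance is
the default (each run whitened by its own Σ̂ before the cross-run inner
product), with pooled and identity options; identity reduces the estimator
to the cross-validated squared Euclidean distance over P, which is one of
the oracle checks.

Robustness procedures mirror the original analysis: `mean_rdm_positivity()`
(consistent patterns imply positive mean cross-validated distance),
`reliability_voxel_mask()` (split-half condition-profile reliability
against a within-run label-permutation null), and `noise_ceilings()` (upper:
mean correlation with the group-mean RDM including each subject; lower:
leave-one-out).

## RSA inference

Model–neural comparisons use the tie-corrected Spearman correlation —
Pearson on midranks, the standard tie correction; with only six pairs, ties
are common and midranks matter (the affordance/link-distance decorrelation
is exact only under midranks). Covariates are removed by the classical
partial-correlation recursion applied on rank correlations; the result is
order-invariant, and we *assert* order-invariance at run time rather than
assume it, since a violation beyond round-off flags a degenerate covariate.
The independent check (and a standing test) is the rank-regression residual
formulation, which agrees to 1e−10.

Group inference Fisher-z-transforms the per-subject correlations and
applies a one-sample t test, one-sided for the directional affordance
hypothesis, with a Bonferroni-corrected α (0.025 for the two hemispheres in
the original design; 0.05/6 ≈ 0.0083 for six pairwise behavioral
comparisons). The correction policy for control ROIs is per-family
Bonferroni by default and configurable.

## Gaze pipeline

Preprocessing masks every sample within 100 ms of a blink (boundary
inclusive) and averages the two eyes into a cyclopean position. Epochs span
−500 to 2500 ms around stimulus onset on the native millisecond grid;
alignment is exact by construction. Condition timecourses are per-timepoint
medians across trials — masked samples are excluded per timepoint with no
interpolation, because medians tolerate missingness without imputation
bias — then smoothed with a Gaussian kernel of SD 4.25 ms whose support is
truncated at ±10 ms (the "20 ms maximum window") and renormalized.

The lateralization timecourse is state 2 minus state 3 on the horizontal
axis; positive means rightward skew for the positive-affording state.
Group inference is a cluster-based sign-flip permutation test: per-timepoint
one-sample t values, clusters formed above the one-tailed p = 0.05 critical
t at n−1 degrees of freedom (the conventional default when no threshold is
dictated; configurable), cluster mass = summed t, and a max-cluster-mass
null from 10,000 random per-subject sign flips. P-values use the +1
correction and are never exactly zero. Per-subject effect sizes are the
median lateralization over the significant cluster window; these feed
(a) the Pearson correlation with probe accuracy and (b) the brain–gaze
link, where each subject's RDM vector is normalized by its root mean
square — chosen so that rescaling a subject's whole RDM leaves the
normalized state-2/3 entry unchanged (z-scoring is offered as an
alternative) — before the (2,3) entry is correlated with the gaze shift.
`window_median_lateralization()` implements the coarse path for gaze
estimates at arbitrary sampling rates (per-trial median in a 1-s window,
then condition medians, then a one-sided paired t test).

## Pipeline and reproducibility

`run_pipeline(pipeline_config(...))` simulates a cohort and executes both
branches in dependency order, streaming subjects so raw BOLD and gaze never
accumulate in memory. Every stochastic stage derives its seed from the
single configured seed, so a report is a pure function of its config
(hashed into the provenance block); disabling the gaze branch leaves the
fMRI outputs bit-identical. The report carries per-subject tables, the
group RSA result with covariates, the cluster result, the two linking
correlations, and recovery diagnostics against the retained ground truth.

## Problem sizes used in the test suite

Statistical calibration is demonstrated on down-scaled cohorts chosen to
keep the full suite fast while leaving every stage of the pipeline intact:
null and power sweeps use 20-subject cohorts with 4 runs of 20 trials and
24 voxels (fMRI) or one 20-trial run sampled at 500 Hz (gaze); the
calibration sweeps use 500 cohorts each with 500 sign-flip permutations per
cluster test (permutation p-values are valid at any permutation count),
while single-cohort analyses use the full 10,000. The power sweep runs at
the calibrated operating point (subject-level mean partial affordance
correlation ≈ 0.4), where the 20-subject one-sided group test is expected
to exceed 80% power.

## Known limitations

* The four-state design gives 6-dimensional RDM vectors; rank correlations
  on six points are coarse and heavily tied, which is faithful to the
  analysis but limits resolution.
* The magnitude-model semantics and the RDM normalization for the linking
  analysis are design choices among defensible readings; both alternatives
  are exposed as options.
* Reliability voxel selection inherits the coarseness of the 4-condition
  label-permutation null: a tuning profile symmetric under some label swap
  can evade selection at any SNR.
* The generator plants effects through a single latent trait; real
  individual differences are unlikely to be one-dimensional.
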