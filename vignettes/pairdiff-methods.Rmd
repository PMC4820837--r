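---
title: "pairdiff: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pairdiff: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
stage models, which parameters matter (with units and defaults), where
the design was genuinely open and what we chose, and what a green test
suite does and does not establish.

## 1. The paradigm being modelled

A two-day pairmate learning study. 72 scene images form 36 pairs of
perceptually and semantically similar scenes; 12 pairs per condition
(No Face / Different Face / Same Face), balanced over indoor/outdoor
subcategories. Scanning presents every scene once per run in an
event-related design (4 s trials, stimulus 500 ms, TR 2 s; 24
null-fixation trials per run: 18 interleaved, 3 lead-in, 3 lead-out),
with pairmates always in opposite half-blocks of the run and 8.33% of
trials flagged as red-cross targets. After scanning, each scene is
paired with a unique object over three study--test cycles; choosing the
pairmate's object at test is an interference error.

Design generation (`make_stimulus_set()`, `make_scan_sequence()`,
`make_learning_schedule()`) is deterministic given the seed. Two open
points were settled as follows:

* **Target trials.** Whether the 8.33% target rate counts null trials in
  its denominator is not stated; we assume it does (8 of 96 at the
  default design), and targets are a *flag* on existing trials sampled
  uniformly, so that the 72-scenes-per-run invariant is preserved.
* **Half-block counterbalancing.** "Counterbalanced" is not specified
  further; we alternate AB/BA across runs with the starting order decided
  by the seed.
* **Adaptive day-1 retesting.** The default schedule assumes an
  error-free learner (two study--test cycles over random halves plus four
  whole-set test blocks, hence exactly six test exposures per
  association); extra criterion blocks would only be generated by an
  attached simulated learner, which the package does not ship.

## 2. The generative representation model

`representation_model()` describes scene representations as continuous
Gaussian factor read-outs rather than literal binary feature units; the
continuous model has closed-form correlations, which gives every
downstream test an analytic oracle. For a scene in condition $k$, latent
unit $u$ is

$$ x_u = \sqrt{c_g^{(k)}}\,G_{u,k} + s\,\sqrt{|c_p^{(k)}|}\,F_{u,p}
   + \sqrt{1 - c_g^{(k)} - |c_p^{(k)}|}\,E_{u,s}, $$

with $G$ a condition-level factor, $F$ a pair-level factor, $E$
scene-unique, all i.i.d. standard normal, and $s = +1$ for both pairmates
when $c_p \ge 0$ but opposite for the two pairmates when $c_p < 0$
(repulsion). Hence pairmate correlation is exactly $c_g + c_p$ and
same-condition nonpairmate correlation $c_g$. Voxels read the units out
through a random projection; adding per-voxel noise of sd $\sigma_p$
attenuates all correlations by $1/(1+\sigma_p^2)$. Both facts are the
oracles used in the tests.

Default couplings (hippocampus-like ROI):

| condition | `c_global` | `c_pair` | pairmate r |
|---|---|---|---|
| NoFace | 0.10 | +0.15 | 0.25 |
| DifferentFace | 0.18 | -0.03 | 0.15 |
| SameFace | 0.18 | -0.15 | 0.03 |

These encode the qualitative end-state of learning: baseline pairmate
clustering, learning-driven increases in nonpairmate coupling, and
pairmate coupling eliminated (Different Face) or driven negative in
difference-score terms (Same Face). The relative contribution of the
nonpairmate increase versus the pairmate decrease is not quantified in
the source; the defaults split the learning effect across both, which we
flag as a choice, not an asserted fact. Raw fMRI pattern correlations of
this magnitude (0.0--0.3) are typical for event-related designs. The
control parameterizations (PPA-like, EVC-like) keep one positive
`c_pair` across all conditions — perceptual similarity survives learning
outside the hippocampus.

**Selectivity profile.** Each voxel has a weight $\alpha_v \in [0,1]$;
the voxel's couplings are a mixture
$\alpha_v \Sigma_\text{condition} + (1-\alpha_v) \Sigma_\text{baseline}$,
implemented by mixing two independent read-outs with weights
$\sqrt{\alpha_v}$ and $\sqrt{1-\alpha_v}$. This makes the learning-driven
coupling change proportional to scene selectivity — the generative hook
for the voxel-tercile effect, whose mechanism the source shows only
empirically. The default profile is all ones, so the closed-form
correlations hold exactly.

**Differentiation operator.** `apply_differentiation(p, d, r)` (i) drops
a fraction $d$ of *shared* pair-factor units — each dropped unit's shared
contribution is replaced by fresh scene-unique variance, so scene
variance is preserved and pairmate correlation interpolates linearly from
$c_g+c_p$ at $d=0$ to $c_g$ at $d=1$ (this is what "units dropping out of
the representation" must mean for the full-dropout correlation to land on
the nonpairmate level; merely zeroing loadings would land on
$c_g/(1-c_p)$); only positively coupled pairs have shared units to lose;
and (ii) adds an anti-symmetric voxel-space perturbation of sd $r$,
scaled by voxel selectivity, pushing pairmates apart. Expected pairmate
correlation is non-increasing in both arguments, and a sufficient $r$
drives the expected difference score negative.

## 3. BOLD simulation and pattern estimation

`simulate_bold()` is the forward model the GLM assumes: per-scene impulse
trains convolved with the canonical double-gamma HRF (peak 6 s,
undershoot 16 s, dispersions 1, ratio 1/6, peak-normalized; the kernel
has finite support [0, 32 s]), scaled by each scene's voxel pattern.
Noise is AR(1) Gaussian (defaults: marginal sd 1, lag-1 autocorrelation
0.3 — the signal amplitude is also order 1, a deliberately favourable
but not noiseless regime) plus a slow drift (random linear trend + 240 s
cosine with random phase, amplitude 1). A small run-specific re-draw of
each pattern (`run_jitter_sd = 0.1`) keeps repeated estimates of a scene
from being degenerate copies of one truth.

`highpass_filter()` implements Gaussian-weighted running-line fitting
with sigma = 64 s: at each timepoint a weighted straight line is fitted
and its fitted value subtracted. Constants and exact ramps map to zero;
the empirical transfer function (tested) attenuates sinusoids slow
relative to sigma and passes fast ones.

`fit_glm()` does per-run OLS, or AR(1)-prewhitened GLS: the lag-1
autocorrelation is estimated from pooled OLS residuals (pooling across
voxels; a documented simplification of voxelwise local autocorrelation
correction), the model is transformed (first observation scaled by
$\sqrt{1-\phi^2}$), and re-fit. Run-level betas are combined by
fixed-effects inverse-variance weighting — the natural reading of
"entered into a fixed-effects model" — and t-maps (beta/se) are the
default pattern for similarity analysis, with run-level estimates
available via `combine = "none"`. Noiseless data would give zero
standard errors; t-statistics are then capped at $10^6$ and flagged
rather than left infinite. Nuisance regressors default to an intercept
plus a linear drift per run.

`localizer_contrast()` computes the scenes > (faces & objects) contrast
with weights (+1, -1/2, -1/2) (the source names the contrast but not the
weights) and converts t to z through tail probabilities on the log scale.
`select_voxels()` keeps voxels with z strictly above threshold (z > 1
hippocampus, z > 3 ventral temporal cortex in the modelled study), or
splits them into rank-ordered terciles; when $n \bmod 3 \ne 0$ the extra
voxels go to the *lower* terciles and ties break by voxel index — an
arbitrary but frozen rule, tested exhaustively.

## 4. Similarity analysis

`fisher_z()` is $\mathrm{arctanh}(r)$ after clipping $|r|$ at
$1 - 10^{-7}$; the clip exists because noiseless synthetic inputs can
produce exact $\pm 1$ correlations, and is documented behaviour, not an
error. `build_similarity_matrix()` correlates set-A against set-B scene
patterns only (within-set correlations are never computed; in the
modelled design they would be temporally confounded), masks
across-condition cells, and errors on zero-variance patterns naming the
scene. `pair_difference_scores()` subtracts from each diagonal cell the
mean of the valid off-diagonal cells of that pair's row *and* column
jointly (2 x 11 = 22 cells at the default design). Averaging jointly
versus per-pairmate-then-averaging gives the same number here because the
two cell sets have equal counts; we implement the joint mean and note the
equivalence. `condition_summary()` averages within subject first, then
reports mean +/- s.e.m. across subjects.

`mds_embed()` uses classical (Torgerson) metric MDS, deterministic up to
rotation/reflection. The dissimilarity rule — not specified by the
source figure — defaults to $d = z_{max} - z$ over observed cells,
symmetrized as $(M + M^\top)/2$, with the never-computed within-set cells
imputed from their across-set pair-level counterparts; a custom rule can
be supplied as a function. Kruskal stress-1 is reported so users can see
how much the 2-D projection compresses.

## 5. Inference layer

`fit_mixed_logistic()` wraps lme4's Laplace-approximated GLMM.
`random = "maximal"` requests per-subject random slopes for all
within-subject main effects; when that fails to converge the fit falls
back to intercept-only and records the simplification (the source used
the maximal structure but does not report convergence handling; the exact
per-model random-slope composition is likewise unreported, so the
shipped configurations are a documented best guess). "Other" outcomes
(nonpairmate-foil errors only) are excluded before fitting. Complete
separation is detected (deviance collapse with runaway coefficients) and
raised as a diagnostic error rather than silent divergence. `lrt()`
computes $\chi^2 = 2(\ell_f - \ell_n)$ with the parameter-count
difference as df, after checking genuine nesting and equal observation
counts.

`paired_tests()` dispatches paired t / one-way repeated-measures ANOVA
(explicit sums-of-squares partition, cross-checked against `stats::aov`
in the tests) with Wilcoxon signed-rank (continuity-corrected) and
Friedman counterparts; Shapiro--Wilk screening is advisory and
auto-switches to the nonparametric test at alpha = 0.05 under
`test = "auto"`. Degenerate identical vectors return t = 0, p = 1
instead of NaN.

`face_evidence()` trains an L2-regularized logistic classifier with the
LIBLINEAR objective $\tfrac12\|w\|^2 + C\sum\log(1+e^{-y f})$ at the
default $C = 1$, intercept unpenalized, by damped Newton iterations
(verified in the tests against a numerical optimum of the same
objective). Patterns are z-scored across voxels before training and
prediction; face evidence is the logit of the face probability after
clipping to $[10^{-6}, 1-10^{-6}]$.

## 6. The behaviour model

`behavior_model_truth()` sets the generative log-odds of a pair being
retrieved correctly (vs an interference error):
intercept 0.7 (repetition coded 0--2, giving ~75% first-cycle accuracy),
score slope -2.0, Different Face offset +1.12, repetition effect +1.2 —
generative analogues of the reported group-level estimates — plus a
subject random intercept (sd 0.5; unreported, a typical
between-subject spread) and a 4% rate of "other" outcomes independent of
the score (the source reports only that such errors were a minority).

## 7. What the tests establish — and what they do not

The synthetic world is favourable by construction: Gaussian factor
patterns, stationary AR(1) noise, a perfectly known HRF, no motion,
no physiological noise, no spatial structure. A green suite establishes
that the *pipeline* is correct (each stage matches an independent
oracle; the end-to-end run recovers the generative signs), not that the
scientific result would replicate: the headline statistics of the
modelled study came from human data that is not available, so tests
assert the qualitative signature — baseline difference score > 0,
eliminated/reversed with learning in the hippocampus-like ROI only, and
a negative score-to-accuracy slope — rather than any numerical F or t
value. Null calibration (orthogonal coding gives score 0 within
Monte-Carlo error), parameter recovery (a planted slope of -2.0 is
covered by its 95% CI in >= 90/100 replicates), and type-I error of the
LRT (~5% at 1,000 null replicates) are tested at stated tolerances. For
runtime, the 1,000-replicate LRT calibration uses the fixed-effects
estimation path under a truth with zero subject variance; the GLMM path
is exercised by the 100-replicate recovery study.

One environment-driven narrowing: no NIfTI reader/writer is available in
the target R environment, so volumetric I/O is out of scope; time series
and patterns move through the package as matrices and are persisted as
CSV/TSV (events use the BIDS-style TSV layout).

## 8. Known limitations

* AR(1)-only prewhitening with a pooled autocorrelation estimate, not a
  voxelwise or higher-order model.
* The "maximal" random structure is main-effects-only (no interaction
  slopes), and the fallback ladder has a single rung.
* The MDS figure construction is one defensible choice among several;
  stress values near the default design sizes are substantial, so
  embedded distances are illustrative, not inferential.
* Selectivity terciles are generated by a single mixing mechanism;
  nothing in the package can distinguish it from other mechanisms that
  produce the same second-order statistics.
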