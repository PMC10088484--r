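---
title: "Methods: region-based lesion-symptom mapping and severity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-based lesion-symptom mapping and severity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roilsm)
```

This vignette is the package's account of the science it implements: the
models, the parameters that matter, the numerical conventions, and what the
synthetic validation does and does not establish.

## Damage quantification

A subject's lesion is a binary 3-D mask on the same voxel grid as an
integer-labelled atlas parcellation. Damage to ROI $k$ is the fraction

$$d_k = \frac{\#\{\text{lesioned voxels with label } k\}}{\#\{\text{voxels with label } k\}} \in [0, 1].$$

Fractions, not percentages, are stored throughout so that mapping
regressors and prediction features share one scale; display layers may
multiply by 100. Lesioned voxels outside every atlas label count towards
the subject's lesion volume but towards no region — the volume-only
prediction mode deliberately uses *total* lesion volume, not
atlas-covered volume. Masks are binarized on read (nonzero → 1) with a
warning when the input was not already binary, tolerating interpolation
artefacts in hand-drawn tracings that were resampled during
normalization. Grids are compared by dimensions and by affine (entrywise
tolerance $10^{-4}$); resampling is out of scope, so a mismatch is an
error rather than a silent fix, and subject alignment between masks and
the behaviour table is by exact `subject_id` string match — fuzzy matching
risks silent misalignment, the worst failure mode in this design.

## Region-based mapping

For each ROI the association statistic is the slope $t$ from the simple
linear regression of the behavioural score on the damage fraction
(equivalently $t = r\sqrt{(n-2)/(1-r^2)}$); negative values mean damage
lowers the score. No covariates are used. ROIs enter the analysis only if
damaged ($d_k > 0$) in at least `round(min_prop * n)` subjects, with
half-away-from-zero rounding; at the default `min_prop = 0.10` this gives
thresholds of 11 subjects for $n = 109$ and 6 for $n = 63$. "Damaged"
means any nonzero fraction; no minimum-fraction variant is implemented.

Family-wise correction uses the max-statistic permutation construction,
one-tailed in the damage-lowers-score direction: scores are permuted
across subjects $B$ times (damage fixed), all included-ROI statistics are
recomputed per permutation, and each permutation contributes its minimum
(most negative) statistic to the null. The corrected p-value for ROI $k$
is $(1 + \#\{\text{minima} \le t_k\})/(B + 1)$ — the add-one convention
guarantees valid p-values with floor $1/(B+1)$. The default
$B = 2000$ permutations at $\alpha = 0.05$ matches standard practice for
ROI-level mapping. With `exact = TRUE` all $n!$ permutations are
enumerated instead (capped at $n = 8$), which the test suite compares
against an independent `lm()`-based exhaustive oracle.

Numerical conventions: a zero-residual regression has an unbounded $t$;
it is reported as the signed sentinel $\pm 10^6$, which places the ROI at
the permutation floor and always inside the significant set — preferable
to propagating an infinity. A constant score vector yields statistic 0
for every ROI and no significant results. A constant damage column among
included ROIs is dropped with a warning (`roi_statistic()` itself refuses
it). Each behaviour (AQ and the four WAB-R subscores) is analysed
independently with its own permutation null; no cross-behaviour
correction is applied.

Cohort-to-cohort agreement of significant sets is summarized by the dice
coefficient $2|A\cap B|/(|A|+|B|)$, defined as 1 when both sets are
empty.

## Severity prediction

A linear $\varepsilon$-insensitive support-vector regression predicts the
normalized score (raw 0–100 divided by 100) from either all damage
fractions (`roi_damage`) or from a single rescaled lesion-volume feature
(`volume_only`); both modes share one code path and differ only in the
feature matrix. The volume feature is the voxel count divided by the
number of atlas-labelled voxels, landing in $[0,1]$ and keeping betas
commensurate with the damage-fraction mode. Features receive no further
standardization: beta magnitudes are scale-dependent, so only their
*ranking* is interpreted (the `top_negative_betas()` list), with ties
broken by ROI-table order.

Hyperparameters are fixed, not tuned: $C = 1$ and $\varepsilon = 0.1$ on
the 0–1 score scale, exposed as arguments. Reproducibility is preferred
over optimality here; tuning inside a leave-one-out loop would also
invite selection effects that the evaluation designs cannot detect. The
solver is libsvm (via `e1071`) with termination tolerance tightened from
its default $10^{-3}$ to $10^{-6}$, so that solutions agree with an
independent quadratic-program solution of the dual to well under the
$10^{-4}$ level at which the test suite cross-checks beta and offset.
When every score fits inside the $\varepsilon$ tube the dual has no
support vectors and the model is offset-only with zero betas — a
legitimate degenerate solution, handled explicitly. Predictions are
reported raw and may leave $[0,1]$; an optional `clip` flag exists but
defaults off, since observed-vs-predicted correlations are computed on
the raw values.

Four evaluation designs share this machinery: leave-one-out within each
cohort ($n$ folds, fold $i$ trained on the other $n-1$ subjects;
reported betas are the arithmetic mean over folds) and cross-cohort
training (one model trained on the full training cohort; its own betas
are reported), with features aligned across cohorts by ROI name.
Accuracy is always the Pearson correlation between actual and predicted
normalized scores with a two-tailed $t$-based p-value. The 10% inclusion
rule is *not* applied to the prediction features by default — it belongs
to the mapping analysis — though the filter can be applied manually
before fitting. Accuracies from two designs are compared with the
two-tailed Fisher r-to-z test; note this test assumes independent
samples, and comparing two accuracies computed on the *same* test
subjects violates that assumption. The package reproduces this standard
usage as-is; a dependent-correlation test (Steiger/Williams) is a
deliberate non-goal.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be validated
against a known answer. It emulates:

- **Geometry.** An atlas of `n_rois` contiguous axis-aligned blocks
  tiling the $x \le \lfloor n_x/2 \rfloor$ half of the grid ("left
  hemisphere"); background elsewhere. Construction is deterministic.
- **Lesions.** A single 6-connected component grown from a uniformly
  drawn seed voxel by stochastic wave expansion (each boundary voxel
  absorbed with probability 0.7 per wave), hitting the target volume
  exactly and never leaving labelled territory. Volumes are log-normal,
  matched by method of moments to published acute
  (mean 22 510.4, SD 42 812.8 voxels, $n = 63$) and chronic
  (mean 118 808.6, SD 94 864.7 voxels, $n = 109$) cohort profiles, then
  truncated to the hemisphere capacity. Log-normality reflects the
  large SD/mean ratios of such cohorts: volumes are positive and
  right-skewed.
- **Behaviour.** The law
  $\text{score} = \mathrm{clip}(100\,(1 - \sum_k w_k d_k) + \varepsilon,\ 0,\ 100)$
  with $\varepsilon \sim N(0, \sigma)$ over a designated critical-ROI
  set. The default criticals are the three ROIs nearest the hemisphere
  centroid (a stand-in for the perisylvian core) with weights
  0.5/0.3/0.2; the default noise SD is 8 AQ points, chosen as a
  plausible magnitude for measurement noise plus unmodelled
  behavioural variance on a 0–100 scale. The four WAB-R subscores are
  generated by the same law rescaled to each subscore's range
  (20/200/100/100) with independent noise. No generative model for
  behaviour is established in the literature this emulates; the
  linear-plus-noise law is a stand-in, chosen to lie inside the linear
  SVR's hypothesis class so that parameter recovery is well-posed.
- **Cohort contrast.** Acute-like and chronic-like presets differ *only*
  in sample size and volume distribution, never in the damage-to-score
  law — isolating the question of cross-stage transferability by
  construction.

One seeded RNG stream per cohort is consumed in a documented order —
volumes, then per-subject lesion growth, then AQ noise, then subscore
noise — so cohorts are bit-reproducible from `(config, seed)`.

What the generator does **not** emulate: vascular-territory lesion
shapes and their spatial clustering (seeds are uniform over the
hemisphere, so acute-scale lesions often miss the critical set entirely,
producing ceiling-heavy score distributions and occasionally unstable
small-cohort accuracies), haemorrhagic vs ischaemic differences,
atlas-parcel size heterogeneity, and any cohort-selection effect (real
chronic cohorts are recruited *because* impairment persisted). Passing
recovery tests on synthetic data therefore demonstrates the
correctness of the estimators under their own assumptions, not their
field performance on real lesions.

## Problem sizes and runtime choices

The full-scale presets use a 1 mm grid of $96 \times 128 \times 96$
voxels (labelled hemisphere ≈ 590k voxels, comparable to a human
hemisphere at 1 mm), on which the published volume distributions apply
unscaled. Tests and the acceptance script run the same presets at
`voxel_mm = 4` — grid dimensions divided by 4, volumes by $4^3$ — which
preserves every volume-to-hemisphere and damage-fraction relationship
while keeping a full pipeline run in seconds. Recovery studies use a
$20 \times 24 \times 20$ grid with 12 ROIs, $n = 100$ subjects, noise
SD 5, and 500 permutations; the mapping-recovery study assigns the full
weight to a single critical ROI, and the beta-ranking study uses two
criticals with weights 0.6/0.4. Exhaustive-permutation checks use
$n = 6$ (720 permutations).

## Known limitations

- The mapping statistic family (t vs z), tail convention and exact GLM
  options of established RLSM toolboxes vary; this package documents its
  choices (slope $t$, one-tailed negative, add-one counting) rather than
  claiming toolbox-for-toolbox equivalence.
- Exact numerical reproduction of any published beta weights is not
  attempted: solver, $C$, $\varepsilon$ and feature scaling are rarely
  reported in the literature, and betas are scale-dependent.
- Welch's t-test is provided for cohort descriptive comparisons, but
  group-level t statistics in published demographic tables are often not
  recoverable from the printed summaries; the package computes its own
  from raw vectors and does not attempt to match printed values.
- No covariate adjustment (age, education, lesion-volume regression-out),
  no voxelwise mapping, no kernel SVR, no cluster-level inference.
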