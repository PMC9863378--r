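---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling choices behind `qsarpt` that are not
obvious from the function reference: the semantics of the descriptor-weighting
network, the combination enumeration, tie-breaking rules, the design of the
synthetic study generator, and the known limitations of the leverage-based
outlier rule.

## 1. Descriptor weighting with a backpropagation perceptron

`ann_weights()` trains a single-layer network — scaled descriptors feeding one
sigmoid output, no hidden layer by default — and uses the mean absolute input
weight over random restarts as each descriptor's importance.  A descriptor is
selected when its importance strictly exceeds twice the median importance.

Several details matter for that selection signal:

* **Update rule.**  Training is plain full-batch gradient descent on the mean
  squared output error, run until the largest absolute error gradient falls
  below `threshold` (default 0.005) or `stepmax` steps (default 1e5).
  Resilient propagation (rprop) variants were deliberately *not* used: rprop
  updates weights by gradient **sign** with per-weight step sizes, so every
  weight — informative or not — grows at a similar rate, which flattens the
  importance profile and destroys the 2×median contrast.  Plain gradient
  descent from near-zero initial weights grows each weight in proportion to
  its descriptor's consistent association with the outcome, which is exactly
  what the importance score is meant to capture.
* **Targets.**  The clearance outcome is min-max rescaled into [0.1, 0.9]
  rather than (0, 1): sigmoid outputs can attain those targets at finite
  weights, so the gradient does not chase saturating values.
* **Initialisation.**  Initial weights are small (SD 0.01) and assigned by
  sorted descriptor code, making the selection invariant to the column order
  of the input matrix (verified by a permutation test).
* **Convergence.**  If no restart converges within `stepmax` steps the
  function raises a typed condition (`qsarpt_convergence_error`) carrying the
  partial importance profile, rather than returning a silently unconverged
  answer.

The learning rate (0.2) was chosen so study-sized problems (15 compounds,
up to ~150 descriptors) converge well inside `stepmax`; with `hidden > 0` the
same machinery trains a one-hidden-layer network and importances are summed
over paths.

## 2. Enumerating uncorrelated combinations

`enumerate_uncorrelated()` implements recursive correlation splitting: while
any retained pair of descriptors has squared correlation strictly above the
threshold (default 0.5), branch on the pair — drop the first, or drop the
second — and recurse; the leaves are exactly the **maximal independent sets**
of the conflict graph whose edges join correlated pairs.  Two implementation
notes:

* Correlated pairs never straddle connected components of the conflict graph,
  so the enumeration factorises: maximal sets are enumerated per component
  and cross-unioned.  The result is provably identical to the naive recursion
  (the test suite pins it against brute-force subset enumeration and an
  independent graph-library implementation) while avoiding exponential
  blow-up on the ~30-node candidate graphs that realistic selections produce.
* The threshold comparison is strict (`R² > threshold`), so a pair exactly at
  the threshold does not branch.

## 3. Weighted regression, pruning and ranking

`fit_wls()` solves the weighted least-squares problem directly on the QR
decomposition of the √w-scaled design, with a memoising cache keyed on
(descriptor set, weighting).  The pipeline fits thousands of heavily
overlapping small models during combination pruning, and the formula/model-
frame machinery of `stats::lm` dominated runtime; equivalence with
`lm(..., weights = )` — coefficients, standard errors, p-values, hat
diagonals — is pinned by oracle tests at 1e-10.

Pruning removes the least significant descriptor (largest p ≥ 0.05) and
refits, switching to a bidirectional stepwise search minimising AIC when more
than three descriptors are simultaneously non-significant.  A set too large
to fit at all (more descriptors than the data's design rank — common when
pooling both descriptor families at 15 compounds) is handled by the same
stepwise machinery seeded at the set's best single descriptor, building the
model up instead of fitting the unfittable full set first.

`rank_models()` filters (R² > 0.7, all descriptors significant, not
degenerate) and sorts by BIC; ties break by fewer descriptors, then by
lexicographic descriptor codes, so rankings are fully deterministic.

A practical note on weighting: with homoscedastic replicate noise the `1/Y`
and `1/Y²` weightings misspecify the error variance, and because the weights
then correlate with the residuals the nominal 5% significance filter inflates
(measured ≈12% for a pure-noise descriptor under `1/Y` at study size).  That
is a property of weighted fits, not a defect; it explains why pipeline runs
under the default `1/Y` weighting occasionally carry one small extra
descriptor through the p < 0.05 filter.

## 4. Validation battery

`lmo_validate()` evaluates a model over a `split_plan` of train/test splits
(default three splits of 55 training / 20 test clearance values, with
high-leverage compounds pinned to the training side).  Per split it reports
calibration R²/RMSEC, leave-one-compound-out Q²/RMSECV (entire compounds —
all replicates — are held out, never single replicates), external QLMO² and
RMSEP; pooled external predictions yield Lin's concordance correlation and
Pearson/Spearman correlations on compound means.  QLMO² uses the training-set
variance as its reference, giving the identity
QLMO² = 1 − RMSEP² / (SS~tr~/n~tr~), which the tests verify to 1e-12.

## 5. The synthetic study generator

`paperlike_study()` produces a full study — EMG chromatograms for 15
compounds × 26 conditions, the measured 15 × 104 chromatographic matrix, a
15 × 50 molecular matrix, and 75 replicate clearance values from a planted
six-descriptor linear model.  Its central design property is
**identifiability by design**: the planted answer is constructed to be the
unique linear explanation of the data, so full-pipeline recovery is a
testable property rather than a coin flip.

Why naive generators fail at this size, structurally and not by bad luck:

* at n = 15 compounds, a random nuisance column explains an expected
  R² ≈ 6/14 ≈ 0.43 of a planted six-column span, so nuisance descriptors
  routinely proxy for planted ones;
* with five identical replicate rows per compound, BIC on 75 rows is nearly
  break-even against absorbing one compound's mean noise (expected 2Δll ≈ 5
  against a penalty of log 75 ≈ 4.3), so supersets of the truth often win;
* best-subset search over hundreds of enumerated combinations adds roughly
  2·log(#models) of selection optimism.

The generator therefore makes each expressive chemistry × solvent condition
an independent latent dimension, sample-orthogonalises every nuisance source
(hydrophobicity, peak width and tailing traits, non-planted condition
residuals) against the planted span, and enforces an explicit correlation
contract on the matrix *as measured from the traces* (planted descriptors
dominate their solvent siblings, nuisance correlations bounded, planted
pairwise R² bounded).  The replicate-noise stream is likewise redrawn over a
deterministic sub-seed sequence until the planted model is clearly supported
by its own replicates.  These rules are fixed and run identically for every
seed.

Realism compromises, stated openly: peaks are exponentially modified
Gaussians (the standard tailed-peak model) rather than instrument traces;
replicate CI values are kept strictly positive (values below 0.01 are
redrawn, with a reflection fallback) so `1/Y` weights stay finite; tail
constants are capped at moderate τ/σ so tailing does not shift measured
apexes enough to leak shape traits into retention descriptors; and
non-expressive chemistries are near-collinear hydrophobicity clones, giving
the correlation splitting realistic redundant groups to collapse.

## 6. Leverage-based outlier flagging: reach and limits

`flag_high_leverage()` flags a compound when its mean leverage over
replicates exceeds `3(A+1)/I`.  Arithmetic limits where that rule can fire:
with five identical replicate rows per compound, a compound's rows share one
hat mass (their leverages sum to at most 1), so its **mean** leverage is at
most 1/5 — while the cutoff for the six-descriptor final model is
3·7/75 = 0.28.  The rule is therefore unreachable on the final model at this
study geometry, whatever the descriptor values; it can fire only for compact
models (A ≤ 3 on replicate rows).

The generator's two constructed outliers respect this: `CPD14` is an
anomalously broad peak on T3/acetonitrile (descriptor `T3A2`) and `CPD15` an
anomalously tailed peak on C8/methanol (`C8M8`).  Both are flagged reliably
by fitting a compact model on the displaced dimension:

```{r}
st <- paperlike_study(seed = 1)
xs <- scale_matrix(st$chrom_matrix)
m  <- fit_wls(xs, st$clearance, "T3A2", "1")
flag_high_leverage(m)   # CPD14 flagged
```

The displaced dimensions are peak-*shape* descriptors, which carry no
outcome signal, deliberately: an outlier planted on a retention (outcome-
bearing) dimension strong enough to flag reaches compound leverage near 1 in
the final model and destabilises leave-one-compound-out validation through
the 1/(1−h) error amplification.

## 7. Problem sizes and determinism

All algorithms are tuned for the study geometry: ≤ ~160 descriptors,
~15 compounds, ~75 replicate observations, hundreds of candidate
combinations.  Enumeration is exponential in the conflict-graph component
size in the worst case; the component factorisation keeps realistic runs in
milliseconds, and the test battery (including 20 full pipeline runs) executes
in well under a minute.  Every stochastic step (ANN restarts, noise streams,
split sampling) is governed by explicit seeds recorded in the pipeline log
and artifacts, and reruns with the same config are bit-identical.
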