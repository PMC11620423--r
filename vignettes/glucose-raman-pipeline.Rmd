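---
title: "Classifying glucose levels from Raman spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying glucose levels from Raman spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Raman spectroscopy offers a non-invasive route to glucose monitoring: a
monochromatic laser excites a sample and the inelastically scattered light
carries a molecular fingerprint. For glucose dissolved in deionized water
("phantom" samples that stand in for blood), the spectrum is a sum of three
components:

* weak, narrow **analyte bands** whose heights grow linearly with glucose
  concentration,
* a strong, smooth **fluorescence background** that varies from sample to
  sample and usually dwarfs the analyte signal, and
* detector and environment **noise**.

`ramanglu` implements a complete classification pipeline for this setting:
spectra are labelled with one of ten concentration levels (5.0–20.0 mmol/L,
label codes 1–10), and three classifiers — Extra Trees, Random Forest, and a
support vector machine — are compared under three preprocessing scenarios:

1. **root** — raw intensities, untouched;
2. **hotspot** — sliding-window variance feature selection;
3. **vra** — fluorescence removal by iterative modified polynomial fitting
   (IModPoly, the core of the Vancouver Raman Algorithm).

Because no public dataset exists for this exact design, the package ships a
synthetic-data generator that reproduces the study conditions (10 levels ×
5 replicates × 2048 points) and is itself first-class, tested code.

## Data model

A `raman_spectrum` is a strictly ascending shift axis (cm⁻¹) plus one
intensity per point. Raw intensities are photon counts and must be ≥ 0
(zero is accepted: an empty bin is physically meaningful). Spectra that have
been baseline-corrected may be negative and are constructed with
`raw = FALSE`. A `raman_dataset` is an ordered collection of spectra sharing
one axis, plus a concentration→code label map. On disk, one sample is one
two-column CSV whose integer filename prefix before the first `-` is its
label code (`7-sample3.csv` → code 7); values are written with 17
significant digits so a write/read round trip is exact.

Indices are **0-based** throughout the hotspot machinery, matching the
convention in which retained-index segments are reported (e.g. "index 0 to
29" is a 30-point run).

## The synthetic generator

`generate_spectrum()` draws

$$ I(\nu) = \max\{0,\; g \cdot (B(\nu) + c \sum_i w_i \beta\,
   e^{-(\nu-\mu_i)^2/2\sigma_i^2}) + \varepsilon(\nu)\}, $$

where $B$ is a degree-5 polynomial background, $c$ the concentration in
mmol/L, $g \sim 1 + \mathcal N(0, \texttt{gain\_sd})$ a per-sample gain, and
$\varepsilon \sim \mathcal N(0, \texttt{noise\_sd})$ additive noise.

Defaults and their reasoning:

* **Axis**: 2048 points over 200–3200 cm⁻¹, the span a dispersive 785 nm
  instrument typically digitizes.
* **Bands**: Gaussians at 911, 1060, 1125 and 1366 cm⁻¹ — canonical glucose
  Raman bands — with width 12 cm⁻¹ and relative weights 0.8/1.0/0.9/0.6.
  These fall in the first ~60 % of the axis, so the discriminative region
  and the global intensity maximum sit inside the first 1250 indices, the
  qualitative shape the pipeline assumes.
* **Background**: the degree-5 polynomial through six template node values
  (peaking at ~1000 counts near the first quarter of the axis, decaying
  toward the red end). Each sample re-solves the polynomial through
  node values jittered by `baseline_jitter` (relative sd 0.05), so the
  background varies realistically between samples and background removal has
  genuine work to do. The background degree equals the default VRA fit order
  — deliberately, so the recovery test is a fair one.
* **Response**: `response_slope` β = 10 counts per mmol/L at a weight-1 band
  apex. Adjacent levels (0.5 mmol/L apart) then differ by ~5 counts at the
  apex — small against the ±50-count background jitter, which is what makes
  the raw-data scenario hard and background removal valuable.
* **Noise**: additive Gaussian, `noise_sd` = 2 counts (the primitive data
  this emulates has already had basic noise reduction applied; shot noise is
  deliberately not modelled).

Determinism: every stochastic unit takes an explicit seed; replicate seeds
derive from the master seed through a fixed 32-bit mix, so a dataset is a
pure function of `(levels, replicates, params, seed)`.

What the generator does **not** emulate: cosmic-ray spikes, detector
etaloning, wavelength miscalibration, water/quartz bands, or any coupling
between concentration and background shape. Passing tests therefore
demonstrate correctness of the pipeline's machinery and the direction of the
preprocessing effect under these assumptions — not instrument-level realism.

## Hotspot series extraction

For a spectrum of length $N$ and window length $l$, every contiguous
*intensity series* starting at index $j \in [0, N-l]$ is scored by its
population variance

$$ \bar S_j = \tfrac1l \sum_{i=j}^{j+l-1} I_i, \qquad
   V_j = \tfrac1l \sum_{i=j}^{j+l-1} (I_i - \bar S_j)^2 , $$

giving exactly $N - l + 1$ windows. Per sample, the $k$ highest-variance
windows are selected — ties resolve toward the smaller start index, making
selection fully deterministic — and the *mask* is the union over all samples
of the indices those windows cover. Every sample is then reduced to the
masked columns. Defaults are $l = 10$, $k = 500$.

Numerical note: window statistics are computed by direct per-window
summation rather than a rolling cumulative-sum update. The two differ by
floating-point crumbs that are harmless for ranking distinct variances but
break exact ties, and the tie rule is part of the contract; bitwise
agreement with a naive recomputation is tested.

Two conventions worth flagging:

* The score is the *mean*-centred variance: the quantity is sometimes
  described as a median-based "hotspot level" in the literature this
  follows, but the defining formula is the arithmetic mean, and the formula
  is what is implemented.
* The default workflow computes one global mask from the **full dataset**
  before cross-validation, mirroring the experiment this package reproduces.
  That lets test samples influence feature selection; when leakage matters,
  compute the mask on a training subset (`select_hotspots()` accepts any
  dataset) and apply it to held-out data.

## Fluorescence removal (IModPoly / VRA)

The Vancouver Raman Algorithm has two stages. First, optional noise
reduction: a boxcar moving average with odd user-set width (default 7
points; windows truncate at the boundaries, so constants pass through).
Second, iterative modified polynomial fitting:

1. least-squares fit a degree-$p$ polynomial (default $p = 5$; fluorescence
   backgrounds are conventionally fit with order five or six) to the working
   spectrum;
2. compute DEV, the standard deviation of the residuals;
3. clip the working spectrum at `fit + DEV`, so points that stand above the
   fit — Raman peaks — are progressively excluded;
4. stop when the relative DEV change falls below `tol` (default 0.005) or
   after `max_iter` (default 100) iterations; DEV = 0 converges immediately.

The corrected spectrum is the smoothed input minus the final fit.
Numerical choices: the fit uses a monomial basis on the shift axis rescaled
to $[-1, 1]$ (the fitted values, not the coefficients, are the contract);
the clipping step is pointwise non-increasing, so the working spectrum is
monotone across iterations; non-convergence is reported via a flag, never an
error. Corrected intensities are *not* clipped at zero — the positivity rule
applies to raw counts, and downstream models see the full residual signal,
undershoot included.

## Evaluation harness

**Metrics.** With ten classes, each class $c$ in turn is treated as positive
against the rest, giving a one-vs-rest table with TP, TN, FP, FN and

$$ \mathrm{Acc}_c = \frac{TP+TN}{TP+FP+TN+FN}, \quad
   \mathrm{Sp}_c = \frac{TN}{TN+FP}, \quad
   \mathrm{Se}_c = \frac{TP}{TP+FN}. $$

Specificity, sensitivity and rank-based ROC-AUC are macro-averaged over
classes (macro matches the one-sample-per-class fold design). The headline
**accuracy is the plain multiclass fraction-correct**, which for balanced
folds equals micro-averaged sensitivity; the macro average of the per-class
OvR accuracies is also exposed (`macro_ovr_accuracy`) but is a different,
systematically higher quantity — with one-per-class test folds of 10, each
misclassification costs 10 points of fraction-correct but only 2 points of
macro OvR accuracy. AUC uses raw ranks of per-class scores: vote fractions
for the forests, uncalibrated one-vs-rest decision values for the SVM (AUC
is rank-based, so calibration would be cosmetic).

**Cross-validation.** Repeated stratified k-fold: each repeat draws a fresh
stratified partition into $k = 5$ folds; each fold serves once as the test
set. The default 90 repeats give 450 train/test iterations — the minimal
reading that reconciles "5 subsets" with "450 iterations" — and with 10
classes × 5 replicates every test fold holds exactly one sample per class.
Reported metrics are arithmetic means over all iterations. Partitions and
model seeds derive deterministically from the config seed, so identical
inputs give bit-identical reports.

**Models.** Extra Trees and Random Forest are `ranger` forests
(`splitrule = "extratrees"` with the full sample and no bootstrap for the
former; bootstrapped Gini trees for the latter), exposing the sklearn-style
hyperparameter names `n_estimators`, `max_features`, `max_depth`,
`max_leaf_nodes`, `min_samples_split`, `min_samples_leaf`. `max_leaf_nodes`
is schema-validated but only its default (unlimited) is supported — no
installed R backend caps leaf count — and a finite value errors rather than
being silently dropped. The SVM is `e1071::svm` with `C`, `kernel`, `gamma`,
`degree`; multiclass labels come from its native pairwise voting, and OvR
AUC scores from one binary machine per class.

**SVM feature scaling.** Features reach the forests unscaled. For the SVM,
a *single global* center and scale (mean and sd over all entries of the
training fold) is applied. Per-channel standardization — the textbook
default for heterogeneous features — is wrong for spectra: all ~2000
channels share one physical unit, and standardizing each channel inflates
signal-free noise channels to the same weight as the analyte bands (in our
conditions it cost the SVM roughly 60 accuracy points on the
background-corrected scenario). The global affine map keeps relative band
structure intact while bringing raw-count magnitudes into a range where the
RBF kernel is non-degenerate.

**Grid search.** `grid_search()` evaluates the full Cartesian product under
the same repeated-CV protocol with identical fold partitions per arm (so
comparisons are paired) and returns the highest mean fraction-correct;
ties keep the earliest combination in enumeration order (keys sorted
alphabetically, values in listed order). Tuning is not nested inside an
outer CV — the tuned score is therefore an optimistic estimate, as it is in
the workflow this reproduces; this is documented rather than hidden.

## The comparison pipeline

`run_comparison()` applies each scenario's preprocessing once to the full
dataset, evaluates every model on every scenario with the *same* CV seed
(improvement rows are paired differences against root from the same run's
cells), and optionally fine-tunes all models on the best-scoring scenario by
grid search. `render_report()` emits a deterministic JSON document (a
serialization fixed point) or an aligned text table; provenance (seeds, CV
and preprocessing parameters, an MD5 of the dataset manifest) travels with
the report.

## Problem sizes used by the test suite

Unit tests run the generator at 256–512 points (the glucose bands stay
on-axis; forests and SVMs fit in milliseconds) with 1–3 CV repeats; the
end-to-end preprocessing-direction check runs the full 2048-point, 50-sample
design with 10 CV repeats (50 iterations per cell), and the acceptance
script does the same. These sizes are the package's chosen reference scale
for routine verification; the full 90-repeat protocol is a configuration
flag away (`cv_config(n_repeats = 90)`).

The null-calibration check estimates chance-level performance as the mean
over five independent label permutations: a single permutation interacts
with the CV partitioning and is a noisy draw of the null (it can land well
below nominal chance), whereas the mean over permutations is a stable
estimator of the same quantity.

## Known limitations

* Synthetic spectra are additive-Gaussian idealizations; results transfer
  to instrument data only to the extent the generator's assumptions hold.
* Under the default conditions the background jitter dominates the
  concentration signal, so root/hotspot accuracies sit near chance and the
  background-removal effect is large; on cleaner real data the gap would be
  smaller, and the *direction* of the effect is the tested claim.
* The default full-dataset preprocessing leaks test information into the
  hotspot mask; leakage-safe (fold-wise) preprocessing is supported but not
  the default, to stay faithful to the reproduced workflow.
* Multiclass accuracy aggregation conventions differ across reports; this
  package always states which quantity it prints (fraction-correct vs macro
  OvR accuracy) and exposes both.
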