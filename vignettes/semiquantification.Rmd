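---
title: "Standard-free semiquantification for SFC/ESI/HRMS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-free semiquantification for SFC/ESI/HRMS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcquant)
```

## The model

Electrospray ionization efficiency varies by orders of magnitude between
analytes, which is why peak areas from nontarget screening are not
directly comparable across chemicals. The workflow implemented here rests
on three linked regressions:

1. **Calibration.** For each chemical with a standard, the response
   factor is the slope of isotope-corrected peak area vs molar
   concentration over the linear range, in 1/M. Isotope correction
   divides the integrated monoisotopic peak area by the monoisotopic
   fraction, the probability that a molecule contains only
   lightest-isotope atoms (product over elements of abundance^count,
   IUPAC 2021 abundances). For small molecules (< 1000 Da) the main
   integrated peak is the monoisotopic one, so this fraction is the right
   correction; for heavier species the most-abundant isotopologue would
   differ, which is a documented limitation.

2. **Ionization-efficiency model.** A guided regularized random forest
   regresses log10 RF (or log10 IE, both base-10 throughout) on filtered
   molecular descriptors. The split gain of a descriptor `j` not yet used
   anywhere in the forest is multiplied by
   `lambda_j = (1 - coef_imp) * coef_reg + coef_imp * imp_j`, where
   `imp_j` is `j`'s importance in a preliminary unregularized forest,
   normalized to max 1. With `coef_reg = 1, coef_imp = 0` every
   `lambda_j = 1` and the model reduces exactly to a plain random forest
   (the test suite asserts this reduction). Performance is always
   reported out-of-fold: 10-fold cross-validation with folds stratified
   on the *rank* of the response, so each fold spans the whole RF
   distribution.

3. **Calibration transfer.** Predicted log IE values are relative, so a
   robust line `log10 RF = slope * log10 IE_pred + intercept` is fitted
   on the calibrant set by iteratively reweighted least squares with
   Huber weights (tuning constant 1.345 for 95% Gaussian efficiency,
   scale re-estimated each iteration as `median(|r|)/0.6745`, at most 50
   iterations, relative tolerance 1e-8). The test suite cross-checks the
   fit against `MASS::rlm`, the canonical implementation of this
   estimator, and verifies that a 10% fraction of gross outliers moves
   the Huber slope by under 5% while ordinary least squares fails that
   bound.

Prediction accuracy is scored with the error factor
`EF = max(c_hat/c, c/c_hat) >= 1`, whose log is `|log10 c_hat - log10 c|`;
it treats over- and underestimation symmetrically, which is what forces
the max-ratio form. Summaries aggregate per chemical (median over its
levels) before taking the median/mean across chemicals, and the
"under 10x" fraction requires *every* level of a chemical below 10.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `rel_residual_tol` | 0.2 | fraction | worst tolerated relative residual in the linear range |
| `replicate_rsd_tol` | 0.3 | fraction | replicate reproducibility bound; levels above it are excluded |
| `freq_cut` | 19 | ratio | near-zero-variance cut (95/5 most/second-most common value) |
| `cor_cutoff` | 0.75 | \|r\| | pairwise Pearson threshold for descriptor pruning |
| `mtry` | 86 | count | descriptors sampled per split (clamped to the surviving count) |
| `coef_reg` | 1.0 | (0,1] | base gain penalty for descriptors new to the forest |
| `coef_imp` | 0.5 | [0,1] | weight of importance guidance in the penalty |
| `n_trees` | 500 | count | ensemble size (300 in the heavier test scenarios) |
| `k_huber` | 1.345 | — | Huber constant, 95% efficiency at the Gaussian |

## Automated linear-range detection

The linear range is traditionally judged by eye from calibration-graph
residuals. The deterministic surrogate here first drops levels whose
replicate RSD exceeds 0.3, then fits a *relative-error weighted* least
squares line (weights `1/concentration^2`) to the mean areas and, while
the worst relative residual exceeds 0.2 and more than three levels
remain, removes the endpoint level with the worse relative residual
(preferring the higher concentration on ties, because detector saturation
at the top is the expected failure mode). At least three surviving levels
within tolerance are required, otherwise the chemical is flagged and
excluded downstream.

Two numerical points deserve emphasis. First, the detection fit is
weighted even though the reported RF is the *unweighted* OLS slope over
the retained levels: with multiplicative area noise and a 143-fold
concentration span, an unweighted fit's absolute residuals are dominated
by the top levels, which makes the bottom levels look disproportionately
bad relative to their tiny fitted values — and, worse, lets a flat
saturated plateau pass as a well-fitting "line". The `1/c^2` weighting
judges every level on the same relative scale and removes both artifacts.
Second, only endpoints are drop candidates, so the retained range stays
contiguous — which is what a linear range means physically.

## Eluent descriptors

Mobile-phase properties at the ESI inlet enter the model as features. The
gradient program (2% B held 1 min, ramp to 60% over 6 min, hold 4 min,
return within 0.1 min; 1.5 mL/min column flow; 200 uL/min water/IPA
90/10 makeup) is interpolated piecewise-linearly; the column flow is
split into CO2 and methanol by %B and mixed volumetrically with the
makeup flow. Properties use simple, swappable mixing rules over a
built-in 25 °C constants table: volume-fraction-weighted Snyder polarity
index and surface tension, log-linear viscosity. By default CO2 is
excluded from the composition (fractions renormalized over condensed
components) because it decompresses before ionization; whether a
measured-data workflow should include it is genuinely open, so the choice
is isolated in one flag (`include_co2`). The pH is recorded as the
aqueous-phase pH (7.0 for 20 mmol/L ammonium acetate) since the pH of a
water–organic mixture is ill-defined, and `nh4_present` is true for
ammonium-salt modifiers.

## What the synthetic generator emulates

`synth_config()` defaults encode the study conditions the package is
tested under: 127 chemicals; 8 geometric concentration levels from 12.2
to 1750 nmol/L in triplicate; true log RF spanning four decades
(anchored at 4.06e14–2.70e18 1/M via a unit-slope instrument map with
intercept log10(4.06e14)); 200 descriptors of which 5 are informative;
instrument noise `sigma_instrument = 0.15` log10 units; multiplicative
area noise `sigma_area = 0.1`; the top quarter of levels saturating; and
retention times weakly anticorrelated with log RF (target rho -0.29, the
weak negative dependence expected when later-eluting chemicals see more
organic modifier).

Design choices, made once:

* **Descriptor structure.** Non-informative descriptors follow a latent
  factor model (10 factors, one factor per descriptor, alternating tight
  and loose idiosyncratic noise), giving the realistic collinearity the
  correlation filter exists for. The informative descriptors are drawn
  independently of the factors: the descriptor-to-log-IE dependence is
  then genuinely sparse, and the planted signal is not smeared across
  whole correlated blocks (which would also make the correlation filter
  silently delete the ground truth the recovery tests need).
* **True log IE** is a linear combination of the informative descriptors
  affinely rescaled to span its target range exactly, so `beta_scale`
  controls only relative weights.
* **Saturation** is a hard plateau: above the top linear level the
  expected area freezes at that level's value. This is the simplest
  mechanism that makes residual-based range detection nontrivial.
* **Areas** are `10^logRF * c * monoisotopic_fraction * (1 + noise)`, so
  the isotope correction downstream is exercised and the noiseless
  dataset reproduces true RFs to machine precision.
* **`sigma_area = 0.1`**: the replicate-to-replicate noise model is not
  something the linear-range rule pins down; 30% is the reproducibility
  bound used for exclusions, and 10% is a typical well-behaved LC/SFC
  peak-area RSD, comfortably below that bound.

What it does **not** emulate: real PaDEL descriptor distributions
(discrete, skewed, block-wise redundant far beyond 10 factors), matrix
effects, adducts and in-source fragmentation, nonlinear ionization
suppression at high concentration (the plateau is a caricature of
saturation), or model misspecification — the true descriptor-to-IE map is
exactly linear and sparse, which flatters any regression. Passing tests
therefore demonstrate that the *machinery* is correct and internally
consistent, not that real SFC data will show a median error factor near
2.

## Numerical choices and degenerate inputs

* All logarithms are base 10, the ionization-efficiency literature
  convention.
* The forest response is centered before fitting and the mean added back
  at prediction. The regularized split-gain comparison in the underlying
  engine is sensitive to a large common offset (log RF lives near 16);
  without centering, any penalty below 1 collapses the forest onto a
  single descriptor.
* "Two-by-two repeated cross-validation" for hyperparameter tuning is
  read as 2-fold CV repeated twice (the standard reading of that
  scheme); the grid argmin is deterministic, first row winning ties.
* Correlation-filter ties (equal mean absolute correlation) are broken
  by column order, the earlier column surviving; correlations are
  recomputed against the shrinking kept set after every removal.
* Rank-stratified folds use ties.method "first", so ties are resolved by
  input order and the assignment is reproducible.
* Degenerate inputs fail loudly: identical calibrant log IE values
  (transfer), `ie_range_target` of zero width (generator), unknown
  elements (isotope table), mtry above the surviving descriptor count
  (clamped with a log message in the pipeline, an error in direct calls).
* A single-chemical synthetic dataset is supported (its log IE sits at
  the target midpoint) so one-row reports remain testable.

## Problem sizes

The test suite and the acceptance script run the full chain at the
default study conditions with 300 trees (the tuned `mtry = 86`,
`coef_reg = 1`, `coef_imp = 0.5`), three seeds for the recovery checks,
and the Monte Carlo study at its full 200 repetitions for calibrant
counts 5–20. Unit tests use smaller scenarios (10–60 chemicals, 8–25
descriptors) chosen so the property under test is sharp: e.g. the exact
forest-interpolation check uses two well-separated response clusters,
where bootstrap resampling almost surely retains both.

## Known limitations

* The isotope table covers C, H, N, O, S, P, F, Cl, Br, I; exotic
  elements raise an error rather than a silent 1.0.
* The pretrained LC-based ionization-efficiency model pathway is
  represented structurally (same API, transfer and evaluation procedure)
  but no published fitted weights ship with the package; predictions
  must be supplied or trained on local data.
* Eluent property mixing rules are deliberately simple (weighted means,
  log-linear viscosity) and are features, not thermodynamics; they are
  isolated behind `eluent_descriptors()` so better models can be
  swapped in.
* The Monte Carlo study samples calibrants uniformly at random, as the
  study design dictates; it does not search for optimal calibrant sets.
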