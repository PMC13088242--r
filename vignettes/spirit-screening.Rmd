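---
title: "Screening distillate fractions and quality analytes from ATR-FTIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening distillate fractions and quality analytes from ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiritspec)
```

## The problem

In single-batch spirit distillation (Pisco is the motivating case) the
distillate is collected in three consecutive fractions. Only the *body* is
bottled; the *head* carries high ethanol together with acetaldehyde and
esters, and the *tail* is dilute and accumulates furfural. Where to make
the cuts is traditionally decided by the distiller's senses, which is
slow, subjective, and — for the head fraction — a chronic exposure hazard.
A portable ATR-FTIR spectrometer pointed at the distillate stream offers
an objective alternative: mid-infrared absorbance carries the fingerprint
of ethanol, water, and the minor congeners (methanol, acetaldehyde,
acetic acid, furfural) that define quality and toxicity.

`spiritspec` implements the complete chemometric pipeline for this
setting:

* **SIMCA class modeling** assigns a spectrum to head, body, or tail —
  or to *no* class, which is how contaminated or mislabeled samples
  surface.
* **PLS1 regression** calibrates one model per quality parameter
  (ethanol % v/v; methanol, acetaldehyde, acetic acid, furfural, and
  titratable acidity in mg/100 mL) against reference values.
* A **synthetic spectra generator** stands in for instrument data, so the
  whole pipeline is testable end to end at realistic sample sizes.

## The synthetic data generator

No spectra are shipped with the package; they are simulated. The
generator is first-class, tested code, and its defaults define the study
conditions used throughout the tests.

**Concentrations.** Each fraction has reference summary statistics
(minimum, maximum, mean, SD) for the six quality parameters, determined
by GC-FID and titration on a production sample set of 188 distillates
(`fraction_distributions()`). Ethanol and the four congeners are drawn
independently per analyte from a normal distribution with the fraction's
mean and SD, truncated to the observed [min, max] by rejection. Body
ethanol, for instance, is `N(36.60, 3.05)` truncated to [31.43, 41.21] %
ABV. Two deliberate departures from full independence:

* Titratable acidity is *derived* as `1.1 x acetic acid` plus a small
  measurement-scale noise (SD 1.5 mg/100 mL, truncated at zero). TA has
  no spectral identity of its own; if it were drawn independently it
  would be unlearnable from spectra, whereas in real distillates it
  tracks the acids.
* Real fractions exhibit further cross-analyte correlations (acetic acid
  tracks ethanol through co-evaporation, for example). No joint law is
  available, so these are **not** emulated; this is a known limitation of
  the generator, and one reason a pipeline that passes these tests still
  needs validation on instrument data.

**Spectra.** Absorbance follows near-linear Beer-Lambert mixing on a
4000-650 cm^-1 grid at 2 cm^-1 spacing (the instrument's nominal
resolution is 4 cm^-1; 2 cm^-1 point spacing puts every region endpoint
on or within 1 cm^-1 of the grid). Each component contributes Gaussian
bands at its mid-IR assignments: the broad water O-H bands (3350, 1646
cm^-1), ethanol C-H and C-O bands (2974, 2928, 2886, 1087, 1045, 879),
methanol (2944, 2833, 1015), acetaldehyde (1715, 950), acetic acid
(1712, 1390, 1275), and furfural (1670, 1080, 1020, 880). Band centers
are anchored to published assignments; widths and heights are invented,
with heights scaled so congener features are one to two orders of
magnitude weaker than the ethanol/water features — mirroring mg/100 mL
versus percent-level concentrations. Water enters with volume weight
`1 - ethanol/100`.

**Noise.** Per-sample multiplicative gain (SD 1%), a random baseline
(offset within ±2e-3 absorbance, slope within ±1e-6 per cm^-1), and
additive white noise (SD 5e-4 absorbance). These magnitudes are small
enough that PLS recovery at the default settings is near-perfect; they
can be raised for stress tests. With noise off, synthesis is *exactly*
affine in the concentration vector, which the tests exploit as an oracle.

**Methanol spiking.** Real methanol concentrations span a narrow range,
so the adulteration protocol is emulated: 20 randomly chosen samples are
cloned and fortified with a uniformly drawn dose in [50, 70] mg/100 mL,
every dose distinct.

```{r example-sim}
s <- simulate_distillates(n_head = 14, n_body = 18, n_tail = 9, seed = 1)
s
```

## Preprocessing

The pipeline order is fixed: region selection, Savitzky-Golay second
derivative, optional sample 2-norm normalization, mean-centering. All
stages are pure and preserve sample order.

* **Regions** are closed wavenumber intervals; each retained region is a
  contiguous block, and the derivative filter never runs across a gap.
* **Savitzky-Golay second derivative** fits a local polynomial (order 2;
  for the central second derivative, orders 2 and 3 give the identical
  filter) in a sliding window and returns the second derivative at the
  center, scaled by `1/step^2` to physical units. Edges are truncated —
  `(window-1)/2` points per block end — rather than padded, to avoid
  fabricating curvature at region boundaries. The derivative suppresses
  baselines and broad water bands and sharpens overlapping peaks.
* **2-norm normalization** scales each spectrum to unit Euclidean length
  over the included variables, and is idempotent.
* **Mean-centering** always uses *training* column means; the mean vector
  is stored in fitted models and applied to future samples.

### Why normalization is off by default for PLSR

On spectra that are strictly Beer-Lambert with only ~1% gain variation,
the post-derivative norm in a congener's spectral window is essentially
proportional to the ethanol content (ethanol's sharp bands dominate every
fingerprint window, and broad water bands vanish under the second
derivative). Unit-norm scaling therefore turns a congener's signal into a
concentration *ratio* against ethanol — a nonlinearity that caps the
achievable validation correlation around 0.86-0.96 on synthetic data,
versus ~0.999 without it. On instrument data with substantial
path-length/contact variation the normalization earns its keep, so it
remains available per analyte (`pls_config(analyte, normalize = TRUE)`
or any custom `preprocess_config()`); it is simply not part of the
synthetic-study defaults.

## SIMCA class modeling

One principal-component model per fraction: class mean, `k` orthonormal
loadings, and a residual scale
`s0^2 = sum(residual^2) / ((n-k-1)(m-k))`. PCA is computed through the
n-by-n Gram matrix with two orthogonal-iteration refinement sweeps — the
training sets are much smaller than the variable count. The distance of
a sample to a class is its RMS orthogonal residual divided by `s0`
(training samples average about 1 by construction). This is the classic
residual-only variant: no score-leverage augmentation is applied.

Membership uses an F-test: a sample is accepted by a class when its
squared distance is at most the F critical value at `alpha = 0.05`
(configurable) with `(m-k, (n-k-1)(m-k))` degrees of freedom. A sample
accepted by no class is labeled `"none"` — the mechanism by which alien
samples (adulterated, mislabeled, or off-process) are flagged rather than
forced into a fraction. Ties go to the smallest distance, then to the
fixed class order head < body < tail.

The component count per class can be fixed (the defaults 3, 3, 2 are the
counts a comparable production study settled on) or chosen automatically
as the smallest `k` in `1..min(10, n-2)` minimizing the leave-one-out
SECV of reconstruction; the per-degree-of-freedom SECV normalization acts
as a natural tie-break toward smaller `k`.

Two study-level diagnostics accompany classification:

* **Interclass distance**: `d_ij = sqrt((d_i(j)^2 + d_j(i)^2)/2)`, with
  `d_i(j)^2` the mean squared normalized distance of class-`i` samples to
  model `j`. On this scale the self-distance baseline is about 1 (not 0),
  and the conventional `> 3` rule marks classes as distinct. This
  normalization is documented explicitly because commercial
  implementations do not publish theirs.
* **Discriminating power** per variable:
  `DP_v = sqrt(sum_{i!=j} s2_v,i(j) / sum_i s2_v,i(i))` with `s2_v,a(b)`
  the mean squared residual of class-`a` samples at variable `v` under
  model `b`; identical classes give 1, and the most class-separating
  wavenumbers attain the largest values. On synthetic fractions the
  854-910 cm^-1 primary-alcohol window ranks in the top decile, matching
  its role in separating head/body/tail.

A limitation worth knowing: because the distance is residual-only, a
sample of one class lying *along* another class's principal direction
(body spectra sit on the head model's ethanol-variation axis) can be
accepted by both classes. The soft "none"/multiple outcomes and the
interclass distance, not the hard label alone, carry the screening
information.

Classification quality is summarized by one-vs-rest confusion counts per
class plus pooled (micro) counts, with
`accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)`,
`specificity = TN/(TN+FP)`. A `"none"` prediction is a false negative for
the true class and a true negative everywhere else, so unmatched samples
never degrade specificity. Undefined ratios are reported as missing, not
as zero.

## PLS1 regression

The classical iterative (NIPALS) PLS1 algorithm with X-deflation only:
each parameter is modeled separately, so y-loadings are scalars. The
regression vector `b = W (P'W)^{-1} q` reproduces the factor-wise
prediction; at full rank PLS1 coincides with least squares, which the
tests assert against a pseudo-inverse oracle.

* **Factor selection**: leave-one-out cross-validation, implemented as
  the literal refit loop (every left-out sample, every candidate factor
  count, re-centered each time). The chosen count is the smallest
  minimizing RMSECV. The loop is exact by construction — the test oracle
  is the same computation written independently — and costs about
  `n x A_max` fits, a few seconds per analyte at n = 150.
* **Diagnostics**: leverage `h_i = sum_a t_ia^2/(t_a.t_a)` (summing to
  the factor count) and studentized residuals on `n - A - 1` degrees of
  freedom. A calibration sample is flagged when `|t| > 3` or
  `h > 3(A+1)/n`; flagged samples are removed and the model refit, for at
  most two rounds, after the calibration/validation split (validation
  samples are never touched).
* **Validation**: RMSEP, Pearson correlation `R_pre` (correlation, not
  R^2), and the residual predictive deviation `RPD = SD(reference)/RMSEP`
  with the usual interpretive bands — below 2 insufficient, 2-2.4 rough
  screening, 2.5-2.9 screening, 3.0-3.4 quality control, 3.5-4.0 process
  control, 4.1+ excellent for any application. The published band edges
  leave small gaps (1.9-2.0, 2.4-2.5, ...); the implementation closes
  them with half-open intervals at the lower edges.
* **Regions and windows** per analyte: ethanol 3071-2698 and 1208-715
  cm^-1 with a 35-point window; methanol 1200-900, acetaldehyde 1100-850,
  furfural 1200-800, acetic acid and TA 1800-1134, each with a 25-point
  window. All configurable.

```{r example-pls}
split <- split_calibration_validation(s, ratio = 0.8, seed = 2)
fit <- pls_analyte(s, "methanol", split = split, a_max = 6)
glance(fit)
```

The regression vector maps the coefficients back onto wavenumbers;
its largest magnitudes should sit on the analyte's bands (for methanol,
the C-O stretch near 1015 cm^-1):

```{r example-rv, fig.width = 6, fig.height = 3}
autoplot(fit$model)
```

## The full workflow

`run_all()` chains simulation, a stratified 80/20 split (calibration size
exactly `floor(0.8 n)`, per-stratum proportions within one sample), SIMCA
training/validation, six PLSR calibrations, and report assembly. A single
seed fans out to per-stage child seeds by fixed offsets, so any stage can
be rerun in isolation and the whole run is byte-for-byte reproducible.
Every reported statistic is recomputable from the exported CSVs.

## Numerical choices and degenerate inputs

* Truncated-normal sampling is by rejection with a bounded number of
  rounds; a degenerate window raises a typed error.
* Class-model residual distances use the explicit residual matrix rather
  than the norm-difference shortcut, which cancels catastrophically for
  samples lying in the class subspace.
* A zero-norm spectrum, a zero-variance response, an empty region, a
  region shorter than the filter window, duplicated sample ids, and
  mismatched grids each raise a typed error naming the offender rather
  than propagating NaNs.
* Exact prediction ties in classification are broken by class order;
  exact RMSECV ties by the smaller factor count.
* Perfect validation predictions report `RPD = Inf`; specificity with no
  negatives is missing, not zero; leverages of exactly 1 yield missing
  studentized residuals.

## Problem sizes used in the tests

Unit and property tests run on small constructed fixtures (tens of
samples, short grids). The end-to-end recovery checks use the reference
study's geometry: 67/89/32 samples per fraction, a 150/38 split, the
default noise model, and all six analytes; the SIMCA separation and PLSR
recovery runs complete in about a minute together. The distributional
fidelity checks use 400-2000 draws per fraction against analytic
truncated-normal moments.

## What passing tests do and do not show

The generator is linear, bands are Gaussian, noise is well-behaved, and
concentrations are (TA aside) independent across analytes. Passing the
recovery suite therefore demonstrates that the pipeline's algebra,
selection rules, and bookkeeping are correct — not that a portable
spectrometer in a distillery will achieve these figures. Matrix effects,
water-band temperature sensitivity, ATR contact variation, correlated
congeners, and instrument drift all live outside the simulation; on real
data, expect to revisit the normalization choice, the outlier thresholds,
and the per-analyte regions.
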