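---
title: "Methods: Raman chemometric urinalysis screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman chemometric urinalysis screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramscreen)
```

`ramscreen` implements a disease screen built on whole-spectrum chemometrics
of liquid urine: no single biomarker is quantified; instead the Raman
fingerprint of the urine metabolome is classified by a discriminant model in
principal-component space. This vignette documents the model, its tunable
parameters and their defaults, the numerical choices made where the design
was open, what the synthetic cohorts do and do not emulate, and the known
limitations.

## 1. Spectral preprocessing

Every replicate scan passes through four stages, in this order:

**Truncation.** Only the fingerprint region is analyzed. The window is
half-open, retaining points with 400 ≤ w < 1800 cm⁻¹, so that a 1 cm⁻¹
integer grid yields exactly 1,400 data points — the dimensionality the
screen was designed around. Grid spacing is treated as data-driven; nothing
assumes integer spacing.

**Baseline correction.** Urine fluorescence produces a smooth, broad
background modeled as a polynomial of order 3 (default). The fit must not be
attracted upward by Raman peaks, so ordinary least squares is replaced by
iteratively reweighted least squares under an asymmetric capped-quadratic
cost: residuals at or below a cap *s* keep full quadratic cost, residuals
above it are capped at *s*² (IRLS weight `(s/r)²`), which removes the
leverage of peak points while leaving below-baseline points fully weighted.
The cap is located by bisection so that the fraction of points treated as
peak-like (residual > *s*) matches the configured estimated peak ratio
(default 0.5). Inner iterations stop when the relative coefficient change
falls below `tol = 1e-6` or after `max_iter = 100` sweeps; non-convergence
flags the result rather than failing, since a slightly unconverged baseline
is still usable and the flag is auditable. The polynomial is expressed in an
orthonormal basis on a unit-scaled wavenumber axis for conditioning at any
order.

Before fitting, the spectrum is smoothed with a centered 5-point window
(default). The smoother is a local polynomial (Savitzky–Golay) fit of the
*baseline's* order rather than a plain moving average: a moving average
systematically biases curved baselines and its asymmetric edge windows break
the identity that a peak-free polynomial input should be returned as its own
baseline (the package tests require that identity to 10⁻⁶ of the input
range). A same-order local-polynomial smoother is polynomial-faithful
everywhere, including the edges, and is the standard smoother in
spectroscopy.

**Vector normalization.** Each corrected scan is scaled to unit Euclidean
norm, removing front-end intensity differences (laser power drift, optical
coupling) between scans. Normalization happens after truncation — the only
ordering consistent with the stated processing sequence — so the norm is
computed over the analyzed region only.

**Replicate averaging.** The ~10 scans per specimen are averaged pointwise
with equal weight, after normalization, giving one spectrum per specimen.
Averaging is skipped (`average = FALSE`) for the TPD analyses, which operate
on unaveraged replicate scans. Spectra are *not* mean-centered at this
stage; centering belongs to PCA.

## 2. PCA and discriminant analysis of principal components

PCA is computed by singular value decomposition of the column-mean-centered
intensity matrix (covariance scaling — spectra are already normalized, so
correlation scaling would only amplify noise at weak bands). At most
n − 1 components are kept for n spectra. Loadings carry a deterministic
sign convention (the largest-magnitude element of each loading is positive)
so results are bit-reproducible across linear-algebra backends.

DAPC fits Fisher canonical variates on the leading `n_pcs` PC scores:
min(k − 1, n_pcs) axes for k classes, maximizing between-class over
within-class scatter. PC scores enter the discriminant unstandardized; the
within-class scatter matrix in the Fisher ratio already accounts for scale,
and standardizing scores would silently reweight components. When the pooled
within-class scatter is singular it is ridged by 10⁻⁸ × its trace (falling
back to the total scatter scale when the within-class trace is itself zero,
as happens with deterministic toy data). Canonical axes are rescaled to unit
pooled within-class variance, so the canonical space is Mahalanobis-whitened
and classification reduces to the nearest class centroid in Euclidean
distance. Class priors are uniform — no prevalence weighting is assumed.

Exact classification ties are broken toward the earliest class in a
user-declared reference order (the leave-one-out engine places the pooled
negative classes first): a screen should fail toward
follow-up-by-gold-standard rather than at random.

## 3. Leave-one-out screening evaluation

The unit of cross-validation is the specimen (replicate scans having been
averaged). For each fold the held-out spectrum takes no part in the PCA
mean, loadings or discriminant fit of that fold — the models are refit from
scratch on the remaining k − 1 specimens. `n_pcs` must stay below
k − 2 so no fold is degenerate.

Multiclass predictions are tallied into binary screening counts: the
declared positive class versus everything else, with control specimens
(e.g. the synthetic urinalysis control fluid, class `"Surine"`)
participating in model fitting as their own class but excluded from the
confusion counts — the screen's operating characteristics concern patients,
not control fluids. Multi-class studies are evaluated one-vs-rest with the
other classes counted as negative. Ratios with a zero denominator are
reported as `NA`, never as 0. Metrics are kept at full precision internally
and rounded to one decimal only for reporting.

The PC sweep (`sweep_pc_counts`) repeats the analysis across model sizes and
annotates each row with the cumulative variance explained by those
components in the full-data PCA. Small models underfit (low sensitivity,
high specificity); large models overfit the folds; the interesting operating
points sit between.

## 4. TPD statistics

The total principal component distance reduces a spectrum *u* to
`TPD_u = Σ_{i=1..4} |P_u,i − P_ref,i|` against a reference spectrum
(default variant `abs_sum`). The published formula's typesetting is
ambiguous about the exponent's placement, so the squared variant
`Σ (P_u,i − P_ref,i)²` (`sq_sum`) is implemented as well; every result is
flagged with the variant used. The PCA for TPD is fitted on unaveraged
scans, and when the reference specimen has several scans its mean score
vector is used. TPD is invariant to the PCA sign convention only insofar as
reference and sample are scored in the same model — which the API enforces
by scoring both through one fitted model.

Group comparisons use classical one-way fixed-effects ANOVA and Tukey HSD
(studentized-range family-wise control), computed on full-precision TPD
values with group labels taken from metadata. Exactly constant inputs
produce rounding-noise sums of squares in any ANOVA routine, so degenerate
scatter is detected scale-awarely and reported as F = 0, p = 1 (ANOVA) or
p = 1 (Tukey pairs with equal means). In the storage-stability
configuration (reference = time-zero measurement, groups = storage weeks)
the reference week is the yardstick, not a comparison group: its scans sit
closer to their own mean score by construction, so the null-uniformity of
ANOVA p-values holds for the non-reference weeks.

## 5. Molecular signatures

The contribution of wavenumber w to a model direction is its absolute
weight as a percentage of the direction's total absolute weight, so each
component's contributions sum to exactly 100%. In PCA space the directions
are the loading vectors; in DAPC space they are the canonical axes mapped
back to wavenumber space (loadings composed with the canonical
coefficients). Absolute values are taken before normalization because the
sign of an axis is convention. Contributions above 0.3% (configurable) are
flagged as major and annotated against a built-in reference band table
within ±5 cm⁻¹. The direction of change (increase vs. decrease in disease)
is deliberately not reported: levels indicative of disease have not been
established for these bands.

## 6. The synthetic cohort generator

Clinical urine spectra are license-restricted, so validation runs on
synthetic cohorts with known ground truth. The generator emulates the
acquisition structure of the clinical studies: a 100–3000 cm⁻¹ grid at
1 cm⁻¹ (2,901 points, 1,400 after truncation), 17 positive and 39 negative
specimens by default, 10 replicate scans per specimen, per-specimen cubic
fluorescence baselines drawn uniformly from fixed coefficient ranges,
Gaussian bands at the signature wavenumbers (576, 702, 721, 817, 827, 846,
981, 1004, 1048, 1065, 1127, 1297, 1340, 1417, 1518 cm⁻¹) plus
class-neutral background urine bands (urea dominating at ~1001 cm⁻¹),
log-normal between-specimen peak-height jitter (sdlog 0.15), and additive
Gaussian scan noise (sd 0.3 a.u., about 0.5% of a typical spectrum maximum).
Default class effects are moderate multiplicative height shifts
(×1.15–1.30 on the disease-associated bands, ×0.8 on the carotenoid bands)
— the size of shift a metabolome-level difference plausibly produces, chosen
once as the package's study conditions. Each cohort uses one explicit seeded
RNG stream and restores the global RNG state; `null_cohort()` forces all
class effects to 1 while keeping labels, giving an exact no-signal control
under the same seed.

The truth record retains every specimen's baseline coefficients and
realized peak heights, so baseline-recovery tests compare against an
external truth rather than the pipeline's own output.

What the generator does **not** emulate: Lorentzian/Voigt line shapes,
shot-noise physics, instrument response and wavelength-calibration error,
cosmic-ray spikes, water/background subtraction artifacts, and the
correlated biochemical variation of real urine (creatinine-coupled
concentration scaling, diet, medication). Passing tests therefore
demonstrate that the algorithms recover planted structure under realistic
noise geometry — not that the screen reaches any particular clinical
performance on real patients.

## 7. Numerical and design notes

- Duplicate (specimen, scan) pairs are hard errors everywhere — silent
  overwrites would hide acquisition faults.
- `assemble_set(grid_policy = "intersect")` linearly interpolates onto the
  intersection range at the median native spacing; no extrapolation ever
  occurs, and `"strict"` mode never alters an intensity value.
- Spectra tables round-trip bit-exactly: numeric fields are written with 17
  significant digits.
- The JCAMP-DX reader is a thin adapter for single-block `##XYDATA=` in
  `(XY..XY)` or `(X++(Y..Y))` AFFN form; compressed encodings and vendor
  binary formats are out of scope.
- Planted-band recovery tests place the effect band at least 25 cm⁻¹ from
  the background bands: two bands 3 cm⁻¹ apart are not resolvable — after
  vector normalization their differential signal blends into one feature
  whose apex can sit past a ±5 cm⁻¹ window, which is a property of the
  physics, not of the estimator.
- Monotonicity of training-set performance in `n_pcs` is asserted on the
  leading canonical eigenvalue (a Rayleigh quotient over nested subspaces,
  hence provably monotone); 0/1 resubstitution accuracy tracks it only up
  to single-specimen flips.
- Test and validation problem sizes: unit tests run cohorts on coarser grids
  (2–8 cm⁻¹ steps) and small specimen counts; the chance-rate calibration
  pools 200–400 held-out specimens across seeded full-scale null cohorts
  (20 + 20 specimens × 10 scans, 1 cm⁻¹ grid), the scale at which the
  Monte-Carlo error of a pooled accuracy is ~2.5 percentage points.

## 8. Known limitations

- The discriminant is linear; nonlinear class boundaries are out of scope.
- No ROC/AUC machinery: operating points are explored by sweeping `n_pcs`.
- Leave-one-out is the only cross-validation scheme (it matches the
  published evaluation); k-fold variants are not provided.
- At the null, leave-one-out accuracy sits slightly *below* 50%: removing a
  specimen shifts the training means away from it, a small, well-known
  pessimistic bias of leave-one-out with nearest-centroid-type rules. The
  calibration band (±5 percentage points around chance) absorbs it.
- The Goldindec-style baseline fit follows the published parameterization
  (order, peak ratio, window) but reconstructs the unpublished internals
  (cost shape, cap search) from the algorithm's description; it is validated
  by recovery of known synthetic baselines to well under 2% of baseline
  range, not by equivalence to any proprietary implementation.
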