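---
title: "Methods: synthetic vineyard hyperspectral trait retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic vineyard hyperspectral trait retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hypervine)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. No empirical number is stated here that the
test suite or `scripts/acceptance.R` does not itself compute.

## The pipeline in one paragraph

A frame hyperspectral camera over a vineyard yields a 50-band DN hypercube
(500–900 nm, ~8 nm FWHM, ~2 cm GSD). The package converts DN to radiance
(factory gains, dark current), radiance to reflectance via the empirical
line method fitted on five reference panels, segments the canopy with a
height model plus a NIR shadow/soil filter, averages the masked spectra in
a 0.8 × 0.8 m square per sample vine, and retrieves thirteen vine traits
three ways: univariate regressions on 37 narrowband/derivative vegetation
indices, full-spectrum partial least squares (PLS), and forward
interval-PLS wavelength selection.

## The synthetic cohort

No raw data of this design are publicly deposited, so the package
generates its own, and the generator is first-class, tested code.

**Trait marginals.** Each of the 13 traits is specified by a mean, a
`[min, max]` range and a coefficient of variation (`default_trait_spec()`;
units MPa, m²/vine, kg/vine, g, °Brix, g/L, mg/g). Draws come from a
normal distribution truncated to the range. Truncation removes variance,
so the parent parameters `(μ, σ)` are solved numerically per trait so that
the *post-truncation* mean equals the target exactly (a monotone
one-dimensional root in μ for each σ) and the post-truncation sd is as
close to the target as the family allows (a one-dimensional optimum in σ).
One trait, must malate (mean 2.13 g/L, CV 56.8 % within 0.75–5.99 g/L),
sits just outside the family: the supremum CV of a truncated normal with
that mean and range is ≈ 56.0 %, approached as σ → ∞ (the exponential-tilt
limit). The calibration therefore matches the malate mean exactly and
realizes a CV about one point short of the target — within the tolerance
the calibration checks use, and a documented family limit rather than a
solver failure.

**Joint structure.** Only marginals are specified by the source material,
so the correlation matrix is a modeling choice
(`default_trait_correlation()`): vigor descriptors (leaf areas, pruning
weight, yield components) are positively correlated; pre-dawn water
potential is negatively correlated with vigor and positively with mid-day
potential; malate, anthocyanins and phenolics move together, against
soluble solids, and with acidity. Sampling uses a Gaussian copula:
correlated standard-normal scores pushed through each trait's truncated
quantile function, so ranges are respected exactly while marginal moments
converge to the calibrated targets. Every stochastic operation takes an
explicit integer seed and runs on a private RNG stream
(`with_seed()`), leaving the caller's `.Random.seed` untouched.

**Canopy forward model.** Per-vine reflectance is
`R(λ) = v + (N − v)·logistic((λ − λ_re)/w) + g·exp(−(λ−550)²/(2·15²))`
with visible baseline `v = 0.05`, NIR plateau `N = 0.45` at cohort-mean
traits, red edge at `λ_re = 715 nm` (width 12 nm) and green bump
`g = 0.04`. The planted couplings are the package's invertible ground
truth: `N` rises by 0.04 per m² of total leaf area and 0.25 per MPa of
pre-dawn potential (less stress → brighter NIR); `λ_re` shifts 20 nm/MPa
(stress moves the red edge to shorter wavelengths); `g` tracks a
standardized vigor composite at 0.012 per z-unit. Multiplicative lognormal
noise (default sd 0.02) emulates residual variability; all spectra are
clipped to (0, 1). These coupling scales were chosen once so that trait
effects span a few percent reflectance over the cohort ranges — visible
but not dominant — and are config, not constants.

**Scene.** Six north–south rows of ten vines at 2.4 × 1 m spacing, canopy
strips 0.6 m wide and 1.8 m tall on flat ground, a 0.4 m shadow strip east
of each row carrying the nearest vine's spectrum times a 0.25 shade
factor, grass strips mid inter-row, bare soil elsewhere, and five
0.5 × 0.5 m panels (2/9/25/50/88 % reflectance) in the southern margin.
DN formation is `round(gain_b · E_b · R + dark_b + noise)` with a smooth
solar-like illumination curve `E(λ)` and per-band gains; setting noise to
zero and disabling quantization gives the exact configuration used by the
round-trip tests. Rasters live in a local metric, north-up, pixel-center
frame; no geodetic CRS is used or needed.

**What the generator does not emulate** — and hence what passing tests do
*not* show about field data: no radiative transfer (no PROSPECT/SAIL leaf
or canopy physics), no BRDF or view-angle effects, no atmosphere, no
mixed-pixel gradients at canopy edges (class boundaries are crisp), iid
band noise rather than structured sensor noise, a single acquisition date,
and trait–spectrum couplings that are exactly monotone by construction.
Retrieval scores on the synthetic block (cross-validated R² up to ~0.98)
are therefore upper bounds that certify the *machinery*, not the
field-achievable accuracy.

## Radiometric calibration

`L_b = gain_b · (DN_b − dark_b)` per band, dark subtracted in the DN
domain by default — processing chains state this order both ways, so a
`dark_domain` switch records the alternative (the two are algebraically
identical for an affine sensor). Negative radiances (DN below dark) are
preserved and reported, not clipped: downstream filters decide validity.
The empirical line is an ordinary least-squares fit of known panel
reflectance on observed mean panel radiance, per band, with panel means
taken over the rectangle eroded by one pixel to avoid boundary mixels.
`apply_elm()` is affine per band; the optional `"unit"` clip policy logs
the clipped fraction. On a noise-free scene the whole chain is exact to
machine precision, and the test suite asserts ≤ 1e−8 on panels and
≤ 1e−6 per scene pixel.

## Segmentation

The ground model is a moving-window low-percentile surface of the DSM:
window 4.8 m (twice the row spacing, so every window sees inter-row
ground), 5th percentile. For large windows the percentile is evaluated
exactly on a strided grid of pixels and bilinearly interpolated between
evaluation points (`stride = 1` is the exact brute-force moving window and
is what the oracle tests use; the default auto-stride is window/6). The
CHM is DSM − ground floored at zero. The mask is
`CHM > 0.5 m AND R(band nearest 800 nm) > 0.15`; the source material gives
no numbers for these thresholds, so the defaults are declared package
choices, all configurable. A shadow threshold of 0 reduces the mask to
the height rule. Pixel-in-polygon uses pixel-center containment
(deterministic); ROIs with zero masked pixels are excluded with a warning
rather than failing the run.

## The index registry

All printed index formulas are implemented *verbatim*, including the
places where they differ from the literature's canonical forms — the
artifact reproduces the source table, not the literature:

* **NDVI1 and NDVI3** are printed with identical formulas and kept as two
  entries that are always exactly equal.
* **NRER** is printed twice with the same formula and collapsed to one
  named entry (flagged `printed_twice` in `vi_registry()`), giving 37
  distinct entries covering 38 printed rows.
* **NDRE** is printed with an unbalanced parenthesis; the normalized
  difference of the printed band pair (770, 750) is the only reading
  consistent with the table's pattern.
* **REP** keeps the printed arithmetic `700 + (45·R670 + R778)/2 −
  R850/(R735 − R695)`, which is structurally unlike the canonical
  linear-interpolation red-edge position; it is reported as printed.
* **EVI** as printed places the `+1` outside the ratio, which makes the
  formula homogeneous of degree zero — i.e. exactly scale-invariant,
  unlike canonical EVI. The tests assert the printed formula's true
  behavior.

Nominal wavelengths resolve to the nearest band center within one FWHM
(8 nm); on the default grid the largest gap is ~4.1 nm so every cited
wavelength resolves. Derivative-window indices (`Max/Σ [D_a, D_b]`)
default to all grid bands whose centers lie in `[a, b]` (2–3 bands),
because a "derivative max" index implies a window search; a `"pair"` mode
restricted to the two named bands is available. Division by exactly zero
yields `NA` with a warning, never an error; per-ROI averaging in
`"index-mean"` mode skips undefined pixels and only returns `NA` when all
pixels are undefined. The two aggregation orders — index-then-average
(used for the index table) and average-then-index (used for the
chemometrics dataset) — are both exposed and agree exactly on uniform
fields; their difference on heterogeneous ROIs is the Jensen gap of the
index nonlinearity.

## Chemometrics

**PLS** is classical single-response NIPALS with deflation on the
mean-centered data; centering vectors are stored in the model and applied
at prediction. With as many latent variables as the centered rank, the
fit coincides with ordinary least squares (asserted to 1e−6 against the
normal-equations oracle); an installed independent implementation
(mixOmics) is used as a numerical cross-check in the tests, never as the
implementation.

**Cross-validation** uses balanced random deletion groups (`cv_plan()` is
a pure function of `(n, k, seed)`; k = 3 by default, so n = 30 gives
10/10/10). Centering is refit inside every training fold by default (no
leakage); a `"global"` switch reproduces toolboxes that center the full
matrix once. RMSECV pools held-out predictions over all folds; the LV
count minimizes RMSECV with ties to fewer LVs. `r2_cv = 1 − PRESS/SS_tot`
(which can be negative) is the default definition; the squared correlation
alternative is a switch. `lv_max` defaults to `min(10, ⌊n/3⌋)` to keep
small training folds from overfitting.

**Forward iPLS** partitions the 50 bands into intervals of 10 or 5 (a
non-divisible remainder is absorbed by the last interval with a warning),
starts from the single best interval by RMSECV — the LV count re-optimized
for every candidate set — and greedily adds the interval with the largest
RMSECV reduction, stopping when no addition strictly improves. The stop
rule and the forced first pick are declared choices (the source does not
state them); so is re-optimizing LVs per candidate. Ties break
deterministically: fewer LVs, then lower interval index, then fewer
variables. Selected intervals are reported as nm ranges
(`"start:end"`, adjacent intervals merged, centers rounded to integer nm).

**Univariate table.** Per (index, trait) cell: OLS slope, intercept, R²,
the two-sided p of the slope F test, and the four-class ladder
`p<0.0001 / p<0.001 / p<0.01 / ns`. Traits measured on a subset (the
water potentials, observed on 30 of 60 vines) use only their subset. No
multiple-testing correction is applied — the matrix is reported raw, as in
the source design, and this is deliberately documented rather than
silently "fixed".

## Numerical choices and problem sizes

Tolerances: NIPALS stops when the residual covariance norm falls below
1e−12; score orthogonality is asserted at 1e−8; exactness checks use
1e−6/1e−8 as stated above. Ties everywhere resolve by `which.min`'s
first-minimum rule, i.e. toward the smaller model. The copula factor uses
an eigenvalue square root tolerant of semi-definite matrices. The test
suite runs on reduced problem sizes chosen as package defaults: a
3-row × 5-vine scene for raster-stage tests, the full 60-vine block for
the demo configuration, n = 10,000 draws for generator calibration, 200
replicates for LV-selection consistency and 100 for interval recovery.

## Known limitations

Univariate p-values are not corrected for the 37 × 13 grid of tests; the
iPLS search is greedy forward only (no backward or synergy variants); the
ground model assumes the low percentile of every window reaches true
ground, which fails for very wide canopies or steep terrain; GeoTIFF
georeferencing is out of scope (rasters carry a local metric frame in a
JSON sidecar); and all validation is against the synthetic generator —
field performance is expressly not claimed.
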