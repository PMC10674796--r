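---
title: "Methods: delineating and validating management zones from soil ECa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineating and validating management zones from soil ECa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecazones)
```

`ecazones` chains four statistical stages — variography and kriging of a
soil apparent electrical conductivity (ECa) survey, unsupervised zoning of
the kriged surface with elevation, fusion of soil-property tables into a
latent soil-fertility measure, and nonparametric zone comparison. This
vignette documents the models, their assumptions, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## Geostatistics

**Model.** ECa is treated as an intrinsically stationary random field: the
semivariance γ(h) = ½ E[(Z(x) − Z(x+h))²] depends only on the lag h
(isotropy is checked, not assumed — see below). The experimental variogram
is the method-of-moments estimator per lag bin; a spherical model

γ(h) = c₀ + c (1.5 h/a − 0.5 (h/a)³) for 0 < h ≤ a, γ(h) = c₀ + c beyond a

is fitted by weighted least squares with Cressie weights
N_k / γ_model(h_k)², which down-weight bins the model itself says are
noisy. Fitting uses `stats::optim` (L-BFGS-B, parameters bounded
nonnegative) from five deterministic multistarts; the criterion a
commercial GIS uses is not published, so WLS was chosen as the standard,
defensible alternative. A near-flat variogram is reported as pure nugget
with `range_identifiable = FALSE` rather than returning an arbitrary range.

**Kriging.** Ordinary kriging assumes an unknown, locally constant mean;
the unbiasedness constraint Σwᵢ = 1 eliminates it, which is why the solver
works directly in semivariance form with a Lagrange multiplier. Each target
location uses its `max_neighbors` (default 16) nearest points within
`search_radius` (default 1.5 × range): with ~2,000 survey points,
neighbourhood systems are orders of magnitude faster than the full solve
and, by a package invariant verified in the tests, identical to it when the
neighbourhood spans all points. Kriging variances that come out a hair
negative from floating-point cancellation are clipped at zero with a
warning. Co-located duplicate points are averaged first, because they make
the kriging matrix singular.

**Diagnostics.** Leave-one-out cross-validation reports RMSE, mean error,
mean kriging standard error and the mean standardised error
mean((Z* − Z)/SE); on data truly generated from the fitted model the
standardised errors should have mean ≈ 0 and mean square ≈ 1, which is
exactly what the calibration test checks. The nugget/sill ratio
100·c₀/(c₀+c) is classified by the conventional thresholds (≤ 25 % strong,
25–75 % moderate, > 75 % weak); the boundaries are arguments, since field
studies often read "about 25 %" as strong. Normality of the survey is
summarised (skewness, kurtosis, CV) but never enforced — it is not a
prerequisite for kriging.

**Anisotropy.** The anisotropy ratio is the largest over smallest fitted
range across `n_directions` directional variograms. Sector tolerance is
90°/n_directions; with only two directions the 45° sectors smear a true 2:1
geometric anisotropy down to about 1.5, so four directions are the
practical minimum — the package default. Ratios below 1.5 are conventionally
treated as compatible with isotropy.

**Defaults the user may care about.** Lag width defaults to twice the mean
nearest-neighbour distance and the maximum lag to half the maximum pairwise
distance — standard variography folklore that keeps early bins populated
and excludes the erratic long-lag tail.

## Zoning

Kriged ECa (mS/m) and the DEM (m) are z-scored per layer before clustering;
without standardization the ECa magnitude would swamp elevation entirely.
Clustering is an ISODATA-style k-means: the split/merge phase is disabled
because the number of zones is fixed a priori (a practical choice — growers
want two or three zones), and initial centres are placed deterministically
at the per-feature quantiles (2j−1)/2k, so the clustering is reproducible
without a random start. The converged classes provide Gaussian signatures
(mean, covariance; regularised by εI if near-singular) for a
maximum-likelihood classifier, whose assignment — argmax of log prior +
Gaussian log-density, ties to the lowest index — is deterministic. Class
priors are equal by default (nothing in a survey justifies informative
priors). Zones are finally relabelled by ascending zone-mean ECa, so label
1 is always the least productive zone; this is a pure relabelling and the
cell partition is untouched. No spatial smoothing is applied by default:
a fragmented productive zone is information, not noise.

Validation samples are allocated to zones by largest-remainder
apportionment of zone areas with a floor of one sample per zone — with
areas 35/45/20 % and 20 samples this gives 7/9/4 — and placed uniformly at
random within zone cells under a fixed seed.

## Latent soil fertility

Nine properties per sample (sand, clay, silt, organic matter, pH, P₂O₅,
K₂O, sum of exchangeable bases, cation exchange capacity) are rated 1–5 per
item — equal intervals over the observed range by default, quantile bins or
injected cut points as alternatives, with per-item polarity flags so that
e.g. high sand content maps to *low* fertility. The mapping table is always
returned: categorisation is the least standardised step of this kind of
analysis and must be auditable.

The ratings are fused by the Andrich rating-scale model,
P(X_{ni} = k) ∝ exp Σ_{j<k}(B_n − d_i − τ_j): one fertility measure B_n per
sample, one difficulty d_i per item, and m − 1 thresholds τ shared across
items — appropriate because all items use the same deliberately uniform
5-category scheme (the partial-credit model, with per-item thresholds,
is out of scope). At m = 2 the model reduces bit-exactly to the dichotomous
Rasch form P = e^{B−d}/(1+e^{B−d}).

**Estimation.** Joint maximum likelihood: damped Newton updates alternately
equate observed and expected raw scores for persons, items and category
counts, until the largest score residual is below 0.01 and no parameter
moves more than 0.001 logits. Identification needs *two* constraints here:
item difficulties are centred to mean 0, and thresholds are centred to mean
0 — a common shift of all thresholds trades exactly against the person
location, so centring d alone leaves the scale adrift. Persons with extreme
raw scores (minimum or maximum possible) have no finite ML estimate; their
scores are pulled 0.3 score points inward and solved against the final
calibration, flagged `extreme`. Threshold disordering is reported, never
forced away. No small-sample bias correction is applied — JMLE measures are
known to be biased outward at small N, which matters at a 20-sample
validation campaign; this is why the package's recovery tests run at
N ≥ 200 and why 20-sample zone means should be read as ordinal evidence,
not precise logit values.

**Fit.** With standardised residuals z = (X − E)/√W (E, W the model mean
and variance of the category score), Outfit is the plain mean of z² and
Infit the information-weighted Σ W z²/Σ W; both ≈ 1 under the model, with
the conventional 0.6–1.5 acceptance band. Extreme persons and zero-variance
cells are excluded from the sums — they carry no fit information.

## Zone comparison

Kruskal–Wallis (tie-corrected, via `stats::kruskal.test`) provides the
omnibus test; Dunn's rank-based z statistics the pairwise follow-up, with
no multiplicity adjustment by default at α = 0.01 (the strict α plays the
role of the correction, matching common practice in this literature;
Bonferroni and Holm are options). For two groups Dunn's z² equals H
exactly — a property the tests verify symbolically on tied data. Compact
letters come from an insert-and-absorb algorithm whose output is checked
exhaustively against all significance patterns for k = 3. NDVI is
(B8 − B4)/(B8 + B4) from Sentinel-2 reflectances; only the standard
two-band form is implemented, since no published formula combines the
20 m bands 8A/11 into NDVI.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical* structure the analysis assumes:
a stationary Gaussian ECa field with spherical correlation (Cholesky below
10⁴ cells, circulant embedding with clipped near-zero eigenvalues above),
nugget realised as iid noise; parallel-transect surveys with logged
corruption (negated or ×10 values mimicking metal interference); a planar
plus sinusoidal DEM; contiguous zone bands from thresholding a smooth
spatial score; and 5-category responses drawn from the rating-scale model
with zone-shifted fertility. Soil chemistry is *back-constructed* from the
drawn categories inside the stored cut-point bins, so categorisation and
fitting are exactly consistent; the texture triple is closed to 100 % by
deriving silt as the remainder, whose category is then recomputed from the
constructed value. The generator does **not** attempt realistic
inter-property correlations, instrument depth response, GPS error, or
non-stationary trends, so passing recovery tests demonstrate correctness of
the estimators under their own assumptions — not robustness to real-world
violations of them.

**Default scenario.** 60 × 60 cells of 10 m (a ~36 ha block, large enough
to hold several 130 m correlation ranges), field mean 46.8 and SD
27.13 mS/m with 26 % nugget fraction and 130.4 m range — the exploratory
statistics of a real vineyard ECa survey; transects every 20 m sampled at
10 m with 2 mS/m noise and 2 % corrupted records; three zones whose ECa
means step by 1.5 residual SD and which track topography with a 1.5 m
elevation step on a gently undulating DEM (≈1 m amplitude, 0.5 % slopes).
Both layers must carry zone signal for two-layer delineation to work: zone
recovery is a property of the whole feature space, and a second layer that
is pure noise actively degrades Euclidean clustering. Twenty soil samples
are allocated by area, with zone fertility shifts (−1, 0, 1) logits and 0.5
logits within-zone SD. These sizes keep the full pipeline under ~10 s and
the entire test suite under a minute while leaving every recovery property
comfortably measurable.

## Numerical choices and degenerate inputs

* ESRI ASCII rasters are written with 15 significant digits — round trips
  are lossless at double precision; `NODATA_value` cells become `NA`.
* TIN gridding uses a hand-implemented Bowyer–Watson Delaunay triangulation
  (coordinates centred and scaled first for conditioning) with barycentric
  interpolation; it reproduces any affine surface exactly at in-hull cell
  centres. Cells outside the convex hull are `NA` unless nearest-neighbour
  fill is requested. Collinear point sets are an error.
* Singular kriging neighbourhood systems (after duplicate averaging these
  are numerical, not structural) get a 10⁻¹⁰ ridge.
* Empty clusters trigger one seeded random restart, then an error.
* Constant items, all-extreme matrices, empty zones, zero-range cleaning
  bounds and unknown config keys all fail loudly with specific messages.

## Known limitations

Only the spherical family (plus pure nugget) is fitted; universal and
co-kriging are out of scope, as are CRS transformations (coordinates are
assumed planar metres), GeoTIFF I/O, automatic selection of the zone count,
fuzzy or contiguity-constrained clustering, partial-credit Rasch models and
conditional/marginal ML estimation. JMLE bias at small N is documented
above. The exact behaviour of the commercial tools this workflow is usually
run in (GIS variogram fitting, TIN edge rules, ISO Cluster internals) is
not reproduced — the package implements the published, documentable form of
each step instead.
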