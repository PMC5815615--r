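---
title: "Geostatistical methods for tree-ring isotope isoscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical methods for tree-ring isotope isoscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(isokrig)
```

## The problem

Stable isotope ratios of oxygen (δ¹⁸O) and hydrogen (δ²H) in tree-ring
cellulose carry a geographic signature: source water becomes progressively
depleted in the heavy isotopes with altitude and latitude, so wood formed at
different places records different values. An *isoscape* — a spatially
continuous map of the expected isotope value — turns a set of point
measurements at sampled forest stands into a prediction surface against
which timber of unknown origin can later be compared. `isokrig` implements
the geostatistical workflow that builds such surfaces from a per-site table
of pooled tree-ring isotope values: exploratory screening, variogram
modelling, four kriging variants, leave-one-out cross-validation, and the
final prediction grids with 95% confidence surfaces.

All coordinates are projected metres (UTM-style); every distance in the
package is Euclidean, and no geographic (lat/lon) arithmetic occurs
anywhere.

## Model and assumptions

The isotope value at location $s$ is modelled as

$$Z(s) = m(s) + \varepsilon(s),$$

where $m(s)$ is a mean function and $\varepsilon$ a zero-mean intrinsically
stationary random field summarized by its semivariogram
$\gamma(h) = \tfrac12\,\mathrm{E}[Z(s) - Z(s+h)]^2$. Four parametric
families are supported: spherical, exponential, linear (unbounded, slope
parameter), and Matérn with Stein's parameterization

$$\gamma(h) = c_0 + c\left(1 - \frac{2^{1-\kappa}}{\Gamma(\kappa)}
\left(\frac{h\sqrt{2\kappa}}{a}\right)^{\kappa}
K_{\kappa}\!\left(\frac{h\sqrt{2\kappa}}{a}\right)\right),$$

which reduces to the exponential model at $\kappa = 1/2$ (a Bessel-function
identity the test suite checks to $10^{-9}$) and approaches a Gaussian
model as $\kappa \to \infty$. The nugget $c_0$ absorbs measurement error
and micro-scale variation — including the within-site spread of the five
pooled trees per stand, which is not modelled explicitly.

Kriging assumes approximately Gaussian variables, so a descriptive gate
(Shapiro–Wilk, skewness, excess kurtosis; `describe_variables()`) runs
before any variogram is fitted. Spatial dependence is screened with
Moran's *I* under inverse-distance, row-standardized weights with a
permutation test; the weighting scheme is a package default — the field
uses many — and is configurable by distance cutoff.

## Variogram estimation and fitting

`empirical_variogram()` bins squared half-differences with a default lag
width of 2,500 m (the typical inter-site spacing of the intended sampling
designs) up to a default maximum distance of one third of the largest
inter-site separation, a standard compromise between bias and pair count.
Directional variograms and `variogram_map()` diagnose anisotropy; the
final models are isotropic, because in the motivating data the anisotropy
is weak, and a geometric-anisotropy correction is out of scope.

Models are fitted by weighted least squares with weights $N(h)/h^2$
(pair count over squared lag), the common default that privileges the
well-populated short lags that matter most for kriging; `N(h)`, Cressie
and equal weights are available. The optimizer works in scaled units
(sills relative to a data-driven scale, range relative to the maximum lag)
with multistart, because raw metres and squared permil differ by four
orders of magnitude and unscaled quasi-Newton steps stall. The Matérn
shape κ is profiled on a log grid over [0.05, 10] and then refined jointly.
Reported diagnostics are the unweighted RSS over bins and
$AIC = m\log(RSS/m) + 2k$; `select_model()` takes the lowest AIC with
ties broken by RSS, then parsimony. The nugget is initialized from the
first bin but remains a free parameter of the fit.

For universal kriging the residual variogram is used: the linear or
quadratic coordinate trend is removed by least squares (on centred, scaled
coordinates for conditioning) and the variogram is re-estimated from the
residuals — the standard practice when a trend is present.

## Kriging systems

All solvers work in semivariance form,

$$\begin{pmatrix} \Gamma & F \\ F^\top & 0 \end{pmatrix}
\begin{pmatrix} \lambda \\ \mu \end{pmatrix} =
\begin{pmatrix} \gamma_0 \\ f_0 \end{pmatrix},
\qquad \sigma^2 = \lambda^\top \gamma_0 + \mu^\top f_0,$$

which handles the unbounded linear model natively under the unbiasedness
constraints. $F$ is a column of ones for ordinary kriging (KriO) and the
monomial basis up to the trend order for universal kriging (KriL, KriQ).
Cokriging (CoK) solves the joint system for the primary variable and a
standardized covariate under a linear model of coregionalization, with the
two constraints $\sum\lambda_{\text{primary}} = 1$,
$\sum\lambda_{\text{covariate}} = 0$. The LMC is fitted by per-structure
weighted least squares with positive semidefiniteness enforced by
eigenvalue clipping and refitting (a Goulard–Voltz-style sweep, at most
100 iterations, tolerance $10^{-8}$); the fit records whether the PSD
constraint was binding.

Numerical choices: predictions use a global neighbourhood (all sites per
solve — the intended n is ~151, so no moving window is needed); data
locations are reproduced exactly with zero kriging variance even under a
nonzero nugget (the dominant software convention; the alternative
"noisy-data" reading would return $\sigma^2 = c_0$ there); singular
systems get one retry with a $10^{-10}\cdot\text{sill}$ diagonal jitter,
then fail loudly; duplicate coordinates are an error and must be averaged
upstream (`read_site_table()` does this with a warning).

Every solver is cross-checked in the test suite against an independent
brute-force BLUP written in covariance form (direct KKT construction and
solve), to $10^{-8}$ on hundreds of random small instances.

### Co-located versus collocated cokriging

Two cokriging data configurations exist. In the strictly *co-located*
default (`cok_predict()`), the covariate is observed only where the
primary variable is. In *collocated* mode the covariate value at the
prediction location joins the system as an extra observation — the natural
choice when the covariate is an exhaustive surface such as a LiDAR DEM.
The distinction matters for cross-validation: with strictly co-located
data, a secondary variable sampled at exactly the primary's sites is
nearly redundant and cokriging hugs ordinary kriging; with the covariate
retained at the held-out site, cokriging uses genuinely extra information
and consistently dominates. Because the altitude covariate is of the
exhaustive kind, the pipeline's LOOCV defaults to the collocated reading
(`cok_collocated = TRUE`), and the dominance property in the test suite is
stated for that mode. Grid prediction uses the strictly co-located system
unless a covariate raster is supplied (`covariate_grid`).

## Cross-validation and model choice

`loocv()` removes one site at a time and predicts it from the rest, with
the variogram/LMC fitted once on all data and frozen across folds (the
near-universal software behaviour; a full refit per fold would be
prohibitive and changes little at these sample sizes). Two diagnostics
are reported: RMSE in permil, and MSDR — the mean of squared errors over
their kriging variances — which equals 1 for a correctly specified model.
`rank_models()` selects the method whose MSDR is closest to 1, breaking
near-ties (within 0.005) by lower RMSE; both orderings are visible in the
returned table because the two criteria can disagree.

The MSDR calibration property is itself the package's headline acceptance
check: simulating Gaussian random fields from a known spherical model
(nugget 0.2, partial sill 1, range 30 km) at 151 sites and cross-validating
with the true model yields a mean MSDR within [0.9, 1.1] over 200
replicates (`scripts/acceptance.R` recomputes this; a typical run prints
1.001).

## Isoscapes

`build_isoscape()` predicts over a polygon-masked grid (default display
resolution 250 m; the examples below use coarser grids to stay fast) and
derives cell-wise 95% confidence bounds as prediction ± 1.96·√variance —
the Gaussian multiplier, since no other definition is standard for
kriging CIs. Summaries report both CI width and half-width so either
reading of a published "CI range" figure can be compared. Rasters are
written as ESRI ASCII grids with a bit-exact round trip.

## The synthetic generator

`make_trentino_like()` produces the package's study-condition dataset:
151 sites (5 trees each) sampled uniformly over an irregular ~120 km
Alpine-like polygon; a deterministic synthetic topography with smooth
regional relief plus 5–11 km fine-scale structure, rescaled to span
exactly 547–1974 m; and four isotope columns built as

$$z = \mu + \sigma\,(c_1\,\mathrm{alt}^* + c_2\,y^{*\perp} + c_3\,e^*),$$

where $e^*$ is a simulated Gaussian random field (spherical, 30 km, for
δ²H; Matérn κ = 1, 40 km, for δ¹⁸O; nugget fractions 0.75–0.90)
orthogonalized against the covariates. The coefficients are chosen by
exact sample-space orthogonal construction so the realized correlations
with altitude and northing equal the published screening values
(−0.65 for δ¹⁸O₂₀₁₄ vs altitude, −0.54 for δ²H₂₀₁₄ vs northing, and so
on) for *every* seed, and a final positive-slope affine map pins the
pooled two-year ranges exactly to the published envelopes (δ¹⁸O
21.0–24.8‰, δ²H −105.6 to −57.0‰). The per-column scales, year offsets
and nugget fractions were fixed once from the published facts (sill equal
to the sample variance, δ²H nugget up to ≈30‰², ranges within 20–70 km,
2013 enriched relative to 2014) together with the reported measurement
uncertainties (0.4‰ for δ¹⁸O, 2‰ for δ²H, which the nugget dominates).
Candidate covariates are included with realistic structure — summer
temperature follows altitude through a lapse rate with noise, radiation
and canopy cover are weakly or un-correlated — so AIC-based covariate
selection has genuine competition and, at full sample size, picks
altitude.

What the generator does *not* emulate: within-site tree-to-tree
variability as an explicit level (folded into the nugget); precipitation
isotope physics; any non-Gaussian features; preferential sampling. Tests
passing on this generator therefore certify the estimators and solvers,
not the climatological fidelity of any particular real-world surface.

Gaussian fields are simulated by dense Cholesky factorization of the
covariance implied by the variogram (exact at these sizes; no spectral
approximation), with the unbounded linear family handled intrinsically
via a reference sill at the domain diameter, and a $10^{-10}\cdot$sill
jitter for numerical positive definiteness.

## Cross-dating statistics

Before isotope pooling, ring series are cross-dated. The package
implements the two agreement statistics used for that step:
Gleichläufigkeit — the percentage agreement of first-difference signs,
with flat years scoring ½ (the Eckstein–Bauch convention; computed on raw
widths, no standardization) — and the correlation *t*-value
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on the overlapping raw widths (the plain
correlation *t*, not the Baillie–Pilcher detrended variant; the choice is
noted because sources differ). Segment-based quality control of the
COFECHA kind is out of scope.

## A short worked run

```{r demo, eval = FALSE}
ds <- make_trentino_like(seed = 1)
res <- run_pipeline(
  ds$sites,
  isotope_cols = c("d18O_2014", "d2H_2013"),
  mask = polygon_mask(trentino_polygon(), resolution = 5000)
)
res$cv_table
autoplot(res$series$d2H_2013$variogram, models = res$series$d2H_2013$models)
autoplot(res$series$d2H_2013$isoscape, "ci_width")
```

On the default synthetic dataset the cross-validation table reproduces the
qualitative pattern expected of these data: universal kriging edges out
ordinary kriging slightly, and cokriging with standardized altitude gives
the lowest RMSE for all four series.

## Problem sizes used by the tests

The shipped checks run at deliberately chosen sizes: solver-oracle
equivalence on 200 random instances with n ≤ 10; MSDR calibration at
n = 151 with 200 replicate fields; spherical range recovery at n = 300
with 100 replicates; cokriging dominance on 50 replicates at n = 60; the
full pipeline at the study scale of 151 sites. These sizes make every
Monte-Carlo band comfortably stable while keeping a complete run in
minutes on one core.

## Known limitations

- Isotropic models only; anisotropy is diagnosed but not corrected.
- Two-variable cokriging only (primary + one standardized covariate).
- No kriging with external drift, block kriging, or indicator variants.
- Raster I/O is ESRI ASCII grid only; reproject and convert upstream.
- The provenance-assignment step (posterior surfaces for samples of
  unknown origin) is a documented future extension, not part of the
  package.
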