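---
title: "Isoscape modelling and mobility inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoscape modelling and mobility inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxisoscape)
```

This vignette is the package's account of its statistical machinery: the
model it fits, the assumptions it makes, the parameters that matter, what
the synthetic generator does and does not emulate, and the places where a
design decision was genuinely open and had to be made.

## The model

Skeletal δ¹⁸Oₚ values observed at planar locations are decomposed as

$$ Z(s) = m(s) + Y(s) + \varepsilon, $$

where $m(s)$ is a deterministic 2nd-order polynomial trend (6 terms in
standardized easting/northing), $Y(s)$ is a zero-mean stationary Gaussian
field with *stable* covariance
$C(h) = c\,e^{-3(h/r)^\omega}$, and $\varepsilon$ is independent nugget
noise with variance $c_0$ interpreted as measurement plus micro-scale
error. Equivalently the residual semivariogram is

$$ \gamma(h) = c_0 + c\left(1 - e^{-3 (h/r)^\omega}\right),\qquad \omega \in (0,2], $$

which interpolates the exponential ($\omega = 1$) and Gaussian
($\omega = 2$) shapes. Two conventions coexist for this family; we use
the **practical-range** convention (the factor 3), under which γ reaches
about 95% of the sill at $h = r$. Parameter sets reported by software
using the other convention must have their range rescaled before being
passed to `stable_variogram()`.

Prediction is ordinary kriging of the detrended residuals with the trend
added back (`krige_grid()`, `predict.isoscape()`). The OK weights solve
the bordered semivariance system and sum to one; the kriging variance is
$\sum_i \lambda_i \gamma_{0i} + \mu$. The trend is treated as fixed when
computing standard errors — trend-estimation variance is *not*
propagated, a deliberate parallel to the GIS workflow this reproduces and
a documented limitation.

### Why trend removal matters here

The local Moran screen (below) and exploratory mapping show that values
of this kind drift smoothly at the national scale (high south-west, low
north-east in the British case). Kriging assumes a stationary residual;
fitting and subtracting an order-2 polynomial is the smallest surface
that can bend once in each axis, and its coefficients are stored with the
per-axis centring/scaling used to condition the design (raw national-grid
coordinates at 10⁵–10⁶ m would make the quadratic design numerically
rank-deficient).

## Spatial autocorrelation screen

Spatial weights are inverse distance, $w_{ij} = d_{ij}^{-p}$, within a
cut-off distance, then row-standardized. Defaults and their reasons:

* **threshold** — `min_connecting_threshold()`: the maximum
  nearest-neighbour distance, i.e. the smallest cut-off at which no
  sample is neighbourless (≈ 85 km for the British survey geometry).
* **idw_power `p` = 1** — the producing software's default; the exponent
  is configurable because the original analysis does not state it.
* **coincident samples** — multiple individuals from one site share a
  1 km grid square and hence a distance of 0, where inverse distance is
  singular. They are given the weight of a 1 m separation: mutual
  neighbours with the strongest weight in the row, so that all values at
  a shared site inform each other. All values are retained; nothing is
  averaged away.

Global Moran's $I$ uses randomization (permutation-moment) inference:
$E[I] = -1/(n-1)$ and the kurtosis-corrected variance, with a two-sided
normal p-value. The local statistic is Anselin's
$I_i = (z_i/m_2)\sum_j w_{ij} z_j$ with $m_2 = \sum_k z_k^2 / n$.
Two inference modes are provided because the original software's mode is
not documented:

* **conditional permutation** (default, 999 draws, seeded): value $i$ is
  held fixed, the remaining $n-1$ values are permuted among its
  neighbours; the one-sided pseudo p-value is $(k+1)/(n_{perm}+1)$,
  which can never be exactly zero.
* **analytic**: exact moments of the lag under that same conditional
  permutation distribution, derived from simple-random-sampling algebra
  ($E[L_i] = W_i \bar m$, $\mathrm{Var}[L_i] = s^2[S_{i2} -
  (W_i^2 - S_{i2})/(n-2)]$), with a two-sided normal p-value. This mode
  is used in the large replicated simulations of the test-suite, where
  999 permutations per sample per replicate would be wasteful.

P-values are Benjamini–Hochberg corrected (`fdr_significant()`, level
0.05 by default — the level is configurable since the source analysis
states FDR use but not the level). Significant samples are classed by the
signs of their deviation and spatial lag: HH/LL cluster cores
($I_i > 0$), HL/LH spatial outliers ($I_i < 0$). The pipeline excludes
only HL/LH from the surface model: outliers are candidate non-locals,
whereas HH/LL cores are exactly the regional structure the trend should
capture.

## Declustering and preferential sampling

Archaeological recovery is preferential: dense clusters where preservation
and excavation history allow, voids elsewhere. Cell declustering
(`decluster_weights()`: weight ∝ 1/cell count, normalized to sum to $n$,
default 50 km cells — about the scale of the sampling foci) is applied to
the **trend fit**. The kriging equations themselves are left unweighted:
kriging already accounts for redundancy among clustered points through
the covariance, so declustering enters where the bias actually arises, in
the estimate of the large-scale mean structure. (Both placements were
considered; weighting the variogram pairs as well made no qualitative
difference on synthetic experiments and is not the default.)

## Variogram estimation and fitting

`empirical_variogram()` is the Matheron estimator on equal-width bins
(default: 12 bins to half the maximum pair distance — conventional
choices, exposed as arguments). Zero-distance pairs are *not* mixed into
the first bin; their mean squared half-difference is reported separately
as direct nugget evidence.

`fit_variogram()` minimises weighted least squares with fixed weights
$N_b/\hat\gamma_b^2$. Because the model is linear in $(c_0, c)$ given
$(r, \omega)$, those two are profiled out exactly (non-negative weighted
least squares with boundary candidates) and the optimizer searches only
$(\log r, \omega)$: a 30 × 14 coarse grid followed by Nelder–Mead from
the three best grid points, twice, at `reltol = 1e-14`. The fit is
deterministic; on noise-free model-generated bins it recovers all four
parameters to better than 1e-4 relative (asserted in the tests). The
shape is bounded to [0.05, 2]; when the residual field is nearly pure
nugget the partial sill legitimately collapses to zero and range/shape
become uninformative — the printed sill is then the quantity to read.
Published parameter sets can bypass fitting entirely
(`isoscape(..., variogram = stable_variogram(...))`), since a proprietary
optimiser's objective cannot be replicated bit-exactly.

## Kriging numerics

* Global neighbourhood by default: at a few hundred samples the full
  bordered system (solved once, all grid targets back-substituted) is
  exact, fast, and avoids guessing another package's sector-search rules.
* A `"smoothed"` mode approximates smoothed search neighbourhoods:
  neighbours within radius $R$ (default the variogram range), solved
  weights multiplied by a taper (1 inside $sR$, linear to 0 at $R$,
  $s = 0.5$) and renormalized to sum to one. This is an approximation —
  the proprietary semantics are not public — and is labelled as such.
* Coincident samples are distinct equations: between two different
  measurements the semivariance at $h = 0$ is the nugget $c_0$, and only
  the matrix diagonal (a sample with itself) is zero. With $c_0 > 0$ this
  keeps the system non-singular. With $c_0 = 0$ exact duplicates are
  collapsed to their mean residual (in the noise-free model they must
  agree), preserving exact interpolation.
* Kriging variances in $[-10^{-8}, 0)$ from floating-point roundoff are
  clipped to zero; anything more negative raises a warning.

Leave-one-out cross-validation holds trend and variogram fixed while each
sample is excluded and re-predicted (`loo_cv()`), matching the original
workflow; the summary reports mean error, RMS, standardized mean and RMS,
and average standard error. Standardized RMS ≈ 1 is the calibration
check: prediction errors are as large as the model says they should be.
Samples left with no usable neighbours (or zero standard error, as for a
nugget-free duplicate) are flagged and excluded from the summary with a
warning.

## Residual mobility classes

CV residuals (predicted − measured) beyond ±0.6 ‰ — about twice the
typical replicate measurement error of enamel phosphate analysis — class
a sample as candidate non-local (`enriched`/`depleted`); the signed bin
index in 0.3 ‰ steps supports residual maps. Both numbers are
configurable; the threshold is strict (±0.6 exactly is `local`), and
shrinking it monotonically grows the non-local set.

## The synthetic generator

`simulate_isoscape()` draws from exactly the model above: deterministic
trend, Gaussian field simulated by dense Cholesky factorisation of the
stable covariance on the *unique* snapped locations (1e-10 diagonal
jitter; exact for the ≤ 2000-point scale this package targets, hence no
spectral approximations), independent nugget per sample, locations from a
mixture of Gaussian sampling foci truncated to the domain and snapped to
1 km-square centres, and optional planted migrants (fixed per-mil
offsets). Coincident samples therefore share the correlated component but
not the nugget — the nugget is measurement error.

The study-scale preset (`sim_config_paper()`) fixes the conditions used
throughout the tests: 258 samples on a 700 × 1250 km domain; the
published stable-variogram parameters (nugget 0.299684, partial sill
0.015628, range 121 384.8 m, shape 1.170313); trend coefficients
(17.9, −0.25, −0.95, 0, 0, −0.15) on standardized coordinates, spanning
≈ 16.6–19.0 ‰ from south-west to north-east — the direction and rough
magnitude of the groundwater-driven gradient in real British enamel
data; 25 sampling foci of 30 km spread, emulating regional clustering of
archaeological recovery; planted migrants use ±2 ‰ offsets, a
convention motivated by the separation of observed spatial outliers from
their neighbours, not a published value.

What the generator does **not** emulate: non-Gaussian tails, anisotropy,
spatially varying nugget (inter-laboratory calibration shifts), errors in
the recorded find-spots beyond 1 km snapping, and any relationship to
actual geography (coastline, geology, preservation bias correlated with
soil chemistry). Passing synthetic tests therefore demonstrates the
*statistical machinery* is correct and calibrated under the stated model,
not that the model is adequate for any particular real dataset.

## Test-suite problem sizes

Simulation-backed checks use sizes chosen to make their Monte-Carlo error
small relative to the asserted tolerances while keeping the default suite
quick: 1000 random instances (n ≤ 10) for solver-vs-oracle exactness at
1e-9; 30–40 random instances (n ≤ 30) for Moran brute-force equality at
1e-12; 100 seeded replicates of the 258-sample preset for trend-recovery
coverage, migrant-detection power, and FDR null control; 20 replicates
for standardized-RMS calibration. Monte-Carlo consistency assertions
(e.g. the permutation mean of Moran's I) use 4σ bands on 999 draws.
The standardized-RMS criterion is evaluated as a calibration property
*across* replicates (pooled RMS in [0.9, 1.1]); single-replicate values
fluctuate with the chi-squared spread of correlated squared errors and a
per-replicate assertion at that width would reject a correct
implementation a third of the time.

## Known limitations

* Standard errors ignore trend-estimation and variogram-estimation
  uncertainty; they are conditional on the fitted mean and covariance
  structure.
* The smoothed-neighbourhood taper is an approximation of undocumented
  proprietary behaviour; global kriging is the reference mode.
* Isotropic covariance only; no universal/co-kriging; no conditional
  simulation.
* Grid-reference support is limited to the 4-figure (1 km) form; no
  geodesic computation or datum transformation — all distances are planar
  metres.
* With a near-pure-nugget residual field the variogram fit is weakly
  identified (flat objective in range/shape); supplying fixed parameters
  is then preferable, and the fitted sill remains reliable.
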