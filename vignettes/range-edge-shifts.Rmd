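---
title: "Estimating northern range-edge shifts and their climatic-niche correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating northern range-edge shifts and their climatic-niche correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeshiftr)
```

## The problem

Under a warming climate, species at the cool (poleward) margin of their
range are expected to expand northwards first. Quantifying that expansion
from opportunistic occurrence records is harder than it sounds, for two
reasons this package is built around:

1. **Recording effort is wildly unequal between periods.** Later atlas
   periods typically contain several times more records than earlier ones.
   A naive comparison of observed range margins then mistakes better
   detection — more occupied cells found, especially wherever effort grew
   fastest — for genuine range expansion.
2. **The range edge is an extreme, not a mean.** The biologically
   interesting quantity is the position of the northern boundary, which is
   operationalized here as a high quantile (0.9, alternatively 0.75) of the
   northings of a species' presence cells.

The pipeline chains five stages: synthetic data generation (or your own
occurrence tables), occurrence preparation with effort balancing, quantile
edge-shift estimation, climatic niche metrics, and a weighted best-subsets
regression of shifts on niche metrics and traits.

## Edge estimation

For a two-level period factor, quantile regression of northings on period
reduces exactly to per-period sample quantiles, so `quantile_edge()`
implements the check-loss minimizer directly: for
$\rho_\tau(u) = u(\tau - \mathbf{1}[u<0])$, the edge is
$\arg\min_q \sum_i \rho_\tau(y_i - q)$. When $n\tau$ is an integer the
minimizer is a flat interval between two order statistics; the **lower
endpoint** is returned, matching the vertex solutions of linear-programming
quantile fits. This tie-break matters: on small supports the two endpoints
can differ by one inter-cell gap (10 km on the default grid), so the
convention is fixed and tested against an exhaustive check-loss oracle over
all small samples.

The shift is the difference of the two period edges in km (positive =
northward). Confidence intervals use a stratified percentile bootstrap
(resampling within each period, `B = 1000` by default), which is
distribution-free and reproducible from a seed; the rank-inversion interval
of quantile-regression software is not available in this environment and is
not reimplemented. Species with fewer than `min_support = 5` presences in
either period are excluded: a 0.9 quantile of four points is not an edge. A
shift is classified northward/southward only when the 95% CI excludes zero.

Where the second period was balanced by subsampling (below), the estimate
and both CI endpoints are arithmetic means over the replicate data sets.

## Effort balancing

`balance_effort()` divides the study extent into five equal-width
latitudinal zones (the break positions are configurable) and, within each
zone, randomly subsamples the pooled-across-species second-period presences
without replacement down to the zone's first-period count. The first period
is never touched, nothing is upsampled, and the procedure repeats five
times with distinct derived sub-seeds. Balancing operates on presence cells
(after deduplication to species x cell x period), which is the reading
under which "equal totals per zone" holds exactly.

Why zones rather than a global match? Effort growth is usually spatially
uneven — often strongest in the north of a study region. A global subsample
would equalize totals while preserving the spatial tilt; zone-wise matching
restores the first period's latitudinal effort profile up to within-zone
residuals. The acceptance suite demonstrates this on a zero-true-shift
world with 3x second-period effort and a northward effort gradient: the
unbalanced mean estimated shift is ~14 km (many standard errors from zero),
the balanced mean is within one standard error of zero.

## Niche metrics

From a continent-scale occupancy grid and cell climate values,
`niche_stats()` computes, per species and variable (MAT, GDD5, PREC, SWC):
the mean (for MAT this is the species temperature index, STI), the sample
SD (absolute niche breadth) and the coefficient of variation CV = SD/mean
(relative breadth). For MAT the CV denominator is converted to Kelvin
(mean + 273.15): ratios of Celsius values are not meaningful because the
zero is arbitrary. SD uses the $n-1$ denominator — the convention of the
statistical software this analysis style comes from; a population-SD option
exists and is flagged in output. Range size is the number of distinct
occupied cells. Cells with missing climate are dropped per variable, not
per species, to maximize usable data.

## The shift model

`assemble_model_table()` joins shifts, niche metrics and traits into one
row per species, with regression weight equal to the **inverse of the 95%
CI width** of the shift — "inverse of the confidence interval" is read as
its width; an inverse-half-width option exists and only rescales all
weights, which leaves coefficients, $R^2$ and (see below) the likelihood
unchanged.

`wls_fit()` standardizes continuous covariates (mean 0, SD 1; coefficients
are km per SD), treatment-codes factors against a declared reference level,
and minimizes $\sum_i w_i (y_i - x_i'\beta)^2$ via `stats::lm`. The
log-likelihood is
$\ell = \tfrac12\bigl[\sum_i \log w_i - n(\log 2\pi + 1 +
\log(\mathrm{RSS}_w/n))\bigr]$ and $\mathrm{AIC} = -2\ell + 2(k+1)$,
counting the error variance as a parameter. Note an algebraic consequence:
rescaling all weights by a constant changes $\sum\log w_i$ and
$\log \mathrm{RSS}_w$ by exactly cancelling amounts, so the likelihood and
AIC are invariant — weights act only through their relative sizes.
Predicted $R^2$ uses the leverage-based weighted PRESS
$\sum_i w_i (e_i/(1-h_{ii}))^2$; negative values are legal and occur in
practice for weak models.

`best_subsets()` fits all $2^8 = 256$ combinations of the eight candidate
predictors (multi-level factors move as blocks) and flags the best model
per size by $R^2$. `select_final()` then applies the parsimony rule: the
chosen model is the **smallest** size whose AIC is within 2 units of the
global minimum — a larger model must beat it by more than 2 AIC units to be
preferred, since models within 2 units carry the same information value.
Single-term deletions (`drop1_table()`) report $\Delta$Df, $\Delta$SS, RSS
and the deviance-scale AIC of `stats::drop1`, which differs from the full
AIC by additive constants only. Diagnostics cover Shapiro-Wilk normality of
weighted residuals, a studentized Breusch-Pagan test (implemented directly:
$n R^2$ of the squared weighted residuals on the design), generalized VIFs
per predictor block via the correlation-determinant formula, and Cook's
distances flagged above $4/n$.

## The synthetic world

The generator states one explicit world, used as-is by the tests:

* **Grid**: 200 km x 1,100 km of 10-km cells, northings 6.6M–7.7M m
  (a Fennoscandian-style band; the 7M m southern-species delimitation
  threshold falls inside it). The continental grid for niche metrics is
  2,000 km x 3,500 km of 50-km cells.
* **Climate**: MAT declines at 1 degree C per 100 km of northing
  (continent: 0.7/100 km starting at 17 degrees C in the south);
  GDD5 = max(0, 200·MAT + 300); PREC and SWC follow mild latitudinal trends
  with Gaussian noise. These are caricatures with realistic magnitudes, not
  climate fields: no spatial autocorrelation beyond the gradients, no
  coastlines.
* **Species**: niche means/SDs drawn from ranges typical of European-scale
  atlas summaries (thermal means 7 ± 2 degrees C, breadths 0.8–4 degrees C);
  four overwintering modes at frequencies 0.2/0.2/0.4/0.2; 30% multivoltine;
  true shifts from $\beta_0 + \sum_j \beta_j z_j + \varepsilon$ on scaled
  covariates.
* **Occupancy and effort**: every cell south of the species' true edge is
  occupied with probability 0.4 — uniform occupancy is the simplest model
  under which the $\tau$-quantile edge has a clean expectation for recovery
  tests. Records per occupied cell are Poisson with intensity 0.3 (first
  period) and 3x that (second period), optionally tilted linearly in
  latitude to emulate spatially uneven effort growth (the bias-removal
  experiment uses tilt 1.5 in the second period). Record coordinates are
  cell centroids; the within-cell position is irrelevant after gridding.

What a green test does **not** establish: robustness to spatially
autocorrelated occupancy, to detection probability varying by species, or
to taxonomic error — none of which the generator emulates.

## Numerical and design choices

* **Sub-seeds**: every random stage derives its seed from the master seed
  and a stage label, so adding a stage never perturbs another's stream;
  everything is bit-reproducible from one integer.
* **Speeds**: group summaries divide by user-supplied period mid-year
  spans (defaults in the examples: 1981.5 to 2008 for birds, 1994 to 2015 for
  Lepidoptera). Both conventions — group mean shift over span, and mean of
  per-species speeds — are reported; they coincide when the span is shared
  within a group, but published speed figures in this literature do not
  always match either convention exactly, so the summary keeps both
  explicit.
* **Distribution centre** for the southern-species filter is the unweighted
  mean of first-period presence northings (median available); species at or
  north of the threshold are removed (the comparison is strict `<`).
* **Degenerate inputs**: empty northing sets, $\tau \notin (0,1)$,
  zero-variance predictors, rank-deficient designs, non-positive CI widths
  and unknown species all raise precise errors rather than propagating NA.

## Limitations

Only the northern (leading) edge is analysed; no longitudinal shifts, no
abundance weighting, no phylogenetic or spatial random effects (none in the
analysis style this implements). The bootstrap CI for a high quantile at
small $n$ is approximate; calibration is verified at $n = 50$ per period
(95% nominal, observed within ±3% over 1,000 simulations) but will degrade
at the support floor. Predicted $R^2$ under weights follows the PRESS
formula above; other software may differ in the weighted case.
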