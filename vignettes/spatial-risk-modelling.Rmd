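---
title: "Methods: geostatistical modelling of household snakebite risk"
author: "snakerisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geostatistical modelling of household snakebite risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakerisk)
```

# The model and its assumptions

The package estimates the probability that a surveyed household suffers a
binary event (a snakebite within twelve months) as a function of
household-level answers and gridded environmental covariates, while
accounting for residual spatial correlation. The model is a latent
Gaussian hierarchical logistic regression: outcome
$SB(s_i) \sim \mathrm{Bernoulli}(\pi(s_i))$ with
$\mathrm{logit}(\pi(s_i)) = \beta_0 + X(s_i)\beta + u(s_i)$, and a
spatially correlated random effect $u \sim N(0, \Sigma)$ whose covariance
is Matérn with smoothness $\nu = 1$:
$\Sigma_{ii'} = \sigma^2 (\kappa d_{ii'}) K_1(\kappa d_{ii'})$,
$\kappa = \sqrt 8 / \rho$. Under this convention $\rho$ (km) is the
practical range: the correlation at distance $\rho$ is
$\sqrt 8\,K_1(\sqrt 8) \approx 0.1397$, i.e. negligible. The assumptions
are the usual ones of model-based geostatistics: stationarity and isotropy
of the field, conditional independence of outcomes given the linear
predictor, and a planar, kilometre-unit coordinate system (all I/O
converts metres to km exactly once at the boundary).

Inference follows the INLA logic but with an independent, exact dense
Matérn engine instead of an SPDE finite-element mesh, which is an
approximation device for the same field. For fixed hyperparameters
$(\sigma, \rho)$, `laplace_fit()` maximizes the joint posterior of
$(\beta, u)$ by Newton–Raphson (score tolerance $10^{-6}$, cap 100
iterations, step halving whenever a step would decrease the log
posterior) and approximates the conditional posterior by the Gaussian at
the mode with precision equal to the negative Hessian. The Laplace
estimate of $\log p(y \mid \sigma, \rho)$ is the log posterior at the
mode plus half the log-determinant difference of prior and posterior
precisions. `hyperparameter_grid()` evaluates this on a log-spaced grid
(7×7 by default), warm-starting each node from the previous mode, and
normalizes the weights after subtracting the maximum so underflow cannot
zero the grid.

# Priors and tunable parameters

* **Fixed effects**: independent $N(0, 10^3)$ (precision `beta_prec =
  1e-3`), effectively vague; the intercept is treated like any
  coefficient. Under complete separation the prior keeps the mode finite
  and the fit is flagged.
* **Field SD $\sigma$**: log-uniform on [0.1, 1.5] — a sensible range for
  a logistic-scale random effect; values much above 1.5 would swamp
  covariate effects of the magnitude seen in household surveys.
* **Range $\rho$**: log-uniform on 0.1–10 times the median inter-knot
  distance, a weakly informative window anchored to the design's own
  spatial scale.
* **Scaling map** (`default_scaling()`): distances m→km (×0.001),
  temperatures ×0.1 (tens of °C), dry-quarter precipitation ×0.01
  (hundreds of mm), poverty likelihood as a fraction in [0, 1] (a percent
  input uses ×0.01), livestock ×0.001 (per thousand head). Scaled columns
  carry a unit tag; a second application of `scale_covariates()` or an
  untagged prediction design is an error, so nothing is ever scaled twice
  or not at all. The poverty index enters as the likelihood itself so
  that "one unit" is its whole range, which is how the odds on such
  coefficients are interpreted.
* **Reporting**: marginals are Gaussian mixtures over the grid; the 90%
  interval is equal-tailed (mixture CDF inverted numerically), the mode is
  the highest-density point of the mixture on a 512-point grid, and odds
  are exponentials of unrounded logit values — rounding to two decimals
  happens only in the report layer.

# The latent-field representation

`glgm()` supports two knot layouts. `field_at = "location"` places one
latent value per observation point (exact; dense factorization, capped at
5,000 points). `field_at = "cluster"` — the default for clustered
surveys — ties the field to cluster centroids and lets households inherit
their cluster's value. With ranges of tens of km and cluster radii around
1.5 km the within-cluster field correlation is ≈0.995, so the reduction
loses almost nothing while cutting the latent dimension from thousands to
the cluster count; it is also closer in spirit to the mesh resolution an
SPDE analysis would use. Location-level knots remain available for the
conditioning identities (e.g. prediction at an observed point returns
that point's posterior mode exactly).

Prediction at new points is standard Gaussian-process conditioning per
hyperparameter node: $u_* \mid u$ has mean $\Sigma_{*k}\Sigma_{kk}^{-1}
\hat u$ and variance $\sigma^2 - \Sigma_{*k}\Sigma_{kk}^{-1}\Sigma_{k*}$
plus the propagated posterior covariance of $(\beta, u)$; far from all
data the field marginal reverts to $N(0, \sigma^2)$. Risk-scale summaries
(posterior mean and SD of $\pi$) integrate over the grid by seeded Monte
Carlo (2,000 draws by default).

WAIC is computed as $-2(\mathrm{lppd} - p_{\mathrm{waic}})$ from seeded
draws of the Gaussian-mixture posterior (1,000 by default), with
pointwise contributions retained so that a WAIC difference carries a
standard error.

# Covariate preparation and selection

Preparation: poverty scoring is sum-then-lookup on a user-supplied table
(the national table is licensed, so the package ships only a clearly
synthetic stand-in, `synthetic_ppi_lookup()`); distance to water is the
exact point-to-segment Euclidean minimum over all features (zero inside
water polygons); raster extraction uses half-open cells (edge points
belong to the cell right/below) on top-left row-major grids.

Selection reproduces the published iterative procedure with deterministic,
logged policies where the procedure itself leaves freedom:

1. **Correlation filter** (threshold 0.6, pairs kept when $|r| \le 0.6$):
   of an offending pair, the member with the larger mean absolute
   correlation to everything else is dropped; ties fall to the later name
   in the configured priority order. Constant columns drop first.
2. **Sequential VIF** (threshold 5): recompute each round, drop the
   largest; perfect collinearity gives an infinite VIF and drops first.
3. **Negligible-effect pruning** (open band ±0.1 log-odds): one removal
   per iteration — the candidate whose removal most improves WAIC — then
   refit to a fixed point. A flagged covariate is retained when every
   candidate removal worsens WAIC, mirroring the published treatment of a
   non-significant but load-bearing covariate. A mean of exactly ±0.1 is
   kept (the band is open).

Interactions are tested by refitting with a product term; "significant"
means the 90% credible interval excludes zero on the logit scale
(equivalently the odds interval excludes one — the two statements are
asserted consistent). Spatial ablation refits the identical covariate set
without the field and reports both WAICs with the standard error of the
difference.

# The synthetic-survey generator

`synth_config()` encodes the study conditions the generator emulates: 249
clusters of 53 households (13,197, near the surveyed 13k), cluster radius
1.5 km (households-per-cluster and radius are not reported by the source
survey; these defaults are configurable, not inferred), human outcome
prevalence calibrated to 1.18% (animal preset: 0.7%, field SD 0.77, range
430 km), field SD 1 and range 30 km, published effect sizes as the true
coefficients, minimum winter temperature in 1.8–10.9 °C and dry-quarter
precipitation in 18–71 mm. Environmental surfaces are low-pass-filtered
uniform noise rescaled into their ranges (smoothness 0 leaves white
noise); rivers are random west–east polylines at a density that keeps
household distances to water in the low-kilometre range of a river-dense
floodplain — the scale on which a per-km odds ratio is interpretable;
administrative units partition the region into rectangles. Cluster
centres are uniform (the original survey's probability-proportional
sampling is deliberately not reproduced; only the spatial-statistical
structure matters for recovery testing). The intercept calibration
bisects on the realized mean of $\mathrm{logit}^{-1}(\eta)$, so the
achieved prevalence is the target up to binomial noise. Above 5,000
households the field is drawn at cluster centres and shared within
clusters (correlation ≈0.995 at these scales); at or below 5,000 it is
drawn exactly at household locations by dense Cholesky.

What the generator does **not** emulate: real geography (rivers, roads,
relief), survey non-response, anisotropy, non-stationary covariate
interactions, and the sampling weights of the original design. Passing
recovery tests therefore demonstrates the correctness of the inference
machinery under the model's own assumptions, not robustness to the ways
real data violate them.

# Test conditions and problem sizes

The recovery suites run at 2,000 households in 80 clusters over a
300×120 km region with field SD 1 and range 30 km and the published human
effect sizes. Their outcome prevalence is calibrated to 0.25 rather than
the survey's 1.18%: with only ~24 cases the likelihood carries almost no
information about the range, and no correct implementation could recover
it from such data; at ~500 cases the hyperparameters are identifiable
while the model structure is unchanged. The full-size default (13,197
households at 1.18%) is exercised by the prevalence-calibration tests.
Coverage of the 90% intervals over 50 replicates sits slightly below
nominal (per-coefficient 0.80–0.94 on the fixed seeds): pure-Gaussian
Laplace marginals omit the skewness correction a full INLA implementation
adds, and the σ prior truncates at 1.5; the suite checks coverage against
the binomial band for a nominal 90% rate. Interaction, ablation and
selection suites use a 3×3 hyperparameter grid and reduced WAIC draws for
runtime; model defaults remain 7×7 and 1,000.

# Numerical choices and degeneracies

* Covariance jitter $10^{-8}\sigma^2$ on the diagonal; duplicate or
  near-duplicate locations warn and rely on the jitter (field surveys put
  households metres apart).
* Bessel evaluation by the standard library routine; the $x K_1(x) \to 1$
  limit is applied analytically at zero distance, and underflow at large
  distance is mapped to covariance 0.
* Newton steps are halved (at most 13 times) on any log-posterior
  decrease; non-convergence warns with the iteration count.
* Bernoulli log-likelihoods are evaluated through the log-CDF of the
  logistic distribution, stable in both tails.
* All Monte-Carlo steps (WAIC, risk prediction, posterior simulation)
  take explicit seeds; pipeline stages derive their seeds from the single
  run-config seed, so reruns are bit-identical.
* Grid-count convention: a w×h region at spacing s yields
  floor(w/s)·floor(h/s) candidate centres before region and exclusion
  masking; cell-centre containment assigns cells to admin polygons, which
  keeps unit sums exactly partition-consistent.
* "Households at risk per cell-year" is the expectation (risk ×
  households), not a thresholded count — the published continuous-valued
  map implies an expectation.

# Limitations

Dense exact covariances limit location-level fields to a few thousand
points; larger problems use the cluster representation. Hyperparameter
integration is a 2-D grid — adequate for two hyperparameters, not
extensible to spatio-temporal models. Marginals are Gaussian mixtures
without higher-order corrections, so intervals for weakly identified
coefficients at very low case counts can be slightly narrow. Only
Bernoulli-logit likelihoods are supported, and no reprojection between
coordinate systems is attempted: inputs must already be planar and
metric.
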