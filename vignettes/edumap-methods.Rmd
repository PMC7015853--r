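---
title: "Methods: space-time geostatistics for attainment mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: space-time geostatistics for attainment mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(edumap)
```

## What the package estimates

`edumap` maps educational attainment over a pixel grid and a span of years
from geolocated survey data: the mean years of schooling and the
proportions of a population falling in four ordinal attainment bins —
zero years, 1–5 years (less than primary), 6–11 (at least primary), and
12 or more (secondary or higher), on years top-coded at 18. The ordinal
bins are not modelled jointly as a multinomial but through a
*continuation-ratio* chain of conditional binomials: the probability of
zero years; of 1–5 years given more than zero; of 6–11 given more than
five. The top bin is the complement, so composed bin probabilities always
sum to one (`compose_cr_probabilities()`), and each conditional indicator
can be fit as an independent binomial geostatistical model. Mean years is
fit as a Gaussian indicator on the identity link.

## The observation model and its assumptions

Point-referenced clusters contribute binomial counts `C_d` of `N_d`
persons at the bin level (after `cr_transform_counts()`), or an observed
mean `edu_d`. The Gaussian likelihood is parameterized by a *precision*
`tau * s_d` with `s_d` the cluster's sample size — so the variance of a
cluster mean shrinks as `1/(tau N)`, and `1/tau` plays the role of a
person-level variance. The notation `Normal(mu, tau s)` admits a variance
reading too; we adopt the precision reading because it is the convention
of the latent-Gaussian software family this model class comes from, and
because it makes `tau` interpretable (the default `tau = 0.05` corresponds
to a person-level standard deviation of about 4.5 years).

Admin-referenced ("polygon") samples are aggregated with their design
weights; the Kish closed form gives the design effect
`DEFF = n * sum(w^2) / sum(w)^2` and effective sample size `n_eff = n /
DEFF` (`aggregate_polygon_obs()`). In the likelihood a polygon observation
sees the population-weighted mixture of its pixels' probabilities,
`p_d = sum_i w_i * plogis(eta_i)`, with `n_eff` as its trials. Each
polygon observation carries its own micro-scale (nugget-level) latent
rather than touching the pixel-time nuggets of every pixel it spans; this
keeps the latent dimension proportional to the data and treats the
polygon-level noise as the overdispersion it is.

Degenerate conditional records with zero trials (every person in a lower
bin) are retained and contribute exactly zero likelihood; dropping them
would silently distort source bookkeeping.

## Recovering single years from binned codings

Some survey families record attainment only in bins. To fit the
single-year machinery, `split_binned_counts()` redistributes each bin's
count over its constituent years proportional to the pooled empirical
within-bin distribution of *single-year-coded* observations from similar
surveys: same country within ±5 survey years first, widening to the same
country at any year, then the whole pool, and falling back to a uniform
split (with a warning) only when no training mass exists. Totals are
conserved exactly per bin; fractional counts are allowed. This is a
deliberately simple pooled-redistribution scheme — the tested property is
that it reduces bias in implied means relative to midpoint imputation
(every person at the bin midpoint), and on synthetic data with a
geometric-decay within-bin profile it does so consistently, because
drop-out really is front-loaded within bins while midpoints are not.

## The mean function: stacked generalization

Nine covariate layers (access, nighttime lights, population, growing
season, aridity, elevation, urbanicity, irrigation, and a year trend; some
time-varying) never enter the linear predictor directly. Three submodels —
penalized additive splines (`mgcv`), depth-limited gradient-boosted trees
(`xgboost`, early stopping on an internal split), and the lasso
(`glmnet`, penalty by its own cross-validation) — are each fit with
fivefold cross-validation at the cluster level, and their out-of-fold
link-scale predictions become the features `X_{i,t}` of the geostatistical
model; full-data refits supply the prediction-time feature grids. The
submodels fit logit-transformed empirical proportions clamped away from 0
and 1 by `0.5/(N+1)`, weighted by trials, which keeps them on the same
link scale as the second stage. Submodel uncertainty is not propagated:
only point predictions enter, because there is no satisfactory way to
carry boosted-tree uncertainty into the final estimates, and the
cross-validated coverage results below indicate the final intervals do not
suffer for it.

The stacking weights are constrained to the simplex (non-negative, summing
to 1) through a softmax parameterization. The constraint lives in the
*outer* (hyperparameter) layer, not the latent layer: given the weights
the linear predictor is linear in all latent quantities, so the Laplace
approximation below is exact whenever the likelihood is Gaussian. A pure
sum-to-one linear constraint (allowing negative weights) is the natural
alternative; the simplex avoids the sign-flipping degeneracy of strongly
correlated submodel predictions.

## Residual structure and estimation

Residual space–time correlation is a zero-mean Gaussian process with a
separable Kronecker covariance: an isotropic Matérn in space (smoothness
fixed at `nu = 2`, which is notoriously unidentifiable from data of this
kind; scale `kappa = sqrt(8 nu)/delta`, so `delta` is the distance at
which correlation has fallen to roughly 0.1) and an annual AR1 in time.
Distances are abstract pixel units (1 = one pixel width): the model is
scale-free and a physical resolution would only relabel `delta`. Sharp
national discontinuities are carried by iid country effects with shared
variance `gamma^2`; micro-scale variation and overdispersion by an iid
pixel-time nugget `sigma^2`.

Fitting is exact-dense rather than mesh-based: at desk scale (a few
hundred pixels, single-digit years) the Kronecker factors can be built and
factorized directly, every approximation is testable against brute force,
and no mesh machinery is needed. The two-level scheme is

1. **inner**: Newton/Fisher scoring on the joint latent vector (GP field
   at all pixel-times, country effects, nuggets at observed pixel-times,
   intercept) given hyperparameters — for the binomial likelihood with
   canonical link the expected and observed information coincide for point
   data, and a rank-one Fisher term handles polygon mixtures;
2. **outer**: Nelder-Mead on the Laplace-approximate marginal posterior of
   the transformed hyperparameters (log variances, log range, a logit-type
   transform of `rho` onto (-1, 1), softmax weights), with weakly
   informative hyperpriors: Normal(0, 3^2) on log-variances and log-tau,
   Normal(log 4, 1.5^2) on log-delta, Normal(0, 2^2) on the transformed
   `rho` and the raw weights, and Normal(0, 10^2) on the intercept.

Posterior candidate maps (`draw_posterior_fields()`, default 1,000) are
joint Gaussian draws from the Laplace curvature at the mode, pushed
through the link, with fresh nugget noise per pixel-time; the three
conditional indicators' draws are aligned by draw index when composed into
bin probabilities. Hyperparameters are plugged in at their modal values
for the field draws, but the *intercept's* reported standard error mixes
over a Gaussian approximation to the hyperparameter posterior (numerical
Hessian of the outer objective, 20 mixture points; law of total variance).
With as few as three countries the country-effect variance is weakly
identified, and conditioning on its point estimate visibly understates the
intercept's uncertainty; the mixture restores calibration and is the same
device the integrated-nested-Laplace family uses. Set
`control$se_hyper = FALSE` to skip it.

### Numerical choices

* Linear predictors are clamped at ±30 before the inverse logit
  (overflow guard; `plogis(30)` is 1 to within 1e-13).
* Covariance factorizations add a relative diagonal jitter of `1e-8`;
  `matern_covariance()` itself returns `C(0) = omega^2` exactly.
* Inner tolerance: gradient norm below `1e-5 * sqrt(dim)`, max 200
  iterations with Armijo step halving. Outer: relative objective `1e-6`,
  max 60 Nelder-Mead iterations; the fit is flagged converged when the
  optimizer reports convergence or the objective improved by less than
  0.2% of its magnitude over the last ten evaluations (Nelder-Mead rarely
  "converges" formally before its cap on objectives this flat).
* Uncertainty intervals are 2.5th/97.5th percentiles with linear
  interpolation between order statistics (R quantile type 7), pinned for
  reproducibility.
* All randomness is seeded; identical configuration and seed give
  bit-identical observation tables, fits and draws.

## Post-estimation

Candidate maps are aggregated to admin levels as population-weighted means
per draw (`aggregate_to_admin()`), so draw count is preserved and
re-aggregation is exact. Raking (`rake_draws()`) multiplies every cell of
a country-year by `reference / (that draw's national aggregate)`; after
raking, each draw's national aggregate equals the reference exactly, and
raking is idempotent. This per-draw reading collapses national-level
uncertainty onto the reference — a documented consequence; `per_draw =
FALSE` instead scales all draws by the single posterior-mean ratio,
preserving relative national uncertainty. Proportions are clipped to
[0, 1] after scaling, since linear raking can exceed 1. Pixels whose
land-cover class is barren/sparsely vegetated, or whose population density
is *strictly* below 10 persons per pixel in the reference year, are masked
from outputs and aggregation weights.

Inequality summaries are computed draw-wise and then summarized: the
two-group index of dissimilarity between attainers and non-attainers
(`D = 0.5 * sum |a_i/A - b_i/B|` — the fraction of attainers who would
have to relocate for evenness; the package computes it per draw, with a
switch for posterior means), the exact additive decomposition of national
rate change into unit contributions `c_{i,t1} r_{i,t1} - c_{i,t0}
r_{i,t0}`, and male:female parity ratios with exceedance probabilities
(`ratio > 1` means male advantage; "credibly different from parity" means
the exceedance probability reaches 0.975 or 0.025).

## Validation

`cv_edu_geostat()` runs source-stratified fivefold cross-validation:
folds are whole survey-years, so a held-out source shares no clusters with
training. Per fold the stacked features are regenerated from training
clusters only (no leakage), the model is refit, and each held-out
cluster's posterior-predictive distribution is simulated by pushing joint
latent draws through binomial sampling at the cluster's `N` — coverage is
therefore of the *observed data*, including sampling noise, not of the
latent probability. Reported metrics are mean error, RMSE, empirical 95%
coverage, and Pearson correlation. Semivariograms of residuals before
(mean function only) and after the full fit verify that the GP absorbs
the spatial structure (distance bins: ten equal-width bins to half the
maximum pairwise distance).

The shipped validation run (`scripts/acceptance.R`) uses the default
synthetic study — 15×15 pixels, 6 years, 3 countries, 12 point sources of
34 clusters (~400 clusters) — and fits the zero-years conditional
indicator per fold; coverage of one conditional level is the cleanest
single coverage number, since the three levels' records are derived from
the same clusters and pooling them would double-count. The test suite
exercises the same machinery at reduced sizes (10×10 grid, 4 years, and an
8×9 study for unit fixtures) so the full suite runs in about two minutes.

## The synthetic world: what it does and does not emulate

`build_world()` generates the scaffolding the real analysis reads from
rasters: contiguous column-block countries with nested admin1/admin2
units, smooth Matérn-correlated covariate fields (AR1 evolution for the
time-varying ones), a log-normal population surface with urban hotspots
and mild growth, and a land-cover layer with a small barren fraction
placed in the emptiest pixels. Survey generation places clusters at
population-weighted pixels within a source's country, draws each person's
single-year attainment from the true bin probabilities and a
geometric-decay within-bin profile (ratio 0.65 — within-bin drop-out is
front-loaded, which real single-year data show but binned data cannot),
and supports binned codings (only bin counts retained) and polygon designs
(gamma-distributed unequal weights, dispersion 0.3).

Defaults were chosen once to be realistic at desk scale: zero-years
proportions mostly between 0.1 and 0.6 and mean years between 2 and 12,
improving over time and with urbanicity/access; GP variance 0.25 on the
logit scale with range 4 pixels and AR1 0.7; country-effect variance 0.2;
nugget 0.05; clusters of ~50 persons as in typical household surveys.

What it deliberately does **not** emulate: real geography or projections,
urban/rural sampling stratification (placement is population-weighted
only), migration (the real limitation that attainment change can reflect
population composition), ISCED year-mapping heterogeneity across
countries, non-stationary or anisotropic residual fields, and
reporting/recall error. Passing tests therefore demonstrate that the
*estimator* is correct under its own assumptions and calibrated under the
generative process it claims — not that those assumptions hold for any
particular country's data.

## Known limitations

* Dense-GP fitting scales as the cube of pixels × years; beyond a few
  thousand pixel-times a sparse or mesh-based approximation would be
  required. This is a scope choice, not an oversight.
* Field draws plug in modal hyperparameters; only the intercept's SE mixes
  over hyperparameter uncertainty. Interval coverage for predictive checks
  is nevertheless near nominal because cluster-level predictive noise
  dominates.
* The three conditional indicators and mean years are fit independently;
  no coherence between the composed bin means and the Gaussian mean-years
  surface is enforced.
* Nelder-Mead with a 60-iteration cap trades hyperparameter optimality
  for speed; the plateau-based convergence declaration is documented
  above.
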