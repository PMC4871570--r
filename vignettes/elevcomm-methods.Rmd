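---
title: "Methods: elevational community analysis with elevcomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elevational community analysis with elevcomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevcomm)
```

## The analysis problem

`elevcomm` implements the statistical workflow used to analyse communities
of poorly dispersing animals — the motivating case is flightless ground
beetles caught in pitfall traps — sampled across elevational gradients in
several isolated mountain subregions. The data are (i) a plot table
(subregion, nominal zone elevation, actual plot elevation, latitude),
(ii) a plots-by-species matrix of pooled trap counts, and (iii) a
plots-by-predictors environment table. The workflow answers four questions:

1. *Was sampling sufficient?* — individual- and coverage-based rarefaction
   with extrapolation.
2. *Do richness and abundance increase with elevation?* — negative-binomial
   mixed models with a subregion random intercept.
3. *Is composition structured by subregion and elevation?* — Bray-Curtis
   dissimilarity, NMDS, and PERMANOVA with sequential sums of squares.
4. *Which environmental predictors matter?* — exhaustive AICc model
   averaging with a permutation null.

## Rarefaction and extrapolation

For an abundance vector with `n` individuals, `S_obs` species, `f1`
singletons and `f2` doubletons:

* interpolation is classical hypergeometric rarefaction,
  `S(m) = sum_i [1 - C(n - X_i, m) / C(n, m)]`, evaluated in log space so
  binomial coefficients cannot overflow for large samples;
* extrapolation uses the Chao1 estimate of undetected richness
  `f0 = ((n-1)/n) f1^2 / (2 f2)`, switching to the bias-corrected form
  `((n-1)/n) f1 (f1-1) / (2 (f2+1))` when no doubletons exist (this avoids
  the division by zero and is the standard guard in the
  rarefaction/extrapolation literature);
* sample coverage is estimated as
  `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`, with the analytic
  extension of the same estimator (not resampling) used along the
  extrapolated branch.

Curves run from one individual to twice the observed sample size by
default (`factor = 2`), on a grid of about 40 knots that always includes
the observed point; interpolated and extrapolated branches agree there
exactly. Because the sampling-sufficiency question is posed per subregion,
`subregion_abundances()` pools plot counts within subregions before the
curves are computed; pooling at the subregion rather than the plot level is
an interpretation — the plot-level alternative is available by passing any
single row of the community matrix.

## Trend models

Per-plot observed richness (species with count > 0) and total abundance
are modelled with `fit_nb_glmm()`: a negative-binomial GLMM with
log link, the plot's *actual* elevation as the covariate and subregion as a
random intercept, estimated with the Laplace approximation (via `lme4`).
Plots without any animals enter as zeros; they are data, not missingness.
Elevation is expressed in kilometres and centred. The scale matters only
for reading the coefficient: a slope of 0.75 means richness multiplies by
`exp(0.75) = 2.1` per 1000 m. Whether raw or transformed elevation is the
better covariate is genuinely open; raw kilometres were chosen because the
coefficient stays interpretable and the design spans only 1.5 km.

## Dissimilarity, ordination, PERMANOVA

All multivariate analyses square-root transform the counts and use
Bray-Curtis dissimilarity with a constant *dummy species* of 1e-7 appended
to every plot. The dummy makes empty-vs-empty comparisons equal to 0
instead of undefined, while perturbing ordinary dissimilarities by less
than 1e-6 (a property the tests check). The dummy is appended after the
transform; at 1e-7 the order is numerically irrelevant, but the choice is
recorded here as an interpretation.

NMDS minimises Kruskal stress-1 with vegan's monotone-regression engine
(`monoMDS`, global model), taking the best of 20 starts: the first from
metric scaling, the rest random, under a caller-supplied seed. Because an
NMDS configuration is only defined up to rotation, reflection and
translation, the returned configuration is Procrustes-aligned to the
metric-scaling reference and centred, which makes output reproducible
run-to-run. Plots with zero total abundance are excluded from the
ordination (their position would be determined entirely by the dummy
species) but are retained in the dissimilarity matrix and in every other
stage. Stress-1 rather than stress-2 is the objective, the conventional
choice for reported stress values around 0.2.

`permanova()` partitions the Gower-centred squared dissimilarities
sequentially (Type I): each term's sum of squares is the trace of the
centred matrix projected onto the span the term adds beyond the terms
before it, with subregion entered first and the elevation covariate second.
Pseudo-F uses the full-model residual. P values come from permutation of
residuals under the reduced model (Freedman-Lane): for the term in
position *j*, the residual of the model containing terms `1..j-1` is
row-and-column permuted and the statistic recomputed, with the add-one
correction `P = (1 + #{F* >= F}) / (n_perm + 1)`. This is how a "random
factor" enters the analysis — through the permutation strategy, not through
an expected-mean-squares denominator. Under Euclidean distance on a single
variable the pseudo-F statistics are *exactly* the classical sequential
ANOVA/ANCOVA F statistics, which the tests exploit as an oracle. The
elevation covariate is left unstandardised (sums of squares are invariant
to its scale).

## Predictor screening

`screen_predictors()` removes, within groups of predictors measuring
similar properties (temperature, precipitation, soil, habitat, geography),
one member of any pair correlated at `|r| > 0.90` — strictly greater, so a
pair at exactly 0.90 survives. Which member is dropped is governed by an
explicit priority list rather than a hidden rule; the default priority
keeps annual means and seasonality indices over extreme-period variables
and raw elevation. Cross-group pairs are never removed regardless of
correlation; this is what lets a historical-stability and a
precipitation-seasonality predictor that are correlated at 0.90 both stay
in the model pool — collinearity that the permutation null is then
responsible for calibrating away.

## Summed-weight model averaging with a permutation null

The core estimator, `importance_permtest()`:

1. fits **all** `2^p` subsets of the screened predictors (4096 at p = 12),
   as negative-binomial GLMs of richness (univariate mode) or as sums of
   per-species negative-binomial GLMs of the community matrix
   (multivariate mode, AICc added over species with per-species parameter
   counts and shared n);
2. converts AICc to Akaike weights
   `w_m = exp(-Delta_m/2) / sum exp(-Delta/2)` and sums, for each
   predictor, the weights of the models containing it (no Delta-AICc
   cut-off: the whole model set contributes);
3. repeats the computation on `n_null` datasets built by permuting response
   rows against the *fixed* predictor table — whole community-matrix rows
   in multivariate mode, so species co-occurrence and the predictor
   correlation structure are both preserved, which is exactly what the
   calibration requires;
4. reports, per predictor: observed summed weight (a), null mean (b),
   null SD (c), the standardised effect size `(a-b)/c`, and an upper-tail
   permutation P with the add-one correction.

The parameter count for AICc includes the intercept, the slopes and the
dispersion parameter theta, so the penalty is consistent across the model
set; theta is re-estimated in every model. Models whose small-sample
correction is undefined (`n <= k+1`) are dropped from the weight
normalisation rather than imputed — the AICc guard *is* the defence
against over-parameterisation, and silently patching it would defeat it.
The one-sided upper tail reflects the hypothesis that a predictor's summed
weight is *greater* than expected under no association.

### Numerical core

Each analysis requires thousands to millions of NB GLM fits (a null run at
p = 12 is 4096 x n_null model sets), so the fitting engine is compiled
code: IRLS for the coefficients alternating with safeguarded Newton updates
of theta in log space, converging when the relative log-likelihood change
falls below 1e-8 (at most 200 alternations). Three numerical choices
matter:

* **theta bounds** — theta is capped at 1e8, representing the Poisson
  limit for equidispersed responses, and floored at 1e-5 for degenerate
  near-all-zero responses;
* **integer-count recurrences** — for integer counts the
  digamma/trigamma/lgamma differences in the theta score collapse to exact
  finite sums over tail frequencies (`digamma(y+t) - digamma(t) =
  sum_{j<y} 1/(t+j)`), removing special-function calls from the hot loop;
* **step-halved IRLS** — the IRLS step is halved until the likelihood does
  not decrease, and convergence is judged on the likelihood plateau rather
  than on the coefficients. Rare species induce quasi-separation: their
  coefficients legitimately diverge while the fitted values and the
  likelihood stabilise, and the plateau value is what AICc needs. Fits are
  warm-started from the parent subset (one predictor dropped).

The R-level fit agrees with `MASS::glm.nb` to ~1e-8 in log-likelihood on
regular data, and with a direct `optim()` maximisation of the NB likelihood
on small toys; both comparisons are in the test suite, as is the exact
decomposition of the multivariate AICc into independent univariate fits.
All-zero species columns are dropped before fitting (their likelihood is
degenerate and permutation-invariant); an optional minimum-prevalence
filter is exposed but off by default.

## The synthetic survey generator

No field data ship with the package, so `sim_design()`,
`sim_environment()` and `sim_community()` generate surveys with the
structure the analysis assumes. The default design is five subregions with
23 elevational zones about 200 m apart (4 + 6 + 4 + 6 + 3), three plots
per zone (69 plots), three traps per plot and twelve months — 2,484
trap-months; actual plot elevations jitter uniformly within ±50 m of the
zone value so that the elevation covariate varies within zones.

**Environment.** Seventeen named predictors are generated by a Gaussian
copula: a target correlation matrix over (elevation, latitude, simulated
predictors) is assembled from latent property factors — guaranteeing
positive-definiteness for the defaults — and predictors are drawn
conditional on the observed z-scored plot elevations and latitudes, so
realised pairwise correlations match targets in expectation. Users can
override individual pairs (`env_targets`); an override set that breaks
positive-definiteness errors out naming the pairs. Key default structure:
temperature predictors track elevation at a lapse rate of 1 °C per 200 m
(their scale is derived from the lapse rate and the design's elevation
spread, so the regression slope on elevation is the lapse rate itself);
extreme-temperature and extreme-precipitation variables correlate with
their annual summaries above 0.94, so screening reliably removes the five
redundant predictors (17 to 12); and historical vegetation stability and
precipitation seasonality are correlated at 0.90 — high collinearity that
survives screening by design, exercising the permutation null's job.
Bounded scores (habitat heterogeneity, treefall disturbance on a 0–4
scale, aspect in degrees) use probability-integral marginal transforms.

**Community.** Counts are negative binomial (theta = 1 by default) with a
log-link mean combining log-normal species intercepts (mean −2.2, SD 1.5 on
the log scale at the 800 m reference), a common elevation slope of 3.5 per
km, community-wide subregion intercepts (SD 0.5), and subregional endemism:
33% of species are confined to one home subregion with structural zeros
elsewhere. These defaults were calibrated once against the qualitative
structure such surveys report — steeply increasing richness and abundance, totals of
roughly a thousand to a few thousand individuals across 43 species
(varying several-fold between seeds), upland plots holding around ten
species, and a third or more of the lowest-elevation plots catching
nothing at all — and then frozen. An optional trap-loss
flag thins counts binomially as if a configured number of trap-months had
been lost (off by default; lost catches are reported as non-influential in
the motivating study design).

What the generator does *not* emulate: spatial autocorrelation beyond the
subregion and elevation structure, within-subregion distance decay (the
relevant decay rate is not reported for such surveys, so it is left out
rather than invented), monthly phenology, and trap-level variation.
Passing tests therefore demonstrate that the *estimators* behave correctly
under known data-generating processes — unbiased slope recovery, nominal
type-I error, power against strong effects — not that any particular field
system satisfies those processes.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route:
Monte-Carlo subsampling for rarefaction, `MASS::isoMDS` for NMDS stress,
classical ANOVA and `vegan::adonis2` for PERMANOVA, `MASS::glm.nb` and
brute-force `optim()` for the NB engine, and explicit enumeration for the
weighting identities. The stochastic suites are scaled to keep the full
run on one CPU comfortable while retaining statistical resolution:

* null calibration of the importance test: 200 independent datasets,
  p = 6 predictors, n = 45 plots, 199 null permutations each; rejection at
  the nominal 0.05 is required to fall inside the binomial 95% interval;
* the same for PERMANOVA with 200 datasets and 199 permutations;
* power: 2 of 6 predictors drive richness with unit log-scale effects
  (a "strong" effect: one SD of the predictor doubles the expected count
  e-fold); both must rank top-2 by SES with P <= 0.05 in at least 90% of
  50 replicates;
* mixed-model recovery: 100 simulated surveys with a true elevation slope
  of 0.75 per km; the Monte-Carlo confidence interval of the mean estimate
  must cover the truth.

The acceptance script (`scripts/acceptance.R`) reruns the whole pipeline
at the default study conditions; its model-averaging stage uses 199 null
datasets for richness and 19 for composition with a prevalence filter of
three plots — the composition null is by far the most expensive computation
(each null dataset refits 4096 models for every species), and these sizes
keep a complete from-scratch run in the tens of minutes while leaving the
standardised effect sizes stable for reporting.

## Known limitations

* The multivariate AICc treats species as independent given the
  predictors; correlated residuals across species are not modelled (the
  permutation null preserves them, which is the usual defence).
* Because composition-mode AICc values are sums over species, their
  differences between models grow with the number of species, and the
  Akaike weights often concentrate on one or a few models. The summed
  weights then approach 0/1 and the null SD can be very small, making the
  SES numerically extreme; in this regime the permutation P value (which
  is exact under exchangeability regardless of weight concentration) and
  the summed weights themselves are the summaries to interpret, not the
  SES magnitude.
* `glmer.nb` occasionally reports singular random-effect fits when the
  subregion variance is genuinely near zero; the wrapper flags rather than
  hides this.
* The screening rule is greedy (lowest-priority member of any offending
  pair, iterated); it is deterministic and auditable but not globally
  optimal in the number of removals.
* Coverage-based rarefaction reports the analytic coverage extension, not
  bootstrap intervals; uncertainty bands are out of scope.

## Session info

```{r}
sessionInfo()
```
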