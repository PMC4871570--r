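# elevcomm

Community analysis for elevationally stratified count data — the analysis
stack used for surveys of flightless, dispersal-limited insects (pitfall
trap catches of ground beetles) across the isolated mountain subregions of
a tropical rainforest region, usable for any plots × species count matrix
with plot-level environmental predictors.

For community ecologists asking four linked questions:

1. **Sampling sufficiency** — individual- and coverage-based rarefaction
   with extrapolation to twice the sample size; sample coverage estimated
   from singletons/doubletons as
   `Ĉ = 1 − (f₁/n)·((n−1)f₁ / ((n−1)f₁ + 2f₂))`.
2. **Elevational trends** — negative-binomial GLMMs (Laplace
   approximation, subregion random intercept) of per-plot richness and
   abundance on actual elevation.
3. **Community structure** — square-root transformed abundances,
   Bray-Curtis dissimilarity with a 1e-7 dummy species (so empty plots
   compare as identical rather than undefined), NMDS (Kruskal stress-1,
   multiple restarts), environmental vector fitting, and distance-based
   PERMANOVA with Type I (sequential) sums of squares and P values from
   4,999 permutations of residuals under the reduced model.
4. **Predictor importance** — the core estimator `importance_permtest()`:
   all `2^p` negative-binomial models of richness (univariate) or of every
   species (multivariate) are fitted, AICc-weighted
   (`wₘ = exp(−Δₘ/2)/Σ exp(−Δ/2)`), and each predictor scored by its
   **summed Akaike weight** `SWⱼ = Σ_{m ∋ j} wₘ`. Observed `SWⱼ` (a) is
   calibrated against `n_null` datasets with permuted response rows:
   null mean (b), null SD (c), standardised effect size `SES = (a−b)/c`,
   and an upper-tail permutation P value.

Predictors first pass correlation screening (`screen_predictors()`): within
groups of similar properties, one member of any pair with `|r| > 0.90` is
removed by an explicit priority list (strictly greater — a cross-group pair
at exactly 0.90 survives).

Because the motivating field data are not deposited, the package ships a
first-class synthetic survey generator (`sim_design()`,
`sim_environment()`, `sim_community()`) reproducing the study conditions:
5 subregions, 23 elevational zones (~200 m apart) × 3 plots = 69 plots,
2,484 trap-months, 17 inter-correlated predictors (including a 0.90
history/precipitation-seasonality pair), 43 species with 33% subregional
endemics, negative-binomial counts rising steeply with elevation, and
empty lowland plots.

## Worked example

```r
library(elevcomm)

cfg   <- sim_config(seed = 1)          # the default survey conditions
plots <- sim_design(cfg)               # 69 plots in 5 subregions
env   <- sim_environment(plots, cfg)   # 17 predictors
comm  <- sim_community(plots, env, cfg)

gm  <- default_env_groups()
scr <- screen_predictors(env, gm$groups, priority = gm$priority)
print(scr)
#> Predictor screening at |r| > 0.90 (within property groups)
#> retained 12 of 17 predictors
#> removed:
#>   Elevation (r = -0.966 with Ave.T)
#>   Min.T (r = 0.981 with Max.T)
#>   Max.T (r = 0.982 with Ave.T)
#>   P.Dry.Q (r = 0.957 with Ann.P)
#>   P.Wet.Q (r = 0.960 with Ann.P)

permanova(bray_curtis(comm), plots, c("subregion", "actual_elev"),
          n_perm = 999, seed = 1)
#> PERMANOVA (sequential SS, 999 permutations of residuals under reduced model)
#>         term Df      SS pseudoF     P
#>    subregion  4  2.6683  2.1534 0.001
#>  actual_elev  1  2.0337  6.5651 0.001
#>     Residual 63 19.5158      NA    NA
#>        Total 68 24.2178      NA    NA

importance_permtest(rowSums(comm > 0),
                    scr$env[c("Hist.veg", "Ave.T", "Seas.P",
                              "Treefall", "Litter", "AWC")],
                    "univariate", n_null = 199, seed = 1)
#> Summed-Akaike-weight importance (univariate mode, 64 models, 199 null permutations)
#>  variable summed_weight_obs null_mean null_sd    SES     P
#>    Seas.P             0.895     0.344   0.097  5.702 0.005
#>     Ave.T             0.938     0.353   0.130  4.511 0.005
#>  Hist.veg             0.825     0.342   0.109  4.430 0.005
#>  Treefall             0.663     0.337   0.126  2.581 0.040
#>    Litter             0.327     0.326   0.120  0.009 0.325
#>       AWC             0.264     0.334   0.140 -0.499 0.595
```

Reading the table: `Seas.P` appears in models carrying 89.5% of the total
Akaike weight, against 34.4% ± 9.7% expected when richness is shuffled
against the predictors — 5.7 null SDs above expectation, P = 1/200. The
climate/history predictors that the generator wired to elevation and to
each other rank on top; noise predictors sit at SES ≈ 0. The permutation
null, not the raw summed weight, is what makes these comparable across
predictors under collinearity (Hist.veg and Seas.P are correlated at 0.90
by design).

`run_pipeline(default_run_config(seed = 1), "out/")` executes every stage
(screening → per-subregion rarefaction → trend GLMMs → dissimilarity /
NMDS / vector fit → PERMANOVA → univariate + multivariate averaging) and
writes each table as CSV plus a JSON manifest recording the seed.

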