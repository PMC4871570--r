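# Synthetic elevational community survey generator. Emulates a five-
# subregion pitfall-trap design: elevational zones ~200 m apart with three
# plots each, an environment table of 17 named predictors with realistic
# inter-correlations (induced by a Gaussian copula whose target correlation
# matrix is built from latent elevation/latitude/property factors), and
# negative-binomial community counts with elevationally increasing
# abundance, subregional endemism and empty lowland plots.

default_zone_scheme <- function() {
  list(
    "Spec Uplands"          = c(350, 600, 800, 1000),
    "Atherton Uplands"      = c(100, 200, 400, 600, 800, 1000),
    "Bellenden Ker Uplands" = c(1000, 1200, 1400, 1600),
    "Carbine Uplands"       = c(100, 400, 600, 800, 1000, 1200),
    "Windsor Uplands"       = c(900, 1100, 1300))
}

default_subregion_latitudes <- function() {
  c("Spec Uplands" = -18.95, "Atherton Uplands" = -17.55,
    "Bellenden Ker Uplands" = -17.26, "Carbine Uplands" = -16.50,
    "Windsor Uplands" = -16.25)
}

# Latent-factor loadings defining the default target correlation structure
# of the simulated predictors. Columns: elevation and latitude (observed,
# z-scored), then shared property factors (temperature, precipitation,
# history, soil, disturbance). Rows with marginal = "pnorm4"/"pnorm360" get
# a probability-integral marginal transform to a bounded score.
env_factor_loadings <- function() {
  L <- rbind(
    #            elev    lat     Ft     Fp     Fh    Fs     Fd
    Ave.T    = c(-0.97,  0.00,  0.20,  0.00,  0.00, 0.00,  0.00),
    Seas.T   = c(-0.45,  0.00,  0.30,  0.00,  0.00, 0.00,  0.00),
    Max.T    = c(-0.95,  0.00,  0.28,  0.00,  0.00, 0.00,  0.00),
    Min.T    = c(-0.95,  0.00,  0.26,  0.00,  0.00, 0.00,  0.00),
    Ann.P    = c( 0.45,  0.00,  0.00,  0.88,  0.00, 0.00,  0.00),
    Seas.P   = c(-0.34,  0.25,  0.00, -0.224, 0.87, 0.00,  0.00),
    P.Wet.Q  = c( 0.42,  0.00,  0.00,  0.88,  0.00, 0.00,  0.00),
    P.Dry.Q  = c( 0.33,  0.00,  0.00,  0.92,  0.00, 0.00,  0.00),
    AWC      = c( 0.00,  0.00,  0.00,  0.00,  0.00, 0.50,  0.00),
    TWI      = c( 0.00,  0.00,  0.00,  0.00,  0.00, 0.45,  0.00),
    Habitat  = c( 0.15,  0.00,  0.00,  0.00,  0.00, 0.00,  0.00),
    Treefall = c(-0.34,  0.00,  0.00,  0.00,  0.00, 0.00,  0.50),
    Litter   = c( 0.10,  0.00,  0.00,  0.00,  0.00, 0.00, -0.45),
    Aspect   = c( 0.00,  0.00,  0.00,  0.00,  0.00, 0.00,  0.00),
    Hist.veg = c( 0.03,  0.25,  0.00, -0.25,  0.91, 0.00,  0.00))
  colnames(L) <- c("elev", "lat", "Ft", "Fp", "Fh", "Fs", "Fd")
  L
}

env_marginals <- function() {
  data.frame(
    var = rownames(env_factor_loadings()),
    mean = c(20, 1.5, 28, 12, 3500, 85, 1800, 300, 60, 9, NA, NA, 40, NA, 0.6),
    sd   = c(NA, 0.25, NA, NA, 1200, 15, 700, 120, 15, 2, NA, NA, 12, NA, 0.15),
    transform = c("lapse", "linear", "lapse", "lapse", "linear", "linear",
                  "linear", "linear", "linear", "linear", "pnorm4", "pnorm4",
                  "linear", "pnorm360", "linear"))
}

#' Default predictor property groups and screening priority
#'
#' Group map and priority list for [screen_predictors()] matching the 17
#' predictors produced by [sim_environment()]. Only same-group pairs are
#' eligible for removal; the priority list prefers the annual-mean and
#' seasonality summaries over extreme-period variables and raw elevation.
#'
#' @return list with elements `groups` (named character vector) and
#'   `priority` (character vector, most-preferred first).
#' @export
default_env_groups <- function() {
  groups <- c(
    Ave.T = "temperature", Seas.T = "temperature", Max.T = "temperature",
    Min.T = "temperature", Elevation = "temperature",
    Ann.P = "precipitation", Seas.P = "precipitation",
    P.Wet.Q = "precipitation", P.Dry.Q = "precipitation",
    AWC = "soil", TWI = "soil",
    Habitat = "habitat", Treefall = "habitat", Litter = "habitat",
    Latitude = "geography", Aspect = "geography",
    Hist.veg = "history")
  priority <- c("Ave.T", "Seas.T", "Ann.P", "Seas.P", "Hist.veg", "AWC",
                "TWI", "Habitat", "Treefall", "Litter", "Latitude", "Aspect",
                "P.Wet.Q", "P.Dry.Q", "Max.T", "Min.T", "Elevation")
  list(groups = groups, priority = priority)
}

#' Configuration for the synthetic survey generator
#'
#' Bundles every tunable of the generator with defaults reproducing the
#' structure of a five-subregion elevational pitfall survey: 23 zones
#' (three plots each, zones ~200 m apart), a 17-predictor environment table
#' with a 0.90 history/precipitation-seasonality correlation, and
#' negative-binomial counts rising steeply with elevation so that lowland
#' plots are frequently empty while upland plots hold tens of individuals.
#'
#' @param seed integer master seed; each generator stage draws from a
#'   deterministic offset of it.
#' @param n_species number of species in the pool.
#' @param endemic_fraction proportion of species confined to a single
#'   (random) home subregion.
#' @param elev_effect common log-link slope of per-species mean abundance on
#'   elevation, per km.
#' @param elev_effect_sd per-species SD around `elev_effect`.
#' @param intercept_mean,intercept_sd log-scale abundance intercepts across
#'   species at the reference elevation (800 m).
#' @param subregion_sd SD of community-wide subregion random intercepts.
#' @param dispersion negative-binomial size parameter theta.
#' @param lapse_rate temperature decrease per metre of elevation
#'   (default 1/200 degree C per m).
#' @param traps_per_plot,months trap-month bookkeeping.
#' @param plots_per_zone plots per elevational zone.
#' @param zones named list of zone elevations per subregion.
#' @param latitudes named vector of subregion latitudes (decimal degrees).
#' @param jitter half-width (m) of uniform jitter of actual plot elevation
#'   around its zone value.
#' @param env_targets optional data frame (`v1`, `v2`, `r`) of pairwise
#'   correlation targets overriding the default structure; `"elev"` and
#'   `"lat"` refer to the observed design variables.
#' @param lose_traps,lost_catches optionally thin counts as if some
#'   trap-months had been lost (default off).
#' @return a validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' design_arithmetic(cfg)
#' @export
sim_config <- function(seed = 1L, n_species = 43, endemic_fraction = 14 / 43,
                       elev_effect = 3.5, elev_effect_sd = 0,
                       intercept_mean = -2.2, intercept_sd = 1.5,
                       subregion_sd = 0.5, dispersion = 1,
                       lapse_rate = 1 / 200, traps_per_plot = 3, months = 12,
                       plots_per_zone = 3, zones = default_zone_scheme(),
                       latitudes = default_subregion_latitudes(),
                       jitter = 50, env_targets = NULL,
                       lose_traps = FALSE, lost_catches = 32) {
  if (length(zones) == 0 || any(lengths(zones) == 0))
    stop("zone scheme must be non-empty")
  if (endemic_fraction < 0 || endemic_fraction > 1)
    stop("'endemic_fraction' must be in [0, 1]")
  if (dispersion <= 0) stop("'dispersion' (theta) must be > 0")
  if (!all(names(zones) %in% names(latitudes)))
    stop("'latitudes' must cover every subregion in 'zones'")
  if (!is.null(env_targets)) {
    env_targets <- as.data.frame(env_targets)
    stopifnot(all(c("v1", "v2", "r") %in% names(env_targets)))
    if (any(abs(env_targets$r) >= 1))
      stop("correlation targets must satisfy |r| < 1")
  }
  structure(list(seed = as.integer(seed), n_species = n_species,
                 endemic_fraction = endemic_fraction,
                 elev_effect = elev_effect, elev_effect_sd = elev_effect_sd,
                 intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 subregion_sd = subregion_sd, dispersion = dispersion,
                 lapse_rate = lapse_rate, traps_per_plot = traps_per_plot,
                 months = months, plots_per_zone = plots_per_zone,
                 zones = zones, latitudes = latitudes, jitter = jitter,
                 env_targets = env_targets, lose_traps = lose_traps,
                 lost_catches = lost_catches),
            class = "sim_config")
}

#' Design arithmetic of a survey configuration
#'
#' @param config a [sim_config()].
#' @return list with `n_zones`, `n_plots` and `trap_months`
#'   (plots x traps per plot x months), all exact integers.
#' @export
design_arithmetic <- function(config) {
  n_zones <- as.integer(sum(lengths(config$zones)))
  n_plots <- as.integer(n_zones * config$plots_per_zone)
  list(n_zones = n_zones, n_plots = n_plots,
       trap_months = as.integer(n_plots * config$traps_per_plot *
                                  config$months))
}

#' Generate the plot design table
#'
#' One row per plot: subregion, nominal zone elevation, actual elevation
#' (zone value plus uniform jitter) and latitude.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `plot_id`, `subregion`, `zone_elev`,
#'   `actual_elev`, `latitude`.
#' @export
sim_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    rows <- list()
    for (sr in names(config$zones)) {
      abbr <- paste(substr(strsplit(sr, " ")[[1]], 1, 1), collapse = "")
      for (z in config$zones[[sr]]) {
        for (p in seq_len(config$plots_per_zone)) {
          rows[[length(rows) + 1L]] <- data.frame(
            plot_id = sprintf("%s_%04d_%d", abbr, z, p),
            subregion = sr, zone_elev = z,
            actual_elev = z + runif(1, -config$jitter, config$jitter),
            latitude = config$latitudes[[sr]] + rnorm(1, sd = 0.05))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- out$plot_id
    if (anyDuplicated(out$plot_id)) stop("plot ids are not unique")
    out$subregion <- factor(out$subregion, levels = names(config$zones))
    out
  })
}

# Assemble the target correlation matrix over (elev, lat, simulated
# predictors), apply user overrides, and verify positive definiteness.
build_env_sigma <- function(config) {
  L <- env_factor_loadings()
  vars <- rownames(L)
  full <- rbind(elev = c(1, 0, rep(0, ncol(L) - 2)),
                lat  = c(0, 1, rep(0, ncol(L) - 2)),
                L)
  Sigma <- full %*% t(full)
  diag(Sigma) <- 1
  tg <- config$env_targets
  if (!is.null(tg)) {
    for (i in seq_len(nrow(tg))) {
      a <- tg$v1[i]; b <- tg$v2[i]
      if (!all(c(a, b) %in% rownames(Sigma)))
        stop("unknown variable in correlation target: ", a, " / ", b)
      Sigma[a, b] <- Sigma[b, a] <- tg$r[i]
    }
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    offend <- if (!is.null(tg))
      paste(paste0("(", tg$v1, ", ", tg$v2, ")"), collapse = ", ")
    else "(default structure)"
    stop("correlation target set is not positive definite; ",
         "offending pairs: ", offend)
  }
  Sigma
}

#' Generate the plot-level environment table
#'
#' Simulates the 17 named predictors via a Gaussian copula: a target
#' correlation matrix over (elevation, latitude, simulated predictors) is
#' assembled from latent property factors (overridable via
#' `config$env_targets`), and predictors are drawn conditional on the
#' observed, z-scored plot elevations and latitudes so that realised
#' pairwise correlations match the targets in expectation. Temperature
#' predictors are scaled so their regression slope on actual elevation is
#' the configured lapse rate (-1 degree C per 200 m by default); `Elevation`
#' and `Latitude` are copied from the design. Bounded scores (Habitat,
#' Treefall, Aspect) use a probability-integral marginal transform.
#'
#' @param plots design table from [sim_design()].
#' @param config a [sim_config()].
#' @return data frame (row names = plot ids) with the 17 predictors.
#' @export
sim_environment <- function(plots, config) {
  stopifnot(inherits(config, "sim_config"), nrow(plots) > 0)
  Sigma <- build_env_sigma(config)
  vars <- rownames(Sigma)[-(1:2)]
  n <- nrow(plots)
  zf <- cbind(elev = as.numeric(scale(plots$actual_elev)),
              lat = as.numeric(scale(plots$latitude)))
  S_ff <- Sigma[1:2, 1:2]
  S_fs <- Sigma[1:2, vars, drop = FALSE]
  S_ss <- Sigma[vars, vars]
  B <- solve(S_ff, S_fs)                   # 2 x p regression coefficients
  cond_mean <- zf %*% B
  cond_cov <- S_ss - t(S_fs) %*% B
  # guard tiny asymmetries before the Cholesky
  cond_cov <- (cond_cov + t(cond_cov)) / 2
  Lc <- chol(cond_cov + diag(1e-10, nrow(cond_cov)))
  with_seed(config$seed + 1L, {
    Z <- cond_mean + matrix(rnorm(n * length(vars)), n) %*% Lc
    colnames(Z) <- vars
    marg <- env_marginals()
    sd_elev <- sd(plots$actual_elev)
    out <- data.frame(row.names = plots$plot_id)
    for (i in seq_len(nrow(marg))) {
      v <- marg$var[i]
      z <- Z[, v]
      out[[v]] <- switch(marg$transform[i],
        lapse = marg$mean[i] +
          (config$lapse_rate * sd_elev / abs(Sigma["elev", v])) * z,
        linear = marg$mean[i] + marg$sd[i] * z,
        pnorm4 = 4 * pnorm(z),
        pnorm360 = 360 * pnorm(z))
    }
    out$Elevation <- plots$actual_elev
    out$Latitude <- plots$latitude
    out
  })
}

#' Generate a synthetic community matrix
#'
#' Per-species counts are drawn from a negative binomial with log-link mean
#' depending on plot elevation (common slope `elev_effect` per km, optional
#' per-species heterogeneity), log-normal species intercepts, and
#' community-wide subregion random intercepts. A configured fraction of
#' species are subregional endemics whose counts are structurally zero
#' outside their home subregion. All-zero plots (typical in lowland zones)
#' are valid output.
#'
#' @param plots design table from [sim_design()].
#' @param env environment table from [sim_environment()] (row-aligned with
#'   `plots`; reserved for predictor-driven extensions, elevation is taken
#'   from `plots`).
#' @param config a [sim_config()].
#' @return integer matrix (plots x species) with dimnames.
#' @export
sim_community <- function(plots, env, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(env) && nrow(env) != nrow(plots))
    stop("'env' rows must align with 'plots'")
  n <- nrow(plots)
  S <- config$n_species
  with_seed(config$seed + 2L, {
    alpha <- rnorm(S, config$intercept_mean, config$intercept_sd)
    beta <- rnorm(S, config$elev_effect, config$elev_effect_sd)
    subregions <- levels(plots$subregion)
    b_sr <- setNames(rnorm(length(subregions), 0, config$subregion_sd),
                     subregions)
    n_end <- round(config$endemic_fraction * S)
    endemic_home <- rep(NA_character_, S)
    if (n_end > 0)
      endemic_home[sample.int(S, n_end)] <-
        sample(subregions, n_end, replace = TRUE)
    elev_km <- (plots$actual_elev - 800) / 1000
    comm <- matrix(0L, n, S,
                   dimnames = list(plots$plot_id,
                                   sprintf("sp%02d", seq_len(S))))
    for (s in seq_len(S)) {
      mu <- exp(alpha[s] + beta[s] * elev_km +
                b_sr[as.character(plots$subregion)])
      cnt <- rnbinom(n, mu = mu, size = config$dispersion)
      if (!is.na(endemic_home[s]))
        cnt[plots$subregion != endemic_home[s]] <- 0L
      comm[, s] <- cnt
    }
    if (config$lose_traps) {
      tm <- config$traps_per_plot * config$months
      lost <- stats::rmultinom(1, config$lost_catches, rep(1, n))[, 1]
      keep_frac <- pmax(0, tm - lost) / tm
      for (i in seq_len(n))
        comm[i, ] <- rbinom(S, comm[i, ], keep_frac[i])
    }
    attr(comm, "endemic_home") <- endemic_home
    comm
  })
}
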