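test_that("default design reproduces the five-subregion survey arithmetic", {
  cfg <- sim_config(seed = 1)
  da <- design_arithmetic(cfg)
  expect_identical(da$n_zones, 23L)
  expect_identical(da$n_plots, 69L)
  expect_identical(da$trap_months, 2484L)
  plots <- sim_design(cfg)
  expect_equal(nrow(plots), 69)
  expect_false(anyDuplicated(plots$plot_id) > 0)
  # every (subregion, zone) has exactly plots_per_zone plots
  counts <- table(plots$subregion, plots$zone_elev)
  expect_true(all(counts %in% c(0, cfg$plots_per_zone)))
  # actual elevation stays within the configured jitter of the zone value
  expect_true(all(abs(plots$actual_elev - plots$zone_elev) <= cfg$jitter))
})

test_that("minimal designs and invalid zone schemes are handled", {
  cfg <- sim_config(zones = list(X = 500), latitudes = c(X = -17),
                    plots_per_zone = 3)
  expect_equal(nrow(sim_design(cfg)), 3)
  expect_error(sim_config(zones = list()), "non-empty")
  expect_error(sim_config(dispersion = 0), "theta")
  expect_error(sim_config(endemic_fraction = 1.5), "endemic_fraction")
})

test_that("generators are pure functions of the configuration", {
  cfg <- sim_config(seed = 42)
  p1 <- sim_design(cfg); p2 <- sim_design(cfg)
  expect_identical(p1, p2)
  e1 <- sim_environment(p1, cfg); e2 <- sim_environment(p2, cfg)
  expect_identical(e1, e2)
  c1 <- sim_community(p1, e1, cfg); c2 <- sim_community(p2, e2, cfg)
  expect_identical(c1, c2)
  # and global RNG state is untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(sim_design(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("environment table hits its correlation and lapse-rate targets", {
  rs <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s)
    p <- sim_design(cfg)
    e <- sim_environment(p, cfg)
    cor(e$Hist.veg, e$Seas.P)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.90), 0.05)

  cfg <- sim_config(seed = 3)
  p <- sim_design(cfg)
  e <- sim_environment(p, cfg)
  expect_equal(ncol(e), 17)
  # temperature lapse: ~ -1 degree per 200 m of elevation
  slope <- coef(lm(e$Ave.T ~ p$actual_elev))[2]
  expect_lt(abs(slope * 200 + 1), 0.15)
  expect_lt(cor(e$Ave.T, p$actual_elev), -0.9)
})

test_that("realised correlations converge to the target as n grows", {
  cfg <- sim_config(seed = 11, plots_per_zone = 22)  # 506 plots
  p <- sim_design(cfg)
  e <- sim_environment(p, cfg)
  expect_lt(abs(cor(e$Hist.veg, e$Seas.P) - 0.90), 0.03)
  expect_lt(abs(cor(e$Ann.P, e$P.Wet.Q) - 0.963), 0.03)
})

test_that("infeasible correlation targets fail naming the offending pairs", {
  bad <- data.frame(v1 = c("Hist.veg", "Hist.veg", "Seas.P"),
                    v2 = c("Seas.P", "Ann.P", "Ann.P"),
                    r = c(0.95, 0.95, -0.95))
  cfg <- sim_config(seed = 1, env_targets = bad)
  p <- sim_design(cfg)
  expect_error(sim_environment(p, cfg), "positive definite")
  expect_error(sim_environment(p, cfg), "Hist.veg")
  expect_error(sim_config(env_targets = data.frame(v1 = "a", v2 = "b", r = 1)),
               "< 1")
})

test_that("endemic species never occur outside their home subregion", {
  for (s in 1:5) {
    sv <- tiny_survey(seed = s)
    home <- attr(sv$comm, "endemic_home")
    for (j in which(!is.na(home))) {
      away <- sv$plots$subregion != home[j]
      expect_true(all(sv$comm[away, j] == 0))
    }
  }
})

test_that("a null community has no systematic elevation trend in richness", {
  slopes <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s, elev_effect = 0, intercept_sd = 0,
                      intercept_mean = -0.5, subregion_sd = 0)
    p <- sim_design(cfg)
    cm <- sim_community(p, NULL, cfg)
    coef(lm(rowSums(cm > 0) ~ p$actual_elev))[2] * 1000
  }, numeric(1))
  ci <- mean(slopes) + c(-1, 1) * 2 * sd(slopes) / sqrt(length(slopes))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("community counts are non-negative integers on NB marginals", {
  sv <- tiny_survey(seed = 9)
  expect_true(all(sv$comm >= 0))
  expect_true(all(sv$comm == round(sv$comm)))
  # optional trap-loss thinning never increases counts
  cfg2 <- tiny_config(seed = 9, lose_traps = TRUE, lost_catches = 10)
  cm2 <- sim_community(sv$plots, sv$env, cfg2)
  expect_true(all(cm2 >= 0))
})
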