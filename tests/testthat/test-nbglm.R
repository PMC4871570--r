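test_that("NB GLM matches an independent maximum-likelihood fit", {
  set.seed(1)
  n <- 69
  x <- rnorm(n)
  y <- rnbinom(n, mu = exp(1 + 0.5 * x), size = 1.3)
  f <- fit_nb_glm(y, cbind(1, x))
  m <- MASS::glm.nb(y ~ x)
  expect_equal(unname(coef(f)), unname(coef(m)), tolerance = 1e-5)
  expect_equal(f$theta, m$theta, tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(summary(m)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("NB log-likelihood is within 1e-4 of a brute-force optimum", {
  set.seed(2)
  n <- 20
  x <- rnorm(n)
  y <- rnbinom(n, mu = exp(0.8 + 0.6 * x), size = 2)
  f <- fit_nb_glm(y, cbind(1, x))
  negll <- function(par) {
    mu <- exp(par[1] + par[2] * x)
    -sum(dnbinom(y, mu = mu, size = exp(par[3]), log = TRUE))
  }
  o <- optim(c(0, 0, 0), negll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(f$loglik - (-o$value)), 1e-4)
  expect_gte(f$loglik, -o$value - 1e-4)  # ours is not worse than the oracle
  # local optimality: perturbing the coefficients never improves it
  for (eps in c(0.01, -0.01)) {
    expect_lt(sum(dnbinom(y, mu = exp(coef(f)[1] + eps + coef(f)[2] * x),
                          size = f$theta, log = TRUE)), f$loglik + 1e-10)
  }
})

test_that("NB GLM degenerate and limiting cases behave as specified", {
  # constant response, intercept only: fitted mean is the sample mean
  f <- fit_nb_glm(rep(5L, 20))
  expect_equal(unname(exp(coef(f)[1])), 5, tolerance = 1e-8)
  # equidispersed data: theta at the cap, Poisson log-likelihood
  set.seed(3)
  yp <- rpois(200, 5)
  fp <- fit_nb_glm(yp)
  expect_equal(fp$theta, 1e8)
  expect_equal(fp$loglik, sum(dpois(yp, mean(yp), log = TRUE)),
               tolerance = 1e-6)
  # all-zero response: boundary flag and warning
  expect_warning(f0 <- fit_nb_glm(rep(0L, 10)), "all-zero")
  expect_true(f0$boundary)
  expect_equal(f0$loglik, 0)
  # input validation
  expect_error(fit_nb_glm(c(-1, 2)), "non-negative")
  expect_error(fit_nb_glm(c(1, 2, 3), cbind(1, c(2, 2, 2))), "rank")
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(-10, 3, 10), 30)
  expect_equal(aicc(0, 1, 100), 2 + 4 / 98)
  expect_error(aicc(-10, 4, 5), "n <= k \\+ 1")
  # AICc > AIC always, and the gap vanishes as n grows
  expect_gt(aicc(-10, 3, 10), -2 * -10 + 2 * 3)
  expect_lt(aicc(-10, 3, 1e7) - (20 + 6), 1e-5)
})

test_that("NB GLMM recovers fixed effects and nests the GLM", {
  # fewer than two groups: falls back to the fixed-effects GLM
  set.seed(4)
  x <- rnorm(40)
  y <- rnbinom(40, mu = exp(1 + 0.4 * x), size = 2)
  expect_warning(fb <- fit_nb_glmm(y, x, rep("one", 40)), "fewer than 2")
  fg <- fit_nb_glm(y, cbind(1, x))
  expect_equal(fb$table$estimate, unname(coef(fg)), tolerance = 1e-8)
  # zero simulated group variance: GLMM coefficients match GLM closely
  g <- factor(rep(1:8, each = 15))
  x2 <- rnorm(120)
  y2 <- rnbinom(120, mu = exp(1 + 0.5 * x2), size = 2)
  fm <- fit_nb_glmm(y2, x2, g)
  fg2 <- fit_nb_glm(y2, cbind(1, x2))
  expect_lt(max(abs(fm$table$estimate - coef(fg2))), 1e-3)
  expect_lt(fm$ranef_var, 0.05)
  # shifting all means by a common constant moves only the intercept
  fm2 <- fit_nb_glmm(y2 * 1L, cbind(x = x2 + 10), g)
  expect_equal(fm2$table["x", "estimate"], fm$table["x1", "estimate"],
               tolerance = 1e-3)
})

test_that("simple linear regression reports adjusted R-squared", {
  # perfect line (summary.lm warns about the perfect fit; that is the point)
  x <- 1:10
  f <- suppressWarnings(fit_ols(2 * x + 3, x))
  expect_equal(f$slope, 2)
  expect_equal(f$adj_r2, 1)
  # constant response: nothing explained, penalty applies
  f0 <- fit_ols(rep(2, 10), x)
  expect_equal(f0$slope, 0)
  expect_lte(f0$adj_r2, 0)
  # 10-point toy against the normal equations
  set.seed(5)
  y <- rnorm(10)
  z <- rnorm(10)
  f1 <- fit_ols(y, z)
  b <- cov(y, z) / var(z)
  r2 <- 1 - sum((y - mean(y) - b * (z - mean(z)))^2) / sum((y - mean(y))^2)
  expect_equal(f1$slope, b)
  expect_equal(f1$adj_r2, 1 - (1 - r2) * 9 / 8)
  expect_error(fit_ols(y, rep(1, 10)), "zero variance")
  expect_error(fit_ols(y[1:2], z[1:2]), "at least 3")
})
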