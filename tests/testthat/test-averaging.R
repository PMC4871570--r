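test_that("model enumeration covers every subset exactly once", {
  expect_length(enumerate_models(paste0("v", 1:12)), 4096)
  expect_length(enumerate_models(character(0)), 1)
  s3 <- enumerate_models(c("a", "b", "c"))
  expect_length(s3, 8)
  expect_false(anyDuplicated(vapply(s3, paste, "", collapse = ",")) > 0)
  # each predictor present in exactly half the subsets
  for (j in 1:3)
    expect_equal(sum(vapply(s3, function(s) j %in% s, logical(1))), 4)
  expect_error(enumerate_models(paste0("v", 1:21)), "20")
  expect_error(enumerate_models(c("a", "a")), "unique")
})

test_that("Akaike weights follow the exponential Delta rule", {
  expect_equal(akaike_weights(rep(100, 5)), rep(1 / 5, 5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  set.seed(1)
  a <- runif(50, 100, 150)
  expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
  expect_error(akaike_weights(c(Inf, NA)), "finite")
  expect_warning(w2 <- akaike_weights(c(100, NA, 101)), "dropped")
  expect_equal(w2[2], 0)
  expect_equal(sum(w2), 1)
})

test_that("summed weights aggregate models containing each predictor", {
  specs <- enumerate_models(c("a", "b", "c"))
  # all models tie: every predictor appears in half the mass
  sw <- summed_weights(rep(1 / 8, 8), specs)
  expect_equal(unname(sw), rep(0.5, 3))
  # p = 1: the summed weight is the weight of the single containing model
  s1 <- enumerate_models("a")
  w1 <- akaike_weights(c(10, 12))
  expect_equal(unname(summed_weights(w1, s1))[1], w1[2])
  # p = 3 toy with fixed AICc values against brute-force enumeration
  aicc3 <- c(10, 12, 11, 9, 14, 13, 8, 15)
  w3 <- akaike_weights(aicc3)
  sw3 <- summed_weights(w3, specs)
  for (j in 1:3) {
    contains <- vapply(specs, function(s) j %in% s, logical(1))
    expect_equal(unname(sw3[j]), sum(w3[contains]))
  }
  # accounting identity: sum_j SW_j = sum_m w_m * |subset_m|
  expect_equal(sum(sw3),
               sum(w3 * lengths(specs)), tolerance = 1e-10)
})

test_that("multivariate AICc decomposes into independent univariate fits", {
  set.seed(2)
  n <- 40
  env <- data.frame(a = rnorm(n), b = rnorm(n))
  Y <- cbind(sp1 = rnbinom(n, mu = 4, size = 1),
             sp2 = rnbinom(n, mu = exp(1 + 0.5 * env$a), size = 2))
  multi <- fit_all_models(Y, env, "multivariate")
  u1 <- fit_all_models(Y[, 1], env, "univariate")
  u2 <- fit_all_models(Y[, 2], env, "univariate")
  expect_equal(as.numeric(multi), as.numeric(u1) + as.numeric(u2),
               tolerance = 1e-6)
  # the intercept-only model anchors every run
  expect_length(multi, 4)
  # rank-deficient predictor tables surface as an error
  expect_error(fit_all_models(Y[, 1], data.frame(a = env$a, b = env$a),
                              "univariate"),
               "rank deficient")
})

test_that("models with undefined AICc are excluded, not imputed", {
  set.seed(3)
  n <- 6  # with p = 3, the largest subsets have n <= k + 1
  env <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rnbinom(n, mu = 4, size = 5)
  aicc <- fit_all_models(y, env, "univariate")
  expect_true(any(is.na(aicc)))
  expect_warning(w <- akaike_weights(aicc), "dropped")
  expect_equal(sum(w), 1)
  expect_true(all(w[is.na(aicc)] == 0))
})

test_that("null distributions are valid permutations and seed-deterministic", {
  set.seed(4)
  n <- 30
  env <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rnbinom(n, mu = 5, size = 1)
  n1 <- null_distribution(y, env, "univariate", n_null = 5, seed = 11)
  n2 <- null_distribution(y, env, "univariate", n_null = 5, seed = 11)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(5L, 3L))
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_error(null_distribution(y, env, "univariate", n_null = 0), "n_null")
  # permuting rows leaves column sums of a community matrix unchanged
  Y <- cbind(rnbinom(n, mu = 3, size = 1), rnbinom(n, mu = 2, size = 1))
  perm <- sample(n)
  expect_equal(colSums(Y[perm, ]), colSums(Y))
})

test_that("the averaging table computes SES and permutation P correctly", {
  # the observed/null-mean/null-SD composition printed for each predictor
  obs <- c(x = 0.85)
  nullm <- matrix(rnorm(999, 0.36, 0.12), ncol = 1,
                  dimnames = list(NULL, "x"))
  tab <- averaging_table(obs, nullm)
  expect_equal(tab$SES, (0.85 - mean(nullm)) / sd(nullm))
  expect_equal(round((0.85 - 0.36) / 0.12, 2), 4.08)  # rounded-inputs check
  # a = b gives SES = 0
  nm2 <- matrix(c(0.3, 0.5, 0.4), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(averaging_table(c(x = 0.4), nm2)$SES, 0)
  # observed above all null values: P at the +1-corrected floor
  nm3 <- matrix(runif(999, 0, 0.5), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(averaging_table(c(x = 0.99), nm3)$P, 1 / 1000)
  # zero null SD is reported as undefined
  nm4 <- matrix(0.4, 10, 1, dimnames = list(NULL, "x"))
  expect_warning(t4 <- averaging_table(c(x = 0.5), nm4), "SES undefined")
  expect_true(is.na(t4$SES))
})

test_that("the full estimator is reproducible and sorted by SES", {
  set.seed(6)
  n <- 40
  env <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rnbinom(n, mu = exp(log(4) + env$a), size = 2)
  r1 <- importance_permtest(y, env, "univariate", n_null = 49, seed = 3)
  r2 <- importance_permtest(y, env, "univariate", n_null = 49, seed = 3)
  expect_identical(r1$table, r2$table)
  expect_false(is.unsorted(rev(r1$table$SES)))
  expect_equal(r1$table$variable[1], "a")  # the true driver ranks first
  expect_true(all(r1$table$summed_weight_obs >= 0 &
                  r1$table$summed_weight_obs <= 1))
})
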