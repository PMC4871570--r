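test_that("Bray-Curtis with dummy species handles depauperate plots", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(0, 0), d = c(0, 0))
  bm <- as.matrix(bray_curtis(m, transform = "none"))
  expect_equal(bm["a", "b"], 2 / (2 + 2e-7))
  expect_equal(bm["c", "d"], 0)          # empty vs empty is defined
  expect_true(all(diag(bm) == 0))
  expect_equal(bm, t(bm))
  expect_true(all(is.finite(bm)) && all(bm >= 0) && all(bm <= 1))
  expect_error(bray_curtis(rbind(c(-1, 2), c(0, 1))), "non-negative")
})

test_that("dummy convention reduces to plain Bray-Curtis for occupied plots", {
  set.seed(5)
  comm <- matrix(rpois(60, 4) + 1, 10)   # no empty plots
  with_dummy <- as.matrix(bray_curtis(comm, transform = "none"))
  plain <- as.matrix(vegan::vegdist(comm, method = "bray"))
  expect_lt(max(abs(with_dummy - plain)), 1e-6)
  # square-root transform is applied before the dissimilarity
  bc_sqrt <- as.matrix(bray_curtis(comm, transform = "sqrt"))
  ref <- as.matrix(vegan::vegdist(sqrt(comm), method = "bray"))
  expect_lt(max(abs(bc_sqrt - ref)), 1e-6)
})

test_that("NMDS recovers exactly representable configurations", {
  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2)
  o <- nmds(dist(pts), k = 2, restarts = 5, seed = 1)
  expect_lt(o$stress, 1e-3)
  expect_true(o$converged)
  # coordinates centred at the origin
  expect_lt(max(abs(colMeans(o$points))), 1e-8)
})

test_that("NMDS stress agrees with an independent implementation", {
  set.seed(3)
  d6 <- dist(matrix(rnorm(18), 6, 3))
  o6 <- nmds(d6, k = 2, restarts = 10, seed = 1)
  ref <- MASS::isoMDS(as.matrix(d6), k = 2, trace = FALSE)
  expect_lt(abs(o6$stress - ref$stress / 100), 0.01)
})

test_that("stress depends only on inter-point distances", {
  set.seed(4)
  d <- dist(matrix(rnorm(24), 8, 3))
  o <- nmds(d, k = 2, restarts = 10, seed = 1)
  s0 <- stress1(o$points, d)
  expect_lt(abs(s0 - o$stress), 1e-4)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rotated <- o$points %*% R
  reflected <- o$points %*% diag(c(-1, 1))
  shifted <- sweep(o$points, 2, c(3, -5), "+")
  expect_equal(stress1(rotated, d), s0)
  expect_equal(stress1(reflected, d), s0)
  expect_equal(stress1(shifted, d), s0)
})

test_that("NMDS is deterministic under a seed and excludes empty plots", {
  sv <- tiny_survey(seed = 6)
  sv$comm[3, ] <- 0L
  o1 <- ordinate_community(sv$comm, restarts = 5, seed = 9)
  o2 <- ordinate_community(sv$comm, restarts = 5, seed = 9)
  expect_identical(o1$points, o2$points)
  expect_setequal(o1$excluded,
                  sv$plots$plot_id[rowSums(sv$comm) == 0])
  expect_true(sv$plots$plot_id[3] %in% o1$excluded)
  expect_false(sv$plots$plot_id[3] %in% rownames(o1$points))
})

test_that("environmental vectors reproduce least-squares geometry", {
  set.seed(8)
  pts <- scale(matrix(rnorm(40), 20, 2), scale = FALSE)
  # variable equal to axis 1: r2 = 1, direction (1, 0)
  ev <- fit_env_vectors(pts, data.frame(v = pts[, 1]), n_perm = 99, seed = 1)
  expect_equal(ev$r2, 1)
  expect_equal(abs(ev$cos1), 1, tolerance = 1e-8)
  expect_lt(abs(ev$cos2), 1e-6)
  # r2 equals the coefficient of determination of a two-predictor fit
  z <- rnorm(20)
  ev2 <- fit_env_vectors(pts, data.frame(z = z), n_perm = 99, seed = 1)
  expect_equal(ev2$r2, summary(lm(z ~ pts[, 1] + pts[, 2]))$r.squared,
               tolerance = 1e-6)
  # constant variable: flagged, r2 = 0
  expect_warning(
    ev3 <- fit_env_vectors(pts, data.frame(z = z, cst = 1),
                           n_perm = 99, seed = 1),
    "constant")
  expect_equal(ev3$r2[ev3$variable == "cst"], 0)
})

test_that("vector-fit permutation P is approximately uniform under the null", {
  set.seed(10)
  pts <- scale(matrix(rnorm(60), 30, 2), scale = FALSE)
  P <- vapply(1:200, function(i) {
    fit_env_vectors(pts, data.frame(z = rnorm(30)), n_perm = 59,
                    seed = 1000 + i)$P
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(P, "punif"))$p.value, 0.01)
})
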