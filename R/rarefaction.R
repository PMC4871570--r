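# Individual- and coverage-based rarefaction with extrapolation.
# Interpolation is classical hypergeometric rarefaction; extrapolation uses
# the Chao1 estimate of undetected richness; sample coverage is estimated
# from singleton and doubleton counts. Binomial-coefficient ratios are
# evaluated in log space (overflow guard for n in the thousands).

abund_summary <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0) || any(x != round(x)))
    stop("abundances must be non-negative integers")
  x <- x[x > 0]
  list(x = x, n = sum(x), S_obs = length(x),
       f1 = sum(x == 1), f2 = sum(x == 2))
}

# Chao1 estimate of the number of undetected species, with the
# bias-corrected form when no doubletons are present.
chao_f0 <- function(n, f1, f2) {
  if (f1 == 0) return(0)
  if (f2 > 0) (n - 1) / n * f1^2 / (2 * f2)
  else        (n - 1) / n * f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Estimated sample coverage of an abundance vector
#'
#' Sample coverage is the proportion of individuals in the assemblage that
#' belong to species already represented in the sample, estimated from the
#' singleton and doubleton frequencies as
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,
#'   \frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}.}
#' A sample with no singletons has estimated coverage 1.
#'
#' @param x non-negative integer species abundances.
#' @return estimated coverage in \[0, 1\].
#' @examples
#' coverage_estimate(c(4, 3, 2, 1, 1))
#' @export
coverage_estimate <- function(x) {
  a <- abund_summary(x)
  if (a$n < 1) stop("coverage undefined for an empty sample (n = 0)")
  if (a$f1 == 0) return(1)
  1 - (a$f1 / a$n) * ((a$n - 1) * a$f1 / ((a$n - 1) * a$f1 + 2 * a$f2))
}

#' Rarefied (interpolated) species richness
#'
#' Expected number of species in a random subsample of `m` individuals drawn
#' without replacement, \eqn{S(m) = \sum_i [1 - C(n - X_i, m)/C(n, m)]}.
#'
#' @param x non-negative integer species abundances.
#' @param m subsample size, `0 <= m <= n`. Values beyond `n` are an error:
#'   use [extrapolate_richness()].
#' @return expected richness at `m` individuals.
#' @export
interpolate_richness <- function(x, m) {
  a <- abund_summary(x)
  if (m < 0 || m != round(m)) stop("'m' must be a non-negative integer")
  if (m > a$n)
    stop("'m' exceeds the sample size: use extrapolate_richness()")
  if (m == 0) return(0)
  # log-space ratio; species with n - X_i < m are certainly present
  lr <- ifelse(a$n - a$x >= m,
               exp(lchoose(a$n - a$x, m) - lchoose(a$n, m)), 0)
  sum(1 - lr)
}

#' Extrapolated species richness
#'
#' Estimated richness at `n + m_extra` individuals,
#' \eqn{S(n + m^*) = S_{obs} + \hat f_0 [1 - (1 - f_1/(n \hat f_0 + f_1))^{m^*}]},
#' where \eqn{\hat f_0} is the Chao1 estimate of undetected richness
#' (bias-corrected when \eqn{f_2 = 0}). The estimate approaches the Chao1
#' asymptote \eqn{S_{obs} + \hat f_0} for large `m_extra`.
#'
#' @param x non-negative integer species abundances.
#' @param m_extra number of additional individuals beyond the sample.
#' @return estimated richness, `>= S_obs`.
#' @export
extrapolate_richness <- function(x, m_extra) {
  a <- abund_summary(x)
  if (m_extra < 0) stop("'m_extra' must be non-negative")
  if (m_extra == 0) return(a$S_obs)
  f0 <- chao_f0(a$n, a$f1, a$f2)
  if (f0 == 0) return(a$S_obs)
  a$S_obs + f0 * (1 - (1 - a$f1 / (a$n * f0 + a$f1))^m_extra)
}

# estimated coverage of a subsample of size m < n
coverage_interpolated <- function(a, m) {
  lr <- ifelse(a$n - a$x >= m,
               exp(lchoose(a$n - a$x, m) - lchoose(a$n - 1, m)), 0)
  1 - sum((a$x / a$n) * lr)
}

# analytic extension of the coverage estimator to m = n + m_extra
coverage_extrapolated <- function(a, m_extra) {
  if (a$f1 == 0) return(1)
  A <- (a$n - 1) * a$f1 / ((a$n - 1) * a$f1 + 2 * a$f2)
  1 - (a$f1 / a$n) * A^(m_extra + 1)
}

#' Rarefaction and extrapolation curve
#'
#' Builds the individual- or coverage-based rarefaction curve of an
#' abundance vector over a grid of sample sizes from 1 to `factor * n`,
#' with interpolation up to the observed sample size and Chao1-based
#' extrapolation beyond it (by a factor of two by default). Both expected
#' richness `S` and estimated coverage `C` are reported at every point;
#' the mode determines which is plotted on the x axis.
#'
#' @param x non-negative integer species abundances.
#' @param mode `"individual"` (S against m) or `"coverage"` (S against C).
#' @param factor extrapolation factor (`>= 1`); the curve ends at
#'   `m = factor * n`.
#' @param knots approximate number of grid points.
#' @return a data frame of class `"rarefaction_curve"` with columns
#'   `m`, `S`, `C`, `phase` (interpolated / observed / extrapolated).
#' @examples
#' rc <- rarefaction_curve(c(20, 10, 5, 2, 1, 1))
#' head(rc)
#' @export
rarefaction_curve <- function(x, mode = c("individual", "coverage"),
                              factor = 2, knots = 40) {
  mode <- match.arg(mode)
  if (factor < 1) stop("'factor' must be >= 1")
  a <- abund_summary(x)
  if (a$n < 1) stop("empty sample: rarefaction undefined")
  m_max <- max(round(factor * a$n), a$n)
  grid <- sort(unique(c(1, round(seq(1, m_max, length.out = knots)), a$n)))
  S <- C <- numeric(length(grid))
  phase <- character(length(grid))
  for (i in seq_along(grid)) {
    m <- grid[i]
    if (m < a$n) {
      S[i] <- interpolate_richness(x, m)
      C[i] <- coverage_interpolated(a, m)
      phase[i] <- "interpolated"
    } else if (m == a$n) {
      S[i] <- a$S_obs
      C[i] <- coverage_estimate(x)
      phase[i] <- "observed"
    } else {
      S[i] <- extrapolate_richness(x, m - a$n)
      C[i] <- coverage_extrapolated(a, m - a$n)
      phase[i] <- "extrapolated"
    }
  }
  structure(data.frame(m = grid, S = S, C = C, phase = phase),
            class = c("rarefaction_curve", "data.frame"),
            mode = mode, n = a$n, S_obs = a$S_obs)
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("%s-based rarefaction/extrapolation curve: n = %d, S_obs = %d\n",
              attr(x, "mode"), attr(x, "n"), attr(x, "S_obs")))
  cat(sprintf("coverage at n: %.4f; curve to m = %d\n",
              x$C[x$phase == "observed"][1], max(x$m)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @export
plot.rarefaction_curve <- function(x, ...) {
  if (attr(x, "mode") == "coverage") {
    graphics::plot(x$C, x$S, type = "n", xlab = "Sample coverage",
                   ylab = "Species richness", ...)
    xs <- x$C
  } else {
    graphics::plot(x$m, x$S, type = "n", xlab = "Individuals",
                   ylab = "Species richness", ...)
    xs <- x$m
  }
  int <- x$phase != "extrapolated"
  graphics::lines(xs[int], x$S[int], lty = 1)
  graphics::lines(xs[!int], x$S[!int], lty = 2)
  obs <- x$phase == "observed"
  graphics::points(xs[obs], x$S[obs], pch = 19)
  invisible(x)
}

#' Pool a community matrix into per-subregion abundance vectors
#'
#' Sums plot-level counts within each subregion, yielding one species
#' abundance vector per subregion (the pooling used for the per-subregion
#' sampling-sufficiency assessment).
#'
#' @param comm plots x species count matrix with plot ids as row names.
#' @param plots plot table with `plot_id` and `subregion` columns.
#' @return named list of species abundance vectors.
#' @export
subregion_abundances <- function(comm, plots) {
  comm <- as.matrix(comm)
  stopifnot(nrow(comm) == nrow(plots))
  lapply(split(seq_len(nrow(comm)), plots$subregion),
         function(i) colSums(comm[i, , drop = FALSE]))
}
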