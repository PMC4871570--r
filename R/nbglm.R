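#' Negative-binomial GLM with log link
#'
#' Fits a negative-binomial (NB2) generalised linear model with log link by
#' iteratively reweighted least squares alternating with maximum-likelihood
#' Newton updates of the size parameter theta. The dispersion parameter is
#' capped so that equidispersed responses converge to the Poisson limit.
#'
#' @param y vector of non-negative integer counts.
#' @param X design matrix (include an intercept column; defaults to
#'   intercept-only). Must have full column rank.
#' @param theta_cap upper bound for theta; reaching it signals the Poisson
#'   limit.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum outer (beta/theta alternation) iterations.
#' @return an object of class `"nbglm"`: coefficients, standard errors,
#'   `theta`, `loglik`, `k` (parameter count including theta), `n`, `aicc`,
#'   and flags `converged` and `boundary` (all-zero response).
#' @seealso [aicc()], [fit_nb_glmm()]
#' @examples
#' set.seed(1)
#' x <- rnorm(50)
#' y <- rnbinom(50, mu = exp(1 + 0.5 * x), size = 2)
#' fit <- fit_nb_glm(y, cbind(1, x))
#' coef(fit)
#' @export
fit_nb_glm <- function(y, X = matrix(1, length(y), 1),
                       theta_cap = 1e8, tol = 1e-8, maxit = 200L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("'y' must be non-negative integer counts")
  if (nrow(X) != length(y)) stop("rows of 'X' must align with 'y'")
  if (qr(X)$rank < ncol(X)) stop("'X' is rank deficient")
  fit <- C_nb_fit(y, X, theta_cap, tol, maxit)
  if (fit$boundary)
    warning("all-zero response: intercept estimated at the lower boundary")
  else if (!fit$converged)
    warning("negative-binomial GLM did not converge")
  cf <- drop(fit$coefficients)
  names(cf) <- colnames(X) %||% paste0("b", seq_along(cf) - 1L)
  se <- sqrt(diag(as.matrix(fit$vcov)))
  k <- ncol(X) + 1L  # slopes + intercept + theta
  n <- length(y)
  structure(list(
    coefficients = cf, se = se, vcov = fit$vcov,
    theta = fit$theta, loglik = fit$loglik, fitted = drop(fit$fitted),
    k = k, n = n,
    aicc = if (n > k + 1) aicc(fit$loglik, k, n) else NA_real_,
    converged = fit$converged, boundary = fit$boundary
  ), class = "nbglm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nbglm <- function(x, ...) {
  cat("Negative-binomial GLM (log link)\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  cat(sprintf("theta = %s   logLik = %.4f   AICc = %.4f   n = %d\n",
              format(x$theta, digits = 4), x$loglik, x$aicc, x$n))
  if (x$boundary) cat("(boundary fit: all-zero response)\n")
  invisible(x)
}

#' @export
coef.nbglm <- function(object, ...) object$coefficients

#' @export
logLik.nbglm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.nbglm <- function(object, ...) object$vcov

#' @export
fitted.nbglm <- function(object, ...) object$fitted

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 log L + 2k + 2k(k + 1) / (n - k - 1). The correction is
#' undefined for n <= k + 1, which signals an over-parameterised model.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (including any dispersion).
#' @param n sample size.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1)
    stop("AICc undefined for n <= k + 1 (over-parameterised model)")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Negative-binomial mixed model with a random intercept
#'
#' Random-intercept negative-binomial GLMM estimated by Laplace-approximated
#' maximum likelihood (via \pkg{lme4}), as used for testing elevational
#' trends in richness and abundance while controlling for subregional
#' differences.
#'
#' @param y non-negative integer response.
#' @param x fixed-effect predictor matrix or vector (no intercept column;
#'   an intercept is added).
#' @param group grouping factor for the random intercept (e.g. subregion).
#' @return an object of class `"nbglmm"` with a fixed-effect `table`
#'   (estimate, SE, t value, P), `ranef_var`, `theta`, `loglik`, `n` and a
#'   `converged` flag. With fewer than two groups the model falls back to
#'   [fit_nb_glm()] with a warning.
#' @examples
#' \donttest{
#' cfg <- sim_config(seed = 1)
#' plots <- sim_design(cfg)
#' comm <- sim_community(plots, sim_environment(plots, cfg), cfg)
#' elev <- (plots$actual_elev - mean(plots$actual_elev)) / 1000
#' fit_nb_glmm(rowSums(comm), elev, plots$subregion)
#' }
#' @export
fit_nb_glmm <- function(y, x, group) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  group <- factor(group)
  if (length(y) != nrow(x) || length(y) != length(group))
    stop("'y', 'x' and 'group' must be aligned")
  if (any(y < 0) || any(y != round(y)))
    stop("'y' must be non-negative integer counts")
  if (nlevels(group) < 2) {
    warning("fewer than 2 groups: falling back to fixed-effects NB GLM")
    fit <- fit_nb_glm(y, cbind(`(Intercept)` = 1, x))
    est <- coef(fit)
    tab <- data.frame(estimate = est, se = fit$se,
                      t = est / fit$se, p = 2 * pnorm(-abs(est / fit$se)))
    return(structure(list(table = tab, ranef_var = 0, theta = fit$theta,
                          loglik = fit$loglik, n = fit$n,
                          converged = fit$converged, fallback = TRUE),
                     class = "nbglmm"))
  }
  if (all(y == 0)) warning("all-zero response: degenerate mixed model")
  dat <- data.frame(.y = y, x, .g = group, check.names = FALSE)
  fml <- stats::reformulate(c(colnames(x), "(1 | .g)"), response = ".y")
  quiet_fit <- function(expr) suppressMessages(withCallingHandlers(
    tryCatch(expr, error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning")))
  # occasional PIRLS failures on awkward samples: retry with a different
  # optimizer, then with glmmTMB (also Laplace) if available
  m <- quiet_fit(lme4::glmer.nb(fml, data = dat))
  if (is.null(m))
    m <- quiet_fit(lme4::glmer.nb(
      fml, data = dat,
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   tolPwrss = 1e-6)))
  if (!is.null(m)) {
    sm <- summary(m)$coefficients
    tab <- data.frame(estimate = sm[, 1], se = sm[, 2],
                      t = sm[, 3], p = sm[, 4])
    vc <- lme4::VarCorr(m)
    return(structure(list(table = tab,
                          ranef_var = as.numeric(vc[[".g"]][1, 1]),
                          theta = lme4::getME(m, "glmer.nb.theta"),
                          loglik = as.numeric(logLik(m)), n = length(y),
                          converged = length(m@optinfo$conv$lme4) == 0,
                          fallback = FALSE),
                     class = "nbglmm"))
  }
  if (requireNamespace("glmmTMB", quietly = TRUE)) {
    fml2 <- stats::reformulate(c(colnames(x), "(1 | .g)"), response = ".y")
    m2 <- quiet_fit(glmmTMB::glmmTMB(fml2, data = dat,
                                     family = glmmTMB::nbinom2))
    if (!is.null(m2)) {
      sm <- summary(m2)$coefficients$cond
      tab <- data.frame(estimate = sm[, 1], se = sm[, 2],
                        t = sm[, 3], p = sm[, 4])
      return(structure(list(table = tab,
                            ranef_var =
                              as.numeric(glmmTMB::VarCorr(m2)$cond$.g[1, 1]),
                            theta = stats::sigma(m2),
                            loglik = as.numeric(logLik(m2)), n = length(y),
                            converged = isTRUE(m2$fit$convergence == 0),
                            fallback = FALSE),
                       class = "nbglmm"))
    }
  }
  stop("NB GLMM failed to fit")
}

#' @export
print.nbglmm <- function(x, ...) {
  cat("Negative-binomial mixed model (Laplace, random intercept)\n")
  print(round(x$table, 4))
  cat(sprintf("random-intercept variance = %.4f   theta = %.3f   n = %d\n",
              x$ranef_var, x$theta, x$n))
  if (!x$converged) cat("(convergence not attained)\n")
  invisible(x)
}

#' Simple linear regression with adjusted R-squared
#'
#' Ordinary least squares of `y` on a single predictor, reporting the slope,
#' adjusted R-squared 1 - (1 - R^2)(n - 1)/(n - 2) and the slope P value.
#' Used for the univariate richness-predictor relationships.
#'
#' @param y numeric response.
#' @param x numeric predictor with non-zero variance.
#' @return list with `slope`, `intercept`, `adj_r2`, `p`.
#' @export
fit_ols <- function(y, x) {
  if (length(y) < 3) stop("need at least 3 observations")
  if (length(x) != length(y)) stop("'x' and 'y' must be aligned")
  if (var(x) == 0) stop("'x' has zero variance")
  n <- length(y)
  if (var(y) == 0)   # nothing to explain: R^2 = 0, penalty applies
    return(list(slope = 0, intercept = y[1],
                adj_r2 = 1 - (n - 1) / (n - 2), p = 1))
  m <- lm(y ~ x)
  sm <- summary(m)
  list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       adj_r2 = sm$adj.r.squared,
       p = unname(sm$coefficients[2, 4]))
}
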