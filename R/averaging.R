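# Exhaustive AICc model averaging with a permutation null: all 2^p
# predictor subsets are fitted as negative-binomial GLMs (univariate
# richness mode) or as sums of per-species negative-binomial GLMs
# (multivariate composition mode); predictor importance is the summed
# Akaike weight of every model containing the predictor, calibrated against
# null datasets obtained by permuting response rows against the fixed
# predictor table.

#' Enumerate all predictor subsets
#'
#' All 2^p subsets of an ordered predictor list (including the intercept-only
#' empty subset) in deterministic bitmask order.
#'
#' @param predictors character vector of unique predictor names.
#' @return list of class `"model_specs"`: integer index vectors into
#'   `predictors` (empty vector = intercept-only model).
#' @examples
#' length(enumerate_models(letters[1:3]))  # 8
#' @export
enumerate_models <- function(predictors) {
  p <- length(predictors)
  if (anyDuplicated(predictors)) stop("predictor names must be unique")
  if (p > 20)
    stop("refusing to enumerate 2^", p, " models; ",
         "screen the predictor set down to at most 20 first")
  specs <- lapply(0:(2^p - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0))
  structure(specs, predictors = predictors, class = "model_specs")
}

#' Fit every predictor subset and return its AICc
#'
#' For each subset, a negative-binomial GLM (log link, theta estimated per
#' model) is fitted; in multivariate mode each species column is fitted
#' separately on the shared subset and the AICc values are summed (with
#' per-species parameter count and shared n). The AICc parameter count
#' includes the intercept, the slopes and theta. Models for which the AICc
#' correction is undefined (n <= k + 1) are returned as `NA` and excluded
#' from the weight normalisation with a warning downstream.
#'
#' @param response numeric vector (univariate mode) or plots x species count
#'   matrix (multivariate mode).
#' @param env data frame of numeric predictors (z-scored internally).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param specs optional [enumerate_models()] result (defaults to all
#'   subsets of `names(env)`).
#' @return numeric vector of AICc values, one per model spec, with the
#'   specs attached as an attribute.
#' @export
fit_all_models <- function(response, env,
                           mode = c("univariate", "multivariate"),
                           specs = NULL) {
  mode <- match.arg(mode)
  env <- as.data.frame(env)
  X <- scale(as.matrix(env))
  if (any(!is.finite(X)))
    stop("predictors must be numeric with non-zero variance")
  if (qr(X)$rank < ncol(X))
    stop("predictor table is rank deficient (duplicated or aliased columns)")
  Y <- if (mode == "univariate") matrix(as.numeric(response)) else
    as.matrix(response)
  if (nrow(Y) != nrow(X)) stop("response rows must align with 'env'")
  if (any(Y < 0) || any(Y != round(Y)))
    stop("response must contain non-negative integer counts")
  if (mode == "multivariate") {
    keep <- colSums(Y) > 0
    if (!all(keep)) {
      warning(sum(!keep), " all-zero species column(s) dropped")
      Y <- Y[, keep, drop = FALSE]
    }
  }
  if (is.null(specs)) specs <- enumerate_models(colnames(env))
  specs0 <- lapply(specs, function(i) as.integer(i - 1L))
  aicc <- C_nb_aicc_subsets(Y, X, specs0)
  attr(aicc, "specs") <- specs
  aicc
}

#' Akaike weights of a model set
#'
#' w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2)), Delta_m = AICc_m -
#' min(AICc). Models with `NA` AICc (undefined small-sample correction) get
#' weight zero and are dropped from the normalisation.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return weights summing to 1 over the defined models.
#' @export
akaike_weights <- function(aicc_values) {
  ok <- is.finite(aicc_values)
  if (!any(ok)) stop("no model has a finite AICc")
  if (any(!ok))
    warning(sum(!ok), " model(s) with undefined AICc dropped from weighting")
  w <- numeric(length(aicc_values))
  d <- aicc_values[ok] - min(aicc_values[ok])
  w[ok] <- exp(-d / 2) / sum(exp(-d / 2))
  w
}

#' Per-predictor summed Akaike weights
#'
#' SW_j = sum of the weights of every model whose subset contains predictor
#' j: the model-averaged importance of the predictor.
#'
#' @param weights Akaike weights, aligned with `specs`.
#' @param specs a [enumerate_models()] result.
#' @return named numeric vector of summed weights, one per predictor.
#' @export
summed_weights <- function(weights, specs) {
  predictors <- attr(specs, "predictors")
  if (length(weights) != length(specs))
    stop("'weights' and 'specs' must be aligned")
  sw <- vapply(seq_along(predictors), function(j)
    sum(weights[vapply(specs, function(s) j %in% s, logical(1))]),
    numeric(1))
  setNames(sw, predictors)
}

#' Null distribution of summed Akaike weights
#'
#' Generates null datasets by permuting the response rows (richness values,
#' or whole community-matrix rows, preserving species co-occurrence) against
#' the fixed predictor table, and recomputes all summed Akaike weights for
#' each.
#'
#' @inheritParams fit_all_models
#' @param n_null number of null datasets.
#' @param seed integer seed.
#' @return `n_null` x p matrix of null summed weights.
#' @export
null_distribution <- function(response, env,
                              mode = c("univariate", "multivariate"),
                              n_null = 999, seed = NULL, specs = NULL) {
  mode <- match.arg(mode)
  if (n_null < 1) stop("'n_null' must be >= 1")
  env <- as.data.frame(env)
  if (is.null(specs)) specs <- enumerate_models(names(env))
  Y <- if (mode == "univariate") matrix(as.numeric(response)) else
    as.matrix(response)
  n <- nrow(Y)
  with_seed(seed, {
    out <- matrix(NA_real_, n_null, length(attr(specs, "predictors")),
                  dimnames = list(NULL, attr(specs, "predictors")))
    for (b in seq_len(n_null)) {
      perm <- sample.int(n)
      aicc <- suppressWarnings(
        fit_all_models(Y[perm, , drop = FALSE], env, mode, specs))
      out[b, ] <- summed_weights(akaike_weights(aicc), specs)
    }
    out
  })
}

#' Standardised effect sizes and permutation P values of summed weights
#'
#' Combines observed summed Akaike weights (a) with the permutation-null
#' mean (b) and SD (c) into SES = (a - b)/c and an upper-tail permutation P
#' value with the +1 correction, P = (1 + #\{null >= observed\}) /
#' (n_null + 1). Rows are sorted by SES, descending.
#'
#' @param observed_sw named vector of observed summed weights.
#' @param null_matrix matrix from [null_distribution()], columns aligned
#'   with `observed_sw`.
#' @return data frame with columns `variable`, `summed_weight_obs`,
#'   `null_mean`, `null_sd`, `SES`, `P`.
#' @export
averaging_table <- function(observed_sw, null_matrix) {
  if (!identical(names(observed_sw), colnames(null_matrix)))
    stop("null matrix columns must align with the observed summed weights")
  b <- colMeans(null_matrix)
  cc <- apply(null_matrix, 2, sd)
  ses <- ifelse(cc > 0, (observed_sw - b) / cc, NA_real_)
  if (any(cc == 0))
    warning("zero null SD for: ",
            paste(names(observed_sw)[cc == 0], collapse = ", "),
            " (SES undefined)")
  n_null <- nrow(null_matrix)
  P <- vapply(seq_along(observed_sw), function(j)
    (1 + sum(null_matrix[, j] >= observed_sw[j])) / (n_null + 1), numeric(1))
  out <- data.frame(variable = names(observed_sw),
                    summed_weight_obs = unname(observed_sw),
                    null_mean = unname(b), null_sd = unname(cc),
                    SES = unname(ses), P = P)
  out[order(-out$SES), , drop = FALSE]
}

#' Rank predictors by summed Akaike weight against a permutation null
#'
#' The package's central estimator. Fits all 2^p negative-binomial models of
#' the response on subsets of the (screened) predictors, computes each
#' predictor's summed Akaike weight, and calibrates it against `n_null`
#' datasets obtained by permuting response rows against the fixed predictor
#' table, yielding a standardised effect size and an upper-tail permutation
#' P value per predictor.
#'
#' @inheritParams fit_all_models
#' @inheritParams null_distribution
#' @param min_prevalence in multivariate mode, drop species occurring in
#'   fewer than this many plots before fitting (default 0 = keep all
#'   non-empty species).
#' @return object of class `"importance_permtest"`: `table` (per-predictor
#'   a, b, c, SES, P, sorted by SES), `summed_weights`, `weights`, `aicc`,
#'   `null`, `mode`, `n_null`, `seed`.
#' @examples
#' \donttest{
#' cfg <- sim_config(seed = 2)
#' plots <- sim_design(cfg)
#' env <- sim_environment(plots, cfg)[, c("Ave.T", "Ann.P", "Hist.veg")]
#' comm <- sim_community(plots, env, cfg)
#' importance_permtest(rowSums(comm > 0), env, "univariate",
#'                     n_null = 99, seed = 1)
#' }
#' @export
importance_permtest <- function(response, env,
                                mode = c("univariate", "multivariate"),
                                n_null = 999, seed = NULL,
                                min_prevalence = 0) {
  mode <- match.arg(mode)
  env <- as.data.frame(env)
  if (mode == "multivariate" && min_prevalence > 0) {
    response <- as.matrix(response)
    response <- response[, colSums(response > 0) >= min_prevalence,
                         drop = FALSE]
  }
  specs <- enumerate_models(names(env))
  aicc <- fit_all_models(response, env, mode, specs)
  w <- akaike_weights(aicc)
  sw <- summed_weights(w, specs)
  nul <- null_distribution(response, env, mode, n_null = n_null,
                           seed = seed, specs = specs)
  structure(list(table = averaging_table(sw, nul),
                 summed_weights = sw, weights = w, aicc = as.numeric(aicc),
                 null = nul, specs = specs, mode = mode,
                 n_null = n_null, seed = seed),
            class = "importance_permtest")
}

#' @export
print.importance_permtest <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Summed-Akaike-weight importance (%s mode, %d models, %d null permutations)\n",
    x$mode, length(x$aicc), x$n_null))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.importance_permtest <- function(object, alpha = 0.05, ...) {
  sig <- object$table$variable[object$table$P <= alpha]
  cat(sprintf("%d of %d predictors with permutation P <= %.3g:\n",
              length(sig), nrow(object$table), alpha))
  cat(" ", paste(sig, collapse = ", "), "\n")
  invisible(object$table)
}

#' @export
plot.importance_permtest <- function(x, ...) {
  tab <- x$table[nrow(x$table):1, ]
  graphics::dotchart(tab$summed_weight_obs, labels = tab$variable,
                     xlab = "Summed Akaike weight", xlim = c(0, 1), ...)
  graphics::points(tab$null_mean, seq_len(nrow(tab)), pch = 4)
  invisible(x)
}
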