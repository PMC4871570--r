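# Distance-based permutational multivariate ANOVA with Type I (sequential)
# sums of squares and P values from permutation of residuals under the
# reduced model (the model containing the terms entered before the one
# being tested).

#' Gower-centred inner-product matrix of a dissimilarity matrix
#'
#' G = -1/2 J D^2 J with J the centring projector. Rows and columns of G
#' sum to zero; for Euclidean distances on column-centred data X, G equals
#' X X'.
#'
#' @param d a `dist` or square symmetric dissimilarity matrix.
#' @return the centred inner-product (Gower) matrix.
#' @export
gower_centered <- function(d) {
  A <- as.matrix(d)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% A %*% J
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Distance-based PERMANOVA with sequential sums of squares
#'
#' Partitions the total sum of squared dissimilarities among ordered model
#' terms (Type I, sequential fit: each term adjusted only for the terms
#' entered before it), computes pseudo-F statistics against the full-model
#' residual, and obtains P values by permutation of residuals under the
#' reduced model (Freedman-Lane): for each term, the Gower-centred residual
#' of the model containing the preceding terms is row/column permuted and
#' the pseudo-F recomputed.
#'
#' Under a Euclidean distance on a single variable the pseudo-F statistics
#' equal the classical sequential ANOVA/ANCOVA F statistics exactly.
#'
#' @param d a `dist` or square symmetric dissimilarity matrix.
#' @param data data frame of term variables (rows aligned with `d`).
#' @param terms character vector naming columns of `data`, in entry order
#'   (e.g. subregion first, then the actual-elevation covariate).
#' @param n_perm number of permutations (P values use the +1 correction, so
#'   the smallest attainable P is 1/(n_perm + 1)).
#' @param seed integer seed for the permutations.
#' @return an object of class `"permanova"` whose `table` has one row per
#'   term plus residual and total rows (Df, SS, pseudo-F, P).
#' @examples
#' cfg <- sim_config(seed = 4)
#' plots <- sim_design(cfg)
#' comm <- sim_community(plots, sim_environment(plots, cfg), cfg)
#' d <- bray_curtis(comm)
#' permanova(d, plots, c("subregion", "actual_elev"), n_perm = 99, seed = 1)
#' @export
permanova <- function(d, data, terms, n_perm = 4999, seed = NULL) {
  G <- gower_centered(d)
  n <- nrow(G)
  if (nrow(data) != n) stop("'data' rows must align with 'd'")
  if (!all(terms %in% names(data)))
    stop("terms not in 'data': ",
         paste(setdiff(terms, names(data)), collapse = ", "))
  # sequential design matrices
  X <- matrix(1, n, 1)
  hats <- list(hat_matrix(X))
  df <- integer(length(terms))
  for (j in seq_along(terms)) {
    v <- data[[terms[j]]]
    Z <- if (is.numeric(v)) matrix(v, n, 1) else
      stats::model.matrix(~v)[, -1, drop = FALSE]
    X <- cbind(X, Z)
    r_prev <- sum(diag(hats[[j]]))
    hats[[j + 1]] <- hat_matrix(X)
    df[j] <- round(sum(diag(hats[[j + 1]])) - r_prev)
    if (df[j] < 1)
      stop("term '", terms[j], "' is aliased with preceding terms")
  }
  H_full <- hats[[length(hats)]]
  df_res <- n - round(sum(diag(H_full)))
  SS_total <- sum(diag(G))
  SS <- vapply(seq_along(terms), function(j)
    sum((hats[[j + 1]] - hats[[j]]) * G), numeric(1))
  SS_res <- sum((diag(n) - H_full) * G)
  Fobs <- (SS / df) / (SS_res / df_res)

  P <- rep(NA_real_, length(terms))
  if (n_perm > 0) with_seed(seed, {
    I_n <- diag(n)
    for (j in seq_along(terms)) {
      H_red <- hats[[j]]
      R <- (I_n - H_red) %*% G %*% (I_n - H_red)
      Hterm <- hats[[j + 1]] - H_red
      Hres <- I_n - H_full
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        p <- sample.int(n)
        Gp <- R[p, p]
        Fb <- (sum(Hterm * Gp) / df[j]) / (sum(Hres * Gp) / df_res)
        if (Fb >= Fobs[j]) exceed <- exceed + 1L
      }
      P[j] <- (1 + exceed) / (n_perm + 1)
    }
  })
  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df, df_res, n - 1),
    SS = c(SS, SS_res, SS_total),
    pseudoF = c(Fobs, NA, NA),
    P = c(P, NA, NA))
  structure(list(table = tab, n_perm = n_perm, n = n),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (sequential SS, %d permutations of residuals under reduced model)\n",
    x$n_perm))
  tab <- x$table
  tab$SS <- round(tab$SS, 4)
  tab$pseudoF <- round(tab$pseudoF, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
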