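# Bray-Curtis dissimilarity with the dummy-species convention, NMDS
# ordination (Kruskal stress-1 via vegan's monotone-regression engine) and
# environmental vector fitting.

#' Bray-Curtis dissimilarity with a dummy species
#'
#' Computes pairwise Bray-Curtis dissimilarities between plots after an
#' optional square-root transform of the abundances and after appending a
#' tiny constant "dummy species" (default 1e-7) to every plot. The dummy
#' makes comparisons between depauperate or entirely empty plots defined
#' (two empty plots have dissimilarity 0 instead of NaN) while perturbing
#' non-degenerate values by less than its own magnitude.
#'
#' @param comm plots x species matrix of non-negative abundances.
#' @param transform `"sqrt"` (the convention for these multivariate
#'   analyses) or `"none"`.
#' @param dummy value of the dummy species appended after the transform.
#' @return a `dist` object labelled by plot ids.
#' @examples
#' m <- rbind(a = c(1, 0), b = c(0, 1), c = c(0, 0), d = c(0, 0))
#' round(as.matrix(bray_curtis(m, transform = "none")), 5)
#' @export
bray_curtis <- function(comm, transform = c("sqrt", "none"), dummy = 1e-7) {
  transform <- match.arg(transform)
  comm <- as.matrix(comm)
  if (any(comm < 0)) stop("abundances must be non-negative")
  x <- if (transform == "sqrt") sqrt(comm) else comm
  x <- cbind(x, .dummy = dummy)
  d <- vegan::vegdist(x, method = "bray")
  attr(d, "dummy") <- dummy
  attr(d, "transform") <- transform
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Global NMDS minimising Kruskal stress-1 by iterative monotone (isotonic)
#' regression, taking the best of several random starts (the first start is
#' the metric-scaling configuration). The returned configuration is
#' Procrustes-aligned to the metric-scaling reference and centred, so output
#' orientation is reproducible despite the rotational indeterminacy of NMDS.
#'
#' @param d a `dist` or square symmetric dissimilarity matrix.
#' @param k number of ordination dimensions.
#' @param restarts number of starts (first metric, remainder random).
#' @param seed integer seed for the random starts.
#' @param maxit maximum iterations per start.
#' @return an object of class `"elev_nmds"`: `points` (n x k, centred),
#'   `stress` (Kruskal stress-1, in \[0, 1\]), `restarts`, `converged`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed = NULL, maxit = 500) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12))
      stop("'d' must be a dist object or square symmetric matrix")
    d <- stats::as.dist(m)
  }
  if (k < 1) stop("'k' must be >= 1")
  n <- attr(d, "Size")
  ref <- stats::cmdscale(d, k = k, add = TRUE)$points
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(max(1, restarts))) {
      y0 <- if (i == 1) ref else matrix(runif(n * k, -1, 1), n, k)
      m <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                          maxit = maxit, smin = 1e-4, sfgrmin = 1e-7)
      if (is.null(best) || m$stress < best$stress) best <- m
    }
    pts <- vegan::procrustes(ref, best$points, symmetric = FALSE)$Yrot
    pts <- scale(pts, scale = FALSE)
    dimnames(pts) <- list(attr(d, "Labels"), paste0("NMDS", seq_len(k)))
    # icause: 1 = stress minimum, 2 = stress ratio, 3 = scale-factor of
    # gradient reached; 4 = iteration limit (not converged)
    structure(list(points = pts, stress = best$stress,
                   restarts = restarts,
                   converged = best$icause %in% 1:3,
                   k = k),
              class = "elev_nmds")
  })
}

#' @export
print.elev_nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d points, k = %d, stress-1 = %.4f (%s)\n",
              nrow(x$points), x$k, x$stress,
              if (x$converged) "converged" else "best of non-converged runs"))
  invisible(x)
}

#' Ordinate a community matrix, excluding empty plots
#'
#' Convenience front-end: square-root transform, Bray-Curtis with dummy
#' species, then NMDS. Plots with zero total abundance are excluded from the
#' ordination (their dissimilarities to everything are dominated by the
#' dummy species and carry no compositional information), mirroring the
#' exclusion of samples in which no animals were collected.
#'
#' @inheritParams bray_curtis
#' @inheritParams nmds
#' @return an `"elev_nmds"` object; excluded plot ids in `$excluded`.
#' @export
ordinate_community <- function(comm, k = 2, restarts = 20, seed = NULL,
                               transform = "sqrt", dummy = 1e-7) {
  comm <- as.matrix(comm)
  empty <- rowSums(comm) == 0
  ord <- nmds(bray_curtis(comm[!empty, , drop = FALSE],
                          transform = transform, dummy = dummy),
              k = k, restarts = restarts, seed = seed)
  ord$excluded <- rownames(comm)[empty]
  ord
}

#' Fit environmental vectors onto an ordination
#'
#' Regresses each environmental variable on the ordination coordinates,
#' reporting the direction cosines of the fitted gradient vector, the
#' squared correlation r2, and a permutation P value (variable values
#' permuted across plots).
#'
#' @param ord an `"elev_nmds"` object (or a matrix of coordinates).
#' @param env data frame of numeric variables; rows matched to ordination
#'   points by name when row names are present, otherwise by position.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data frame of class `"env_vectors"`: one row per variable with
#'   direction cosines (`cos1`, `cos2`, ...), `r2` and `P`. Constant
#'   variables get `r2 = 0` and `P = NA` with a warning.
#' @export
fit_env_vectors <- function(ord, env, n_perm = 999, seed = NULL) {
  pts <- if (inherits(ord, "elev_nmds")) ord$points else as.matrix(ord)
  env <- as.data.frame(env)
  if (!is.null(rownames(pts)) && all(rownames(pts) %in% rownames(env)))
    env <- env[rownames(pts), , drop = FALSE]
  if (nrow(env) != nrow(pts))
    stop("'env' rows must align with the ordination points")
  const <- vapply(env, function(v) var(v) == 0, logical(1))
  if (any(const))
    warning("constant variable(s): ", paste(names(env)[const], collapse = ", "),
            " (r2 = 0)")
  out <- data.frame(variable = names(env))
  kd <- ncol(pts)
  cosm <- matrix(NA_real_, nrow(out), kd,
                 dimnames = list(NULL, paste0("cos", seq_len(kd))))
  out <- cbind(out, cosm, r2 = NA_real_, P = NA_real_)
  keep <- !const
  if (any(keep)) {
    ef <- with_seed(seed,
      vegan::envfit(pts, env[, keep, drop = FALSE], permutations = n_perm))
    arr <- ef$vectors$arrows           # already unit direction cosines
    out[keep, paste0("cos", seq_len(kd))] <- arr
    out$r2[keep] <- ef$vectors$r
    out$P[keep] <- ef$vectors$pvals
  }
  out$r2[const] <- 0
  class(out) <- c("env_vectors", "data.frame")
  attr(out, "n_perm") <- n_perm
  out
}
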