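# Pre-analysis predictor reduction: within groups of predictors measuring
# similar properties (temperature, precipitation, ...), iteratively remove
# the lower-priority member of any pair correlated at |r| strictly greater
# than the threshold. Cross-group pairs are never removed, however strong
# the correlation (this is why a 0.90 history/precipitation pair can
# survive screening at r_max = 0.90).

#' Screen predictors by within-group pairwise correlation
#'
#' @param env data frame of numeric predictors.
#' @param groups named character vector mapping every predictor name to a
#'   property group; only pairs within the same group are eligible for
#'   removal.
#' @param r_max removal threshold; a pair triggers removal only when
#'   `|r| > r_max` (strictly greater).
#' @param priority character vector of predictor names, most-preferred
#'   first; the lowest-priority member of the offending pairs is removed at
#'   each iteration. Defaults to the column order of `env`.
#' @return list of class `"screening_report"`: `env` (the reduced table),
#'   `retained`, `removed` (data frame with the partner and r that triggered
#'   each removal), and the full pairwise `cor_matrix` of the input.
#' @examples
#' env <- data.frame(a = rnorm(30))
#' env$b <- env$a + rnorm(30, sd = 0.05)  # r > 0.99, same group
#' env$c <- rnorm(30)
#' screen_predictors(env, groups = c(a = "g1", b = "g1", c = "g2"))
#' @export
screen_predictors <- function(env, groups, r_max = 0.90, priority = NULL) {
  env <- as.data.frame(env)
  vars <- names(env)
  missing <- setdiff(vars, names(groups))
  if (length(missing))
    stop("group map missing predictor(s): ", paste(missing, collapse = ", "))
  if (is.null(priority)) priority <- vars
  if (!all(vars %in% priority))
    stop("priority list missing predictor(s): ",
         paste(setdiff(vars, priority), collapse = ", "))
  cm_full <- cor(env)
  retained <- vars
  removed <- data.frame(name = character(), partner = character(),
                        r = numeric())
  repeat {
    cm <- cor(env[retained])
    same_group <- outer(groups[retained], groups[retained], `==`)
    offending <- abs(cm) > r_max & same_group & upper.tri(cm)
    if (!any(offending)) break
    idx <- which(offending, arr.ind = TRUE)
    cand <- unique(retained[c(idx[, 1], idx[, 2])])
    # remove the candidate ranked last in the priority list
    drop_var <- cand[which.max(match(cand, priority))]
    rows <- idx[idx[, 1] == match(drop_var, retained) |
                idx[, 2] == match(drop_var, retained), , drop = FALSE]
    rr <- cm[rows[which.max(abs(cm[rows])), , drop = FALSE]]
    partner_i <- rows[which.max(abs(cm[rows])), ]
    partner <- setdiff(retained[partner_i], drop_var)[1]
    removed <- rbind(removed,
                     data.frame(name = drop_var, partner = partner, r = rr))
    retained <- setdiff(retained, drop_var)
  }
  structure(list(env = env[retained], retained = retained,
                 removed = removed, cor_matrix = cm_full,
                 r_max = r_max),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Predictor screening at |r| > %.2f (within property groups)\n",
              x$r_max))
  cat(sprintf("retained %d of %d predictors\n", length(x$retained),
              length(x$retained) + nrow(x$removed)))
  if (nrow(x$removed)) {
    cat("removed:\n")
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  %s (r = %.3f with %s)\n", x$removed$name[i],
                  x$removed$r[i], x$removed$partner[i]))
  }
  invisible(x)
}
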