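# End-to-end orchestration: screening -> per-subregion rarefaction ->
# richness/abundance trend models -> dissimilarity/NMDS/vector fit ->
# PERMANOVA -> model averaging, with every stage's table written to disk
# and a JSON manifest recording the seed and configuration.

#' Elevational trend models for richness and abundance
#'
#' Computes per-plot observed species richness (species with count > 0) and
#' total abundance — plots with no animals contribute zeros, they are not
#' dropped — and fits each as a negative-binomial mixed model on actual
#' elevation (km, centred) with a subregion random intercept.
#'
#' @param comm plots x species count matrix.
#' @param plots plot table with `actual_elev` and `subregion`.
#' @return list of class `"trend_models"` with elements `richness` and
#'   `abundance` (each an [fit_nb_glmm()] result) and the per-plot summary
#'   data frame.
#' @export
richness_abundance_trend <- function(comm, plots) {
  comm <- as.matrix(comm)
  stopifnot(nrow(comm) == nrow(plots))
  richness <- rowSums(comm > 0)
  abundance <- rowSums(comm)
  if (all(abundance == 0)) warning("all plots empty: degenerate trend models")
  elev_km <- (plots$actual_elev - mean(plots$actual_elev)) / 1000
  x <- matrix(elev_km, dimnames = list(NULL, "elev_km"))
  structure(list(
    richness = fit_nb_glmm(richness, x, plots$subregion),
    abundance = fit_nb_glmm(abundance, x, plots$subregion),
    data = data.frame(plot_id = plots$plot_id, richness = richness,
                      abundance = abundance, elev_km = elev_km,
                      subregion = plots$subregion)),
    class = "trend_models")
}

#' @export
print.trend_models <- function(x, ...) {
  for (nm in c("richness", "abundance")) {
    cat("==", nm, "~ elevation (km) ==\n")
    print(x[[nm]])
  }
  invisible(x)
}

#' Default pipeline run configuration
#'
#' @param seed master seed; stage seeds are deterministic offsets so each
#'   stage is reproducible independently of the others.
#' @param n_perm PERMANOVA permutations.
#' @param n_null model-averaging null datasets.
#' @param nmds_k,nmds_restarts NMDS dimensions and random restarts.
#' @param digits significant digits for numeric CSV output.
#' @param averaging_predictors optional character vector restricting the
#'   model-averaging stage to a subset of the screened predictors (useful
#'   for small designs where all 2^12 models would be over-parameterised).
#' @param sim arguments forwarded to [sim_config()].
#' @return a nested list understood by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, n_perm = 4999, n_null = 999,
                               nmds_k = 2, nmds_restarts = 20, digits = 6,
                               averaging_predictors = NULL, sim = list()) {
  list(seed = as.integer(seed), n_perm = n_perm, n_null = n_null,
       nmds_k = nmds_k, nmds_restarts = nmds_restarts, digits = digits,
       averaging_predictors = averaging_predictors, sim = sim)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [default_run_config()];
#'   unknown keys are an error.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(base, raw)
}

write_table <- function(x, path, digits) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], signif, digits)
  write.csv(x, path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic data generated from the configured
#' design: predictor screening, per-subregion rarefaction, richness and
#' abundance trend models, Bray-Curtis dissimilarity, NMDS with
#' environmental vectors, PERMANOVA, and univariate plus multivariate
#' summed-weight model averaging. Each stage's table is written as CSV to
#' `out_dir` together with a JSON manifest (seed, configuration, package
#' version). A stage failure halts the run with an error naming the stage
#' and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config list from [default_run_config()] or [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with every stage result.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("elevcomm_run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digits <- config$digits %||% 6
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  res <- list()
  res$config <- config
  stage("simulate", {
    cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    res$plots <- sim_design(cfg)
    res$env <- sim_environment(res$plots, cfg)
    res$comm <- sim_community(res$plots, res$env, cfg)
    write_table(res$plots, file.path(out_dir, "plots.csv"), digits)
    write_table(cbind(plot_id = rownames(res$env), res$env),
                file.path(out_dir, "environment.csv"), digits)
    write_table(cbind(plot_id = rownames(res$comm),
                      as.data.frame(res$comm)),
                file.path(out_dir, "community.csv"), digits)
    res$sim_config <- cfg
  })
  stage("screen", {
    gm <- default_env_groups()
    res$screening <- screen_predictors(res$env, gm$groups,
                                       priority = gm$priority)
    write_table(as.data.frame(res$screening$cor_matrix),
                file.path(out_dir, "screening_correlations.csv"), digits)
    writeLines(c(paste("retained:", paste(res$screening$retained,
                                          collapse = ", ")),
                 sprintf("removed: %s (r = %.3f with %s)",
                         res$screening$removed$name,
                         res$screening$removed$r,
                         res$screening$removed$partner)),
               file.path(out_dir, "screening_log.txt"))
  })
  stage("rarefy", {
    pools <- subregion_abundances(res$comm, res$plots)
    res$rarefaction <- lapply(pools, function(v) {
      if (sum(v) == 0) NULL else rarefaction_curve(v)
    })
    for (sr in names(res$rarefaction)) {
      if (is.null(res$rarefaction[[sr]])) next
      write_table(as.data.frame(res$rarefaction[[sr]]),
                  file.path(out_dir, paste0("rarefaction_",
                                            gsub("\\W+", "_", sr), ".csv")),
                  digits)
    }
  })
  stage("trend", {
    res$trend <- richness_abundance_trend(res$comm, res$plots)
    tabs <- lapply(c("richness", "abundance"), function(nm) {
      tt <- res$trend[[nm]]$table
      cbind(model = nm, term = rownames(tt), tt)
    })
    write_table(do.call(rbind, tabs), file.path(out_dir, "trend.csv"),
                digits)
  })
  stage("ordinate", {
    res$dissimilarity <- bray_curtis(res$comm)
    dm <- as.matrix(res$dissimilarity)
    write_table(cbind(plot_id = rownames(dm), as.data.frame(dm)),
                file.path(out_dir, "dissimilarity.csv"), digits)
    res$nmds <- ordinate_community(res$comm, k = config$nmds_k,
                                   restarts = config$nmds_restarts,
                                   seed = config$seed + 10L)
    pts <- as.data.frame(res$nmds$points)
    write_table(cbind(plot_id = rownames(pts), pts),
                file.path(out_dir, "nmds_points.csv"), digits)
    writeLines(sprintf("stress = %.6f", res$nmds$stress),
               file.path(out_dir, "nmds_stress.txt"))
    res$env_vectors <- fit_env_vectors(
      res$nmds, res$screening$env, n_perm = 999, seed = config$seed + 11L)
    write_table(as.data.frame(res$env_vectors),
                file.path(out_dir, "env_vectors.csv"), digits)
  })
  stage("permanova", {
    res$permanova <- permanova(res$dissimilarity, res$plots,
                               c("subregion", "actual_elev"),
                               n_perm = config$n_perm,
                               seed = config$seed + 20L)
    write_table(res$permanova$table, file.path(out_dir, "permanova.csv"),
                digits)
  })
  stage("average", {
    avg_env <- res$screening$env
    if (!is.null(config$averaging_predictors)) {
      missing <- setdiff(config$averaging_predictors, names(avg_env))
      if (length(missing))
        stop("averaging_predictors not among screened predictors: ",
             paste(missing, collapse = ", "))
      avg_env <- avg_env[config$averaging_predictors]
    }
    richness <- rowSums(res$comm > 0)
    res$avg_richness <- importance_permtest(
      richness, avg_env, "univariate",
      n_null = config$n_null, seed = config$seed + 30L)
    write_table(res$avg_richness$table,
                file.path(out_dir, "averaging_richness.csv"), digits)
    res$avg_composition <- importance_permtest(
      res$comm, avg_env, "multivariate",
      n_null = config$n_null, seed = config$seed + 31L)
    write_table(res$avg_composition$table,
                file.path(out_dir, "averaging_composition.csv"), digits)
  })
  stage("manifest", {
    manifest <- list(
      package = "elevcomm",
      version = as.character(utils::packageVersion("elevcomm")),
      seed = config$seed,
      n_perm = config$n_perm, n_null = config$n_null,
      config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(res)
}
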