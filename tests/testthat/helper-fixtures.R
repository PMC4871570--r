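# Shared fixtures: all synthetic, built in code at test time.

# a small fully-populated survey (2 subregions x 2 zones x 2 plots)
tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             zones = list(A = c(400, 800), B = c(600, 1000)),
             latitudes = c(A = -17, B = -16.4),
             plots_per_zone = 2, n_species = 8,
             endemic_fraction = 0.25,
             intercept_mean = -0.3, elev_effect = 1, ...)
}

tiny_survey <- function(seed = 1, ...) {
  cfg <- tiny_config(seed = seed, ...)
  plots <- sim_design(cfg)
  env <- sim_environment(plots, cfg)
  comm <- sim_community(plots, env, cfg)
  list(config = cfg, plots = plots, env = env, comm = comm)
}

# Kruskal stress-1 of a configuration against a dissimilarity matrix,
# computed from scratch with isotonic regression (independent of monoMDS)
stress1 <- function(points, d) {
  dv <- as.vector(as.dist(d))
  cv <- as.vector(dist(points))
  o <- order(dv)
  dhat <- stats::isoreg(dv[o], cv[o])$yf[order(o)]
  sqrt(sum((cv - dhat)^2) / sum(cv^2))
}
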