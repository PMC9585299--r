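# Synthetic latitudinal-gradient generator: regions, plots, environment,
# birth-death phylogeny, Brownian traits, and environmentally filtered
# log-series communities, with recorded ground truth.

#' Simulation configuration
#'
#' Defaults emulate the study design of a western-Amazonian plot network:
#' 5 regions of 10 plots each spanning roughly 10 degrees of southern
#' latitude, temperature seasonality nearly collinear with latitude
#' (target |r| = 0.97), precipitation / soil pH / bulk density within
#' realistic lowland-Amazonian ranges and uncorrelated with latitude by
#' construction, a species pool of 800 taxa on an ultrametric birth-death
#' tree (depth rescaled to 100), traits with Brownian phylogenetic signal,
#' log-series abundances with a heavy rare-species tail, and plot richness
#' responding to seasonality, precipitation, and pH on the log scale.
#'
#' @param seed integer seed; mandatory, every run is fully deterministic.
#' @param n_regions number of regions (default 5).
#' @param plots_per_region plots per region (default 10).
#' @param lat_range latitude span in signed decimal degrees
#'   (default `c(-13, -3)`).
#' @param species_pool_size taxa in the regional pool (default 800).
#' @param beta named effect sizes on log plot richness per standardised
#'   predictor: `seasonality`, `precip`, `pH`, `bulk_density`.
#' @param beta0 intercept of log plot richness (default `log(90)`).
#' @param sigma_alpha SD of the region random intercept (default 0.15).
#' @param theta_richness NB dispersion of plot richness (default 15).
#' @param target_r target |Pearson r| between latitude and temperature
#'   seasonality (default 0.97).
#' @param seasonality_range realised seasonality range in °C
#'   (default `c(4.16, 9.30)`).
#' @param precip_range annual precipitation range in mm/yr
#'   (default `c(1756, 3948)`).
#' @param ph_range soil pH range (default `c(3.78, 5.46)`).
#' @param bd_range soil bulk density range in g/cm³ (default `c(0.61, 1.00)`).
#' @param logseries_x log-series parameter in (0,1) controlling the
#'   rare-species tail (default 0.85, giving ~45% singletons and ~3
#'   individuals per species on average).
#' @param abundance_model `"logseries"` (default) or `"lognormal"`.
#' @param lognormal_sd SD of the lognormal abundance alternative (default 1).
#' @param bm_rate Brownian SD per unit branch length for log traits
#'   (default 0.04, giving log-trait SD ~0.4 at tree depth 100).
#' @param birth,death birth-death rates of the pool tree (default 0.15/0.05).
#' @param niche_width Gaussian environmental-filtering kernel width on the
#'   seasonality axis, in °C (default 3).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_regions = 5L,
                       plots_per_region = 10L,
                       lat_range = c(-13, -3),
                       species_pool_size = 800L,
                       beta = c(seasonality = -0.25, precip = 0.10,
                                pH = -0.08, bulk_density = -0.04),
                       beta0 = log(90),
                       sigma_alpha = 0.15,
                       theta_richness = 15,
                       target_r = 0.97,
                       seasonality_range = c(4.16, 9.30),
                       precip_range = c(1756, 3948),
                       ph_range = c(3.78, 5.46),
                       bd_range = c(0.61, 1.00),
                       logseries_x = 0.85,
                       abundance_model = c("logseries", "lognormal"),
                       lognormal_sd = 1,
                       bm_rate = 0.04,
                       birth = 0.15, death = 0.05,
                       niche_width = 3) {
  if (missing(seed) || !is_count(abs(seed) + 1) || !is.finite(seed)) {
    stopf("`seed` is mandatory and must be a single integer")
  }
  if (!is_count(n_regions) || !is_count(plots_per_region) ||
      !is_count(species_pool_size)) {
    stopf("counts in the configuration must be positive integers")
  }
  if (target_r <= 0 || target_r > 1) stopf("target_r must be in (0, 1]")
  if (logseries_x <= 0 || logseries_x >= 1) stopf("logseries_x must be in (0,1)")
  cfg <- list(seed = as.integer(seed), n_regions = as.integer(n_regions),
              plots_per_region = as.integer(plots_per_region),
              lat_range = lat_range,
              species_pool_size = as.integer(species_pool_size),
              beta = beta, beta0 = beta0, sigma_alpha = sigma_alpha,
              theta_richness = theta_richness, target_r = target_r,
              seasonality_range = seasonality_range,
              precip_range = precip_range, ph_range = ph_range,
              bd_range = bd_range, logseries_x = logseries_x,
              abundance_model = match.arg(abundance_model),
              lognormal_sd = lognormal_sd,
              bm_rate = bm_rate, birth = birth, death = death,
              niche_width = niche_width)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the plot environment table
#'
#' Region latitudes are evenly spaced over `lat_range` with small within-region
#' jitter. Temperature seasonality is built as a linear function of |latitude|
#' plus a Gaussian noise draw orthogonalised against |latitude| and mixed in
#' so the realised Pearson correlation with latitude equals the (negative)
#' target; the vector is then mapped linearly into `seasonality_range`.
#' Precipitation, pH, and bulk density are region-level draws (plus plot
#' jitter) inside their configured ranges, independent of latitude by
#' construction.
#'
#' @param cfg a [sim_config()].
#' @return Environment table (see [read_env()]).
#' @export
simulate_environment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nr <- cfg$n_regions; np <- cfg$plots_per_region
  region <- rep(sprintf("R%02d", seq_len(nr)), each = np)
  plot_id <- sprintf("%s_P%02d", region, rep(seq_len(np), nr))
  centers <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = nr)
  lat <- rep(centers, each = np) + stats::runif(nr * np, -0.2, 0.2)
  alat <- abs(lat)
  # seasonality exactly at the target correlation with |latitude|
  noise <- stats::rnorm(nr * np)
  e <- stats::residuals(stats::lm(noise ~ alat))      # orthogonal to |lat|
  z <- cfg$target_r * scale(alat)[, 1] +
    sqrt(1 - cfg$target_r^2) * scale(e)[, 1]
  seas <- cfg$seasonality_range[1] + (z - min(z)) / (max(z) - min(z)) *
    diff(cfg$seasonality_range)
  rg_draw <- function(rng, jitter_frac = 0.06) {
    centers <- stats::runif(nr, rng[1], rng[2])
    v <- rep(centers, each = np) +
      stats::rnorm(nr * np, 0, jitter_frac * diff(rng))
    pmin(pmax(v, rng[1]), rng[2])
  }
  data.frame(plot = plot_id, region = region, latitude = lat,
             temp_seasonality = as.numeric(seas),
             annual_precip = rg_draw(cfg$precip_range),
             soil_pH = rg_draw(cfg$ph_range),
             bulk_density = rg_draw(cfg$bd_range),
             stringsAsFactors = FALSE)
}

#' Simulate the species-pool phylogeny and traits
#'
#' A constant-rate birth-death tree with `species_pool_size` tips is rescaled
#' to depth 100; SLA (mm²/mg), LT (mm), and WD (g/cm³) evolve by Brownian
#' motion on the log scale along it (hence phylogenetically conserved traits)
#' and are exponentiated around field-plausible medians (SLA 15, LT 0.25,
#' WD 0.6).
#'
#' @param cfg a [sim_config()].
#' @return List with `tree` (`ape::phylo`, ultrametric, depth 100) and
#'   `traits` (trait table data frame).
#' @export
simulate_tree_and_traits <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$species_pool_size
  tree <- ape::rphylo(n, birth = cfg$birth, death = cfg$death)
  depth <- max(node_depths(tree)[seq_len(n)])
  tree$edge.length <- tree$edge.length * (100 / depth)
  tree$tip.label <- sprintf("sp%04d", seq_len(n))
  centers <- c(SLA = log(15), LT = log(0.25), WD = log(0.6))
  traits <- vapply(names(centers), function(nm) {
    x <- ape::rTraitCont(tree, model = "BM", sigma = cfg$bm_rate)
    centers[[nm]] + x - mean(x)
  }, numeric(n))
  data_traits <- data.frame(taxon = tree$tip.label, exp(traits),
                            stringsAsFactors = FALSE)
  list(tree = tree, traits = data_traits)
}

# Log-series sampler: counts >= 1, P(k) proportional to x^k / k.
rlogseries <- function(n, x, kmax = 5000L) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = x^k / k)
}

#' Simulate community abundances on the environmental gradient
#'
#' Per plot, a target richness is drawn from a negative binomial whose
#' log-mean is `beta0` plus the configured effects of standardised
#' seasonality, precipitation, pH, and bulk density plus a region random
#' intercept. That many species are then sampled from the pool without
#' replacement, weighted by a Gaussian kernel matching each species'
#' trait-derived seasonality optimum to the plot's seasonality (environmental
#' filtering; the kernel width sets the strength of the FD/PD gradient).
#' Individual counts follow a log-series (default) or lognormal distribution,
#' so most species in a plot are rare.
#'
#' @param cfg a [sim_config()].
#' @param env environment table from [simulate_environment()].
#' @param tree,traits pool phylogeny and traits from
#'   [simulate_tree_and_traits()].
#' @return List with `community` (plot × taxon count matrix restricted to
#'   taxa observed at least once) and `truth` (ground-truth record: the
#'   configuration, region intercepts, per-plot expected log richness and
#'   realised richness, and the species' niche optima).
#' @export
simulate_communities <- function(cfg, env, tree, traits) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n_plot <- nrow(env)
  zs <- function(v) as.numeric(scale(v))
  lp <- cfg$beta0 +
    cfg$beta[["seasonality"]] * zs(env$temp_seasonality) +
    cfg$beta[["precip"]] * zs(env$annual_precip) +
    cfg$beta[["pH"]] * zs(env$soil_pH) +
    cfg$beta[["bulk_density"]] * zs(env$bulk_density)
  region_fx <- stats::rnorm(cfg$n_regions, 0, cfg$sigma_alpha)
  names(region_fx) <- unique(env$region)
  lp <- lp + region_fx[env$region]
  s_target <- stats::rnbinom(n_plot, size = cfg$theta_richness, mu = exp(lp))
  s_target <- pmax(s_target, 2L)
  capped <- s_target > cfg$species_pool_size
  if (any(capped)) {
    warnf("%d plot(s) had target richness above the species pool; capped",
          sum(capped))
    s_target[capped] <- cfg$species_pool_size
  }
  # species' seasonality optimum: first principal axis of log traits, mapped
  # onto the realised seasonality range (trait-environment matching)
  lt <- scale(log(as.matrix(traits[, c("SLA", "LT", "WD")])))
  ax <- stats::prcomp(lt)$x[, 1]
  rng <- range(env$temp_seasonality)
  optimum <- rng[1] + (ax - min(ax)) / (max(ax) - min(ax)) * diff(rng)
  names(optimum) <- traits$taxon
  counts <- matrix(0L, n_plot, cfg$species_pool_size,
                   dimnames = list(env$plot, traits$taxon))
  for (i in seq_len(n_plot)) {
    w <- exp(-(optimum - env$temp_seasonality[i])^2 / (2 * cfg$niche_width^2))
    sp <- sample(traits$taxon, s_target[i], prob = w)
    ab <- switch(cfg$abundance_model,
      logseries = rlogseries(s_target[i], cfg$logseries_x),
      lognormal = pmax(1L, round(stats::rlnorm(s_target[i], 0, cfg$lognormal_sd))))
    counts[i, sp] <- ab
  }
  storage.mode(counts) <- "double"   # matches the CSV round-trip type
  seen <- colSums(counts) > 0
  truth <- list(config = unclass(cfg), region_intercepts = region_fx,
                expected_log_richness = as.numeric(lp),
                realised_richness = as.integer(rowSums(counts > 0)),
                plot = env$plot, niche_optimum = optimum)
  list(community = counts[, seen, drop = FALSE], truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_environment()], [simulate_tree_and_traits()], and
#' [simulate_communities()] under one configuration, optionally writing the
#' four input files (community/traits/environment CSV, newick tree) plus a
#' `ground_truth.json` into a directory.
#'
#' @param cfg a [sim_config()], or an integer seed for defaults.
#' @param dir optional output directory.
#' @return List `community`, `traits`, `tree`, `env`, `truth`, `config`.
#' @export
simulate_study <- function(cfg, dir = NULL) {
  if (is.numeric(cfg)) cfg <- sim_config(seed = cfg)
  stopifnot(inherits(cfg, "sim_config"))
  env <- simulate_environment(cfg)
  tt <- simulate_tree_and_traits(cfg)
  com <- simulate_communities(cfg, env, tt$tree, tt$traits)
  out <- list(community = com$community,
              traits = tt$traits[tt$traits$taxon %in% colnames(com$community), ],
              tree = tt$tree, env = env, truth = com$truth, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_community(out$community, file.path(dir, "community.csv"))
    write_traits(out$traits, file.path(dir, "traits.csv"))
    write_env(out$env, file.path(dir, "environment.csv"))
    ape::write.tree(out$tree, file.path(dir, "tree.nwk"))
    truth <- out$truth
    truth$niche_optimum <- as.list(truth$niche_optimum)
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
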