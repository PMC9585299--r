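test_that("simulation is fully deterministic under a fixed configuration", {
  cfg <- sim_config(seed = 99, species_pool_size = 120L, beta0 = log(40))
  a <- suppressWarnings(simulate_study(cfg))
  b <- suppressWarnings(simulate_study(cfg))
  expect_identical(a$community, b$community)
  expect_identical(a$env, b$env)
  expect_identical(a$traits, b$traits)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("environment table has the study's shape and calibrated collinearity", {
  env <- simulate_environment(sim_config(seed = 1))
  expect_equal(nrow(env), 50)
  expect_equal(length(unique(env$region)), 5)
  expect_true(all(table(env$region) == 10))
  expect_true(all(env$latitude >= -13.2 & env$latitude <= -2.8))
  expect_true(all(env$annual_precip >= 1756 & env$annual_precip <= 3948))
  expect_true(all(env$soil_pH >= 3.78 & env$soil_pH <= 5.46))
  expect_true(all(env$bulk_density >= 0.61 & env$bulk_density <= 1.00))

  for (seed in 1:10) {
    env <- simulate_environment(sim_config(seed = seed))
    r <- cor(env$latitude, env$temp_seasonality)
    expect_lt(abs(abs(r) - 0.97), 0.02)
    expect_lt(r, 0)   # seasonality rises away from the Equator
  }
  # a target of 1 gives perfect collinearity
  env1 <- simulate_environment(sim_config(seed = 3, target_r = 1))
  expect_equal(abs(cor(env1$latitude, env1$temp_seasonality)), 1,
               tolerance = 1e-9)
  expect_error(sim_config(seed = 1, target_r = 1.2), "target_r")
})

test_that("pool tree is ultrametric at depth 100 with Brownian trait signal", {
  cfg <- sim_config(seed = 5, species_pool_size = 100L)
  tt <- simulate_tree_and_traits(cfg)
  depths <- divgrad:::node_depths(tt$tree)[seq_len(100)]
  expect_equal(unname(depths), rep(100, 100), tolerance = 1e-9)
  expect_true(all(tt$traits$SLA > 0 & tt$traits$LT > 0 & tt$traits$WD > 0))

  # Brownian rate 0: traits identical, downstream Q = 0 handled
  flat <- simulate_tree_and_traits(sim_config(seed = 5,
                                              species_pool_size = 50L,
                                              bm_rate = 0))
  expect_equal(var(flat$traits$SLA), 0)
  dm <- matrix(0, 3, 3)
  expect_equal(hill_functional(dm, rep(1 / 3, 3), 1)$equiv_species, 1)

  # phylogenetic signal: sister tips more similar than random pairs
  sister_mse <- random_mse <- numeric(0)
  for (seed in 1:10) {
    tt <- simulate_tree_and_traits(sim_config(seed = seed,
                                              species_pool_size = 80L))
    tr <- tt$tree
    lsla <- log(tt$traits$SLA)
    names(lsla) <- tt$traits$taxon
    ntip <- length(tr$tip.label)
    parents <- tr$edge[tr$edge[, 2] <= ntip, 1]
    tips <- tr$edge[tr$edge[, 2] <= ntip, 2]
    sisters <- split(tips, parents)
    sisters <- sisters[lengths(sisters) == 2]
    for (s in sisters) {
      sister_mse <- c(sister_mse,
                      (lsla[tr$tip.label[s[1]]] - lsla[tr$tip.label[s[2]]])^2)
    }
    rnd <- replicate(50, sample(ntip, 2))
    random_mse <- c(random_mse, (lsla[rnd[1, ]] - lsla[rnd[2, ]])^2)
  }
  expect_lt(mean(sister_mse), mean(random_mse))
})

test_that("communities carry a heavy rare-species tail and respond to seasonality", {
  sing <- rich_cold <- rich_warm <- numeric(0)
  for (seed in 1:5) {
    s <- simulate_study(sim_config(seed = seed, species_pool_size = 300L))
    frac <- apply(s$community, 1, function(x) sum(x == 1) / sum(x > 0))
    sing <- c(sing, mean(frac))
    seas <- s$env$temp_seasonality
    rich <- rowSums(s$community > 0)
    rich_cold <- c(rich_cold, mean(rich[seas > median(seas)]))   # harsher
    rich_warm <- c(rich_warm, mean(rich[seas <= median(seas)]))
  }
  expect_gte(mean(sing), 0.40)
  # negative seasonality effect: richer plots where seasonality is low
  expect_gt(mean(rich_warm), mean(rich_cold))
})

test_that("null effects are recovered as near-zero coefficients", {
  set.seed(71)
  betas <- matrix(NA_real_, 20, 4)
  for (i in 1:20) {
    cfg <- sim_config(seed = 7000 + i, species_pool_size = 200L,
                      beta = c(seasonality = 0, precip = 0, pH = 0,
                               bulk_density = 0),
                      sigma_alpha = 0)
    s <- simulate_study(cfg)
    rich <- rowSums(s$community > 0)
    fit <- fit_nb_glmm(rich, s$env[, c("temp_seasonality", "annual_precip",
                                       "soil_pH", "bulk_density")],
                       group = s$env$region, nodes = 5, standardize = TRUE)
    betas[i, ] <- fit$coefficients[-1, 1]
  }
  expect_lt(max(abs(colMeans(betas))), 0.1)
})

test_that("simulate_study writes the pipeline's input formats plus ground truth", {
  dir <- withr::local_tempdir()
  s <- suppressWarnings(
    simulate_study(sim_config(seed = 11, species_pool_size = 80L,
                              beta0 = log(30)), dir = dir))
  expect_true(all(file.exists(file.path(dir, c("community.csv", "traits.csv",
                                               "environment.csv", "tree.nwk",
                                               "ground_truth.json")))))
  cm <- read_community(file.path(dir, "community.csv"))
  expect_identical(cm, s$community)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(truth$config$sigma_alpha, 0.15)
  expect_equal(length(truth$expected_log_richness), 50)
})
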