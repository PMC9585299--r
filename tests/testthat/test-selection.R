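test_that("Pearson matrix handles exact, inverse, and orthogonal relations", {
  x <- 1:10
  quad <- (x - 5.5)^2                      # symmetric: orthogonal to x - mean
  env <- data.frame(a = x, b = 2 * x + 3, c = -x, d = quad - mean(quad))
  cm <- pearson_matrix(env, c("a", "b", "c", "d"))
  expect_equal(cm["a", "b"], 1.0, tolerance = 1e-12)
  expect_equal(cm["a", "c"], -1.0, tolerance = 1e-12)
  expect_equal(cm["a", "d"], 0.0, tolerance = 1e-12)
  expect_error(pearson_matrix(data.frame(a = x, k = rep(5, 10)), c("a", "k")),
               "constant")
})

test_that("collinearity flags respect the threshold and sort by |r|", {
  m <- diag(3)
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  m["x", "y"] <- m["y", "x"] <- 0.95
  m["y", "z"] <- m["z", "y"] <- -0.75
  fl <- flag_collinear(m, 0.7)
  expect_equal(nrow(fl), 2)
  expect_equal(fl$r[1], 0.95)
  expect_equal(nrow(flag_collinear(diag(3), 0.7)), 0)
  expect_equal(nrow(flag_collinear(m, 1.0)), 0)
})

test_that("the selection rule rejects delta >= 2 and prefers complexity below it", {
  fits <- list(fake_fit(430.0, n_slopes = 2, formula = "m2"),
               fake_fit(431.5, n_slopes = 4, formula = "m4"),
               fake_fit(434.0, n_slopes = 3, formula = "m3"))
  sel <- select_model(fits)
  expect_equal(sel$selected$formula, "m4")

  # delta >= 2: the 4-term model is rejected
  fits2 <- list(fake_fit(430.0, n_slopes = 2, formula = "m2"),
                fake_fit(432.1, n_slopes = 4, formula = "m4"))
  expect_equal(select_model(fits2)$selected$formula, "m2")

  expect_equal(select_model(list(fake_fit(99, formula = "only")))$selected$formula,
               "only")
  # equal term counts inside the window: lower AICc wins
  fits3 <- list(fake_fit(430.0, n_slopes = 2, formula = "lo"),
                fake_fit(431.0, n_slopes = 2, formula = "hi"))
  expect_equal(select_model(fits3)$selected$formula, "lo")

  expect_error(select_model(list(fake_fit(1, converged = FALSE))), "converged")
})

test_that("selection is invariant to candidate order", {
  set.seed(61)
  fits <- list(fake_fit(430.0, n_slopes = 2, formula = "m2"),
               fake_fit(431.5, n_slopes = 4, formula = "m4"),
               fake_fit(431.1, n_slopes = 3, formula = "m3"),
               fake_fit(436.0, n_slopes = 1, formula = "m1"))
  base <- select_model(fits)$selected$formula
  for (i in 1:10) {
    perm <- sample(length(fits))
    expect_equal(select_model(fits[perm])$selected$formula, base)
  }
})

test_that("candidate_glmms fits all 16 main-effect subsets", {
  set.seed(62)
  env <- data.frame(
    plot = sprintf("p%02d", 1:30), region = rep(c("A", "B", "C"), each = 10),
    latitude = runif(30, -13, -3), temp_seasonality = runif(30, 4, 9),
    annual_precip = runif(30, 1800, 3900), soil_pH = runif(30, 3.8, 5.4),
    bulk_density = runif(30, 0.6, 1.0))
  y <- rnbinom(30, size = 5, mu = exp(3 - 0.2 * scale(env$temp_seasonality)))
  res <- candidate_glmms(y, env, nodes = 5)
  expect_equal(nrow(res$table), 16)
  expect_equal(sum(res$table$selected), 1)
  expect_true(all(res$table$Rm2[res$table$converged] <=
                    res$table$Rc2[res$table$converged] + 1e-8))
})

test_that("permuted predictors yield small, mostly non-significant pseudo-R2", {
  set.seed(63)
  y <- rnbinom(50, size = 4, mu = 20)
  x <- rnbinom(50, size = 4, mu = 15)
  null_fit <- fit_nb_glm(y)
  hits <- 0
  for (i in 1:100) {
    xp <- sample(x)
    f <- fit_nb_glm(y, data.frame(x = xp))
    pr2 <- cragg_uhler_r2(f, null_fit)
    pval <- f$coefficients["x", "Pr(>|z|)"]
    if (pr2 < 0.1 && pval >= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("cross-attribute GLM tables handle regions and missing attributes", {
  set.seed(64)
  plots <- sprintf("p%02d", 1:20)
  td <- rnbinom(20, size = 10, mu = 40)
  prof <- rbind(
    data.frame(plot = plots, attribute = "TD", q = 0, value = td),
    data.frame(plot = plots, attribute = "FD", q = 0,
               value = td * 0.8 + rpois(20, 3)))
  env <- data.frame(plot = plots,
                    region = rep(c("r1", "r2"), each = 10),
                    latitude = runif(20, -13, -3),
                    temp_seasonality = runif(20, 4, 9),
                    annual_precip = runif(20, 1800, 3900),
                    soil_pH = runif(20, 3.8, 5.4),
                    bulk_density = runif(20, 0.6, 1.0))
  # duplicate-region construction: identical data in both regions
  prof2 <- prof
  prof2$value[prof2$plot %in% plots[11:20]] <-
    prof2$value[prof2$plot %in% plots[1:10]]
  tab <- attribute_cross_glms(prof2, env, min_region_plots = 5)
  r1 <- tab[tab$scope == "r1" & tab$response == "TD" & tab$predictor == "FD", ]
  r2 <- tab[tab$scope == "r2" & tab$response == "TD" & tab$predictor == "FD", ]
  expect_equal(r1$pr2, r2$pr2, tolerance = 1e-9)
  # PD absent: flagged, not fatal
  pd_rows <- tab[tab$predictor == "PD", ]
  expect_true(all(is.na(pd_rows$pr2)))
  expect_true(all(pd_rows$note != ""))
})

test_that("a response equal to its predictor gives pseudo-R2 near 1 without NaN", {
  set.seed(65)
  v <- rnbinom(30, size = 8, mu = 50)
  prof <- rbind(data.frame(plot = paste0("p", 1:30), attribute = "TD", q = 0,
                           value = v),
                data.frame(plot = paste0("p", 1:30), attribute = "FD", q = 0,
                           value = v))
  tab <- attribute_cross_glms(prof)
  row <- tab[tab$response == "TD" & tab$predictor == "FD", ]
  expect_false(is.nan(row$pr2))
  expect_gt(row$pr2, 0.9)
})
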