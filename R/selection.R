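# Collinearity screen, the AICc selection rule, and the candidate-set
# machinery for the environmental-driver models.

#' Pearson correlation matrix of environmental variables
#'
#' @param env environment table (see [read_env()]).
#' @param variables column names to correlate; default the four candidate
#'   predictors plus latitude.
#' @return Symmetric correlation matrix.
#' @export
pearson_matrix <- function(env, variables = c("latitude", "temp_seasonality",
                                              "annual_precip", "soil_pH",
                                              "bulk_density")) {
  missing_v <- setdiff(variables, names(env))
  if (length(missing_v)) stopf("variables not in env: %s",
                               paste(missing_v, collapse = ", "))
  m <- as.matrix(env[, variables])
  if (nrow(m) < 3L) stopf("need at least 3 observations")
  const <- variables[apply(m, 2, function(v) stats::sd(v) == 0)]
  if (length(const)) stopf("constant variable(s): %s", paste(const, collapse = ", "))
  stats::cor(m, use = "pairwise.complete.obs", method = "pearson")
}

#' Flag collinear variable pairs
#'
#' Advisory screen: reports every pair with `|r| >= threshold`, sorted by
#' descending `|r|`. Nothing is dropped automatically.
#'
#' @param cm correlation matrix from [pearson_matrix()].
#' @param threshold default 0.7.
#' @return Data frame `var1`, `var2`, `r` (possibly empty).
#' @export
flag_collinear <- function(cm, threshold = 0.7) {
  ut <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  out <- data.frame(var1 = rownames(cm)[ut[, 1]], var2 = colnames(cm)[ut[, 2]],
                    r = cm[ut], row.names = NULL)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' AICc-based model selection, preferring the most complex near-tie
#'
#' Ranks candidate fits by AICc; fits with `ΔAICc >= 2` from the minimum are
#' rejected, and among the remainder the fit with the most fixed-effect terms
#' is selected (ties on term count broken by lower AICc). The result is
#' invariant to the input order of candidates.
#'
#' @param candidates list of `ModelFit` objects sharing the same response;
#'   non-converged fits are excluded (an error is raised if none converged).
#' @param n_terms optional integer vector of fixed-effect term counts; by
#'   default inferred as the number of non-intercept coefficients.
#' @return List with `table` (data frame: formula, n_terms, k, logLik, AICc,
#'   delta_aicc, converged, selected), `selected` (the chosen `ModelFit`),
#'   and `selected_index` (into the original candidate list).
#' @export
select_model <- function(candidates, n_terms = NULL) {
  if (!length(candidates)) stopf("no candidate models")
  if (inherits(candidates, "ModelFit")) candidates <- list(candidates)
  if (is.null(n_terms)) {
    n_terms <- vapply(candidates, function(f) {
      sum(rownames(f$coefficients) != "(Intercept)")
    }, integer(1))
  }
  conv <- vapply(candidates, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stopf("no converged candidate model")
  aiccs <- vapply(candidates, function(f) f$aicc, numeric(1))
  aiccs[!conv] <- Inf
  delta <- aiccs - min(aiccs)
  in_window <- delta < 2
  pool <- which(in_window)
  pool <- pool[order(-n_terms[pool], aiccs[pool])]
  sel <- pool[1]
  tab <- data.frame(
    formula = vapply(candidates, function(f) f$formula, character(1)),
    n_terms = n_terms,
    k = vapply(candidates, function(f) f$k, integer(1)),
    logLik = vapply(candidates, function(f) f$logLik, numeric(1)),
    aicc = vapply(candidates, function(f) f$aicc, numeric(1)),
    delta_aicc = delta,
    converged = conv,
    selected = seq_along(candidates) == sel)
  tab <- tab[order(tab$aicc), ]
  list(table = tab, selected = candidates[[sel]], selected_index = sel)
}

#' Fit all main-effect candidate GLMMs for one response
#'
#' Fits the 2^p subsets of the fixed-effect predictors (no interactions;
#' the region random intercept always included) and applies [select_model()].
#' Predictors are z-standardised before fitting. For each candidate, Nakagawa
#' marginal and conditional R² are computed.
#'
#' @param y response vector (Hill numbers; real values accepted).
#' @param env environment table with the predictor columns and `region`.
#' @param predictors candidate fixed effects; default temperature
#'   seasonality, annual precipitation, soil pH, bulk density.
#' @param nodes Gauss–Hermite nodes for [fit_nb_glmm()].
#' @return List as [select_model()], with `table` gaining `Rm2` and `Rc2`
#'   columns and `fits` holding all candidate `ModelFit`s.
#' @export
candidate_glmms <- function(y, env, predictors = c("temp_seasonality",
                                                   "annual_precip", "soil_pH",
                                                   "bulk_density"),
                            nodes = 15L) {
  missing_v <- setdiff(c(predictors, "region"), names(env))
  if (length(missing_v)) stopf("env lacks columns: %s",
                               paste(missing_v, collapse = ", "))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(predictors)))
  fits <- vector("list", nrow(subsets))
  r2 <- matrix(NA_real_, nrow(subsets), 2)
  for (i in seq_len(nrow(subsets))) {
    vars <- predictors[unlist(subsets[i, ])]
    Xi <- if (length(vars)) env[, vars, drop = FALSE] else NULL
    fits[[i]] <- fit_nb_glmm(y, Xi, group = env$region, nodes = nodes,
                             standardize = length(vars) > 0)
    if (isTRUE(fits[[i]]$converged)) {
      r2i <- nakagawa_r2(fits[[i]])
      r2[i, ] <- c(r2i$Rm2, r2i$Rc2)
    }
  }
  res <- select_model(fits, n_terms = rowSums(subsets))
  ord <- match(rownames(res$table), as.character(seq_along(fits)))
  res$table$Rm2 <- r2[ord, 1]
  res$table$Rc2 <- r2[ord, 2]
  res$fits <- fits
  res
}

# Significance stars for Wald p-values, alpha = 0.05 / 0.01 / 0.001.
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Cross-attribute negative binomial GLMs
#'
#' For each ordered attribute pair (TD~FD, TD~PD, FD~PD) and each order q,
#' fits a negative binomial GLM of the first attribute's Hill numbers on the
#' second's, overall and (optionally) per region, reporting the Cragg–Uhler
#' pseudo-R² and a Wald significance star on the slope.
#'
#' @param profile long diversity profile (`plot`, `attribute`, `q`, `value`).
#' @param env optional environment table; when given, per-region fits are
#'   added for regions with at least `min_region_plots` plots.
#' @param min_region_plots minimum plots for a per-region fit (default 5).
#' @return Data frame `scope`, `q`, `response`, `predictor`, `pr2`, `p_slope`,
#'   `stars`, `n`, `note`.
#' @export
attribute_cross_glms <- function(profile, env = NULL, min_region_plots = 5L) {
  pairs <- list(c("TD", "FD"), c("TD", "PD"), c("FD", "PD"))
  qs <- sort(unique(profile$q))
  scopes <- list(list(name = "all", plots = unique(profile$plot)))
  if (!is.null(env)) {
    for (rg in unique(env$region)) {
      pl <- env$plot[env$region == rg]
      if (length(pl) >= min_region_plots) {
        scopes <- c(scopes, list(list(name = rg, plots = pl)))
      }
    }
  }
  rows <- list()
  for (sc in scopes) for (q in qs) for (pr in pairs) {
    sub <- profile[profile$q == q & profile$plot %in% sc$plots, ]
    resp <- sub$value[match(unique(sub$plot), sub$plot)]
    wide <- stats::reshape(sub[, c("plot", "attribute", "value")],
                           idvar = "plot", timevar = "attribute",
                           direction = "wide")
    ycol <- paste0("value.", pr[1]); xcol <- paste0("value.", pr[2])
    note <- ""
    if (!all(c(ycol, xcol) %in% names(wide))) {
      rows[[length(rows) + 1]] <- data.frame(
        scope = sc$name, q = q, response = pr[1], predictor = pr[2],
        pr2 = NA_real_, p_slope = NA_real_, stars = "", n = 0L,
        note = "attribute not computed")
      next
    }
    ok <- stats::complete.cases(wide[, c(ycol, xcol)])
    yv <- wide[[ycol]][ok]; xv <- wide[[xcol]][ok]
    if (sum(ok) < 3L) {
      rows[[length(rows) + 1]] <- data.frame(
        scope = sc$name, q = q, response = pr[1], predictor = pr[2],
        pr2 = NA_real_, p_slope = NA_real_, stars = "", n = sum(ok),
        note = "too few complete plots")
      next
    }
    res <- tryCatch({
      f1 <- fit_nb_glm(yv, data.frame(x = xv))
      f0 <- fit_nb_glm(yv)
      pr2 <- cragg_uhler_r2(f1, f0)
      pv <- f1$coefficients["x", "Pr(>|z|)"]
      data.frame(scope = sc$name, q = q, response = pr[1], predictor = pr[2],
                 pr2 = pr2, p_slope = pv, stars = p_stars(pv), n = sum(ok),
                 note = note)
    }, error = function(e) {
      data.frame(scope = sc$name, q = q, response = pr[1], predictor = pr[2],
                 pr2 = NA_real_, p_slope = NA_real_, stars = "", n = sum(ok),
                 note = conditionMessage(e))
    })
    rows[[length(rows) + 1]] <- res
  }
  do.call(rbind, rows)
}

#' Latitude GLMs for each attribute and order
#'
#' Negative binomial GLM of each attribute's Hill numbers on signed latitude
#' (decimal degrees); a positive slope means diversity increases toward the
#' Equator in the southern hemisphere.
#'
#' @param profile long diversity profile.
#' @param env environment table with `plot` and `latitude`.
#' @return Data frame `attribute`, `q`, `slope`, `pr2`, `p_slope`, `stars`, `n`.
#' @export
latitude_glms <- function(profile, env) {
  rows <- list()
  for (att in unique(profile$attribute)) for (q in sort(unique(profile$q))) {
    sub <- profile[profile$attribute == att & profile$q == q, ]
    lat <- env$latitude[match(sub$plot, env$plot)]
    ok <- stats::complete.cases(sub$value, lat)
    if (sum(ok) < 3L) next
    res <- tryCatch({
      f1 <- fit_nb_glm(sub$value[ok], data.frame(latitude = lat[ok]))
      f0 <- fit_nb_glm(sub$value[ok])
      pv <- f1$coefficients["latitude", "Pr(>|z|)"]
      data.frame(attribute = att, q = q,
                 slope = f1$coefficients["latitude", "Estimate"],
                 pr2 = cragg_uhler_r2(f1, f0), p_slope = pv,
                 stars = p_stars(pv), n = sum(ok))
    }, error = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  do.call(rbind, rows)
}
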