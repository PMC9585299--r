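# End-to-end orchestration: read or simulate inputs, compute the diversity
# profile, run the cross-attribute and latitude GLM tables, fit and select
# the environmental GLMM candidates, and write tidy CSV outputs.

#' Run configuration
#'
#' Exactly one of `input` (paths to community/traits/tree/environment files)
#' or `simulate` (arguments for [sim_config()]) must be given.
#'
#' @param output_dir directory for the output bundle.
#' @param seed integer seed (mandatory in simulate mode; also seeds any
#'   downstream randomness).
#' @param input named list with paths `community`, `traits`, `tree`, `env`
#'   (traits/tree optional), or `NULL`.
#' @param simulate named list of [sim_config()] overrides, or `TRUE` for
#'   defaults, or `NULL`.
#' @param q_list diversity orders (default 0, 1, 2).
#' @param distance_method `"gower"` or `"euclidean"` for [trait_distance()].
#' @param collinearity_threshold |r| threshold for [flag_collinear()].
#' @param nodes Gauss–Hermite nodes for the GLMMs.
#' @param min_region_plots minimum plots for per-region cross-attribute GLMs.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir, seed, input = NULL, simulate = NULL,
                       q_list = c(0, 1, 2),
                       distance_method = "gower",
                       collinearity_threshold = 0.7,
                       nodes = 15L,
                       min_region_plots = 5L) {
  if (is.null(input) == is.null(simulate)) {
    stopf("exactly one of `input` or `simulate` must be given")
  }
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              input = input,
              simulate = if (isTRUE(simulate)) list() else simulate,
              q_list = q_list, distance_method = distance_method,
              collinearity_threshold = collinearity_threshold,
              nodes = as.integer(nodes),
              min_region_plots = as.integer(min_region_plots))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

write_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(format(df, digits = 10, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the inputs, aligns them, computes the plot × attribute
#' × q Hill-number profile, fits the cross-attribute GLM table, the latitude
#' GLM table, and the 16-candidate environmental GLMM set per response with
#' AICc selection, and writes the output bundle:
#' `diversity_profile.csv`, `attribute_glms.csv`, `latitude_glms.csv`,
#' `glmm_candidates.csv`, `glmm_selected.csv`, `correlation_matrix.csv`,
#' `coverage_report.csv`, and `run.log`, each carrying the hash of the
#' serialised configuration (`config.yaml`). On a stage failure the outputs
#' written so far are retained and the failing stage is named in the error.
#'
#' @param config a `run_config` (or path to its YAML serialisation).
#' @return Invisibly, a list with all computed tables and the bundle dir.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$output_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  # hash of the analysis configuration (where the bundle lands is excluded,
  # so identical analyses hash identically)
  hashable <- unclass(config)
  hashable$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hashable, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  logfile <- file.path(config$output_dir, "run.log")
  cat(sprintf("divgrad run %s\nconfig_hash: %s\n", format(Sys.time()), hash),
      file = logfile)
  logmsg <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = logfile, append = TRUE)
  }
  stage <- "load inputs"
  result <- list(dir = config$output_dir, config_hash = hash)
  tryCatch({
    if (!is.null(config$simulate)) {
      sim <- do.call(sim_config, c(list(seed = config$seed), config$simulate))
      study <- simulate_study(sim, dir = file.path(config$output_dir, "inputs"))
      logmsg("simulated inputs: %d plots, %d taxa observed",
             nrow(study$community), ncol(study$community))
    } else {
      inp <- config$input
      study <- list(
        community = read_community(inp$community),
        traits = if (!is.null(inp$traits)) read_traits(inp$traits),
        tree = if (!is.null(inp$tree)) read_newick(inp$tree),
        env = read_env(inp$env))
      logmsg("read inputs: %d plots, %d taxa", nrow(study$community),
             ncol(study$community))
    }

    stage <- "align inputs"
    aligned <- align_inputs(study$community, study$traits, study$tree,
                            study$env)
    write_table(aligned$coverage,
                file.path(config$output_dir, "coverage_report.csv"), hash)
    result$coverage <- aligned$coverage

    stage <- "diversity profile"
    dmat <- if (!is.null(study$traits) && length(aligned$taxa$FD) >= 2) {
      trait_distance(study$traits[study$traits$taxon %in% aligned$taxa$FD, ],
                     method = config$distance_method)
    }
    profile <- diversity_profile(study$community, traits = NULL,
                                 tree = study$tree, q_list = config$q_list,
                                 distance = dmat)
    write_table(profile, file.path(config$output_dir, "diversity_profile.csv"),
                hash)
    result$profile <- profile
    logmsg("diversity profile: %d rows", nrow(profile))

    stage <- "correlation screen"
    cormat <- pearson_matrix(study$env)
    flagged <- flag_collinear(cormat, config$collinearity_threshold)
    write_table(data.frame(variable = rownames(cormat), round(cormat, 6)),
                file.path(config$output_dir, "correlation_matrix.csv"), hash)
    result$correlation <- cormat
    if (nrow(flagged)) {
      logmsg("collinear pairs (|r| >= %.2f): %s",
             config$collinearity_threshold,
             paste(sprintf("%s~%s (r=%.3f)", flagged$var1, flagged$var2,
                           flagged$r), collapse = "; "))
    }

    stage <- "cross-attribute GLMs"
    cross <- attribute_cross_glms(profile, study$env,
                                  config$min_region_plots)
    write_table(cross, file.path(config$output_dir, "attribute_glms.csv"),
                hash)
    result$attribute_glms <- cross

    stage <- "latitude GLMs"
    latg <- latitude_glms(profile, study$env)
    write_table(latg, file.path(config$output_dir, "latitude_glms.csv"), hash)
    result$latitude_glms <- latg

    stage <- "GLMM candidates and selection"
    cands <- list(); selected <- list()
    for (att in unique(profile$attribute)) for (q in config$q_list) {
      sub <- profile[profile$attribute == att & profile$q == q, ]
      y <- sub$value[match(study$env$plot, sub$plot)]
      ok <- is.finite(y)
      if (sum(ok) < 10L) next
      res <- candidate_glmms(y[ok], study$env[ok, ], nodes = config$nodes)
      key <- sprintf("%s_q%g", att, q)
      tab <- cbind(response = key, res$table)
      cands[[key]] <- tab
      sel <- tab[tab$selected, , drop = FALSE]
      r2sel <- c(Rm2 = sel$Rm2, Rc2 = sel$Rc2)
      selected[[key]] <- sel
      logmsg("%s: selected %s (AICc %.2f, Rm2 %.3f, Rc2 %.3f)", key,
             sel$formula, sel$aicc, r2sel[1], r2sel[2])
    }
    cand_tab <- do.call(rbind, cands)
    sel_tab <- do.call(rbind, selected)
    write_table(cand_tab, file.path(config$output_dir, "glmm_candidates.csv"),
                hash)
    write_table(sel_tab, file.path(config$output_dir, "glmm_selected.csv"),
                hash)
    result$glmm_candidates <- cand_tab
    result$glmm_selected <- sel_tab
    logmsg("pipeline complete")
  }, error = function(e) {
    logmsg("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}

#' Human-readable summary of a pipeline output bundle
#'
#' Renders a markdown summary of the bundle written by [run_pipeline()]:
#' cross-attribute pseudo-R² blocks with significance stars, the latitude
#' trend table, and the AICc ladder per response with the selected model
#' marked.
#'
#' @param dir bundle directory.
#' @param file optional path to write the summary to (default
#'   `report.md` inside the bundle).
#' @return The summary text, invisibly; written to `file`.
#' @export
report_bundle <- function(dir, file = file.path(dir, "report.md")) {
  need <- c("attribute_glms.csv", "latitude_glms.csv", "glmm_candidates.csv",
            "glmm_selected.csv", "diversity_profile.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) stopf("missing bundle file: %s", f)
  }
  rd <- function(f) utils::read.csv(file.path(dir, f), comment.char = "#",
                                    stringsAsFactors = FALSE)
  cross <- rd("attribute_glms.csv")
  latg <- rd("latitude_glms.csv")
  cand <- rd("glmm_candidates.csv")
  sel <- rd("glmm_selected.csv")
  out <- c("# divgrad run summary", "",
           "## Cross-attribute pseudo-R² (NB GLMs)", "")
  for (sc in unique(cross$scope)) {
    out <- c(out, sprintf("### %s", sc), "",
             "| q | TD~FD | TD~PD | FD~PD |", "|---|---|---|---|")
    for (q in sort(unique(cross$q))) {
      cell <- vapply(list(c("TD", "FD"), c("TD", "PD"), c("FD", "PD")),
                     function(pr) {
        row <- cross[cross$scope == sc & cross$q == q &
                       cross$response == pr[1] & cross$predictor == pr[2], ]
        if (!nrow(row) || !is.finite(row$pr2[1])) return("not computed")
        sprintf("%.2f%s", row$pr2[1], row$stars[1])
      }, character(1))
      out <- c(out, sprintf("| %g | %s |", q, paste(cell, collapse = " | ")))
    }
    out <- c(out, "")
  }
  out <- c(out, "## Latitude GLMs", "",
           "| attribute | q | slope | pR² | |", "|---|---|---|---|---|")
  for (i in seq_len(nrow(latg))) {
    out <- c(out, sprintf("| %s | %g | %.4f | %.2f | %s |", latg$attribute[i],
                          latg$q[i], latg$slope[i], latg$pr2[i], latg$stars[i]))
  }
  out <- c(out, "", "## GLMM selection (AICc ladders)", "")
  for (key in unique(cand$response)) {
    sub <- cand[cand$response == key, ]
    out <- c(out, sprintf("### %s", key), "")
    for (i in order(sub$aicc)) {
      mark <- if (sub$selected[i]) "**" else ""
      out <- c(out, sprintf("- %s%s — AICc %.2f (Δ %.2f), Rm² %.3f, Rc² %.3f%s",
                            mark, sub$formula[i], sub$aicc[i],
                            sub$delta_aicc[i], sub$Rm2[i], sub$Rc2[i], mark))
    }
    chosen <- sel[sel$response == key, "formula"]
    if (length(chosen) && !chosen %in% sub$formula[sub$selected]) {
      stopf("selected model mismatch for %s", key)
    }
    out <- c(out, "")
  }
  writeLines(out, file)
  invisible(paste(out, collapse = "\n"))
}
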