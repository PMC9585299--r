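# Domain containers and CSV I/O: community matrix, specimen records, trait
# table, environment table. Taxon and plot identifiers are opaque strings
# (whitespace-trimmed); no nomenclature resolution is attempted.

#' Validate a plot-by-taxon community matrix
#'
#' @param cm numeric matrix, plots in rows (rownames) and taxa in columns
#'   (colnames), holding non-negative integer counts of individuals.
#' @return The validated matrix (invisibly unchanged).
#' @details Invariants enforced: unique plot and taxon names, integer counts
#'   >= 0, and strictly positive total abundance in every plot.
#' @export
validate_community <- function(cm) {
  if (!is.matrix(cm) || !is.numeric(cm)) {
    stopf("community matrix must be a numeric matrix")
  }
  if (is.null(rownames(cm)) || is.null(colnames(cm))) {
    stopf("community matrix needs plot rownames and taxon colnames")
  }
  if (anyDuplicated(colnames(cm))) {
    stopf("duplicate taxon names: %s",
          paste(unique(colnames(cm)[duplicated(colnames(cm))]), collapse = ", "))
  }
  if (anyDuplicated(rownames(cm))) {
    stopf("duplicate plot names: %s",
          paste(unique(rownames(cm)[duplicated(rownames(cm))]), collapse = ", "))
  }
  bad <- which(!is.finite(cm) | cm < 0 | cm != round(cm), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("invalid count at plot '%s', taxon '%s' (must be integer >= 0)",
          rownames(cm)[bad[1, 1]], colnames(cm)[bad[1, 2]])
  }
  tot <- rowSums(cm)
  if (any(tot == 0)) {
    stopf("plot has zero total abundance: %s",
          paste(rownames(cm)[tot == 0], collapse = ", "))
  }
  cm
}

#' Read a community matrix from CSV
#'
#' Expects a header row of taxon names and a first column of plot identifiers;
#' the remaining cells are integer counts. Row and column order are preserved.
#'
#' @param path CSV file path.
#' @return Validated plot-by-taxon integer matrix.
#' @export
read_community <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("community CSV needs a plot column plus taxa")
  plots <- trimws(as.character(df[[1]]))
  taxa <- trimws(colnames(df)[-1])
  vals <- df[, -1, drop = FALSE]
  suppressWarnings(num <- vapply(vals, function(col) as.numeric(col),
                                 numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df))
  nonnum <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(nonnum) > 0L) {
    stopf("non-numeric count at plot '%s', taxon '%s'",
          plots[nonnum[1, 1]], taxa[nonnum[1, 2]])
  }
  dimnames(num) <- list(plots, taxa)
  validate_community(num)
}

#' Write a community matrix to CSV
#'
#' Inverse of [read_community()]: the written file round-trips bit-exactly.
#'
#' @param cm validated community matrix.
#' @param path output CSV path.
#' @export
write_community <- function(cm, path) {
  cm <- validate_community(cm)
  df <- data.frame(plot = rownames(cm), cm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive per-taxon trait means from specimen measurements
#'
#' Specific leaf area is the ratio of leaf surface area (mm²) to leaf dry
#' mass (mg); wood density is the ratio of branch dry mass (g) to branch fresh
#' volume (cm³); leaf thickness (mm) is taken as measured. Specimens lacking
#' any of the three traits are dropped, and the unweighted arithmetic mean
#' over the remaining specimens of each taxon is returned. Taxa with no
#' complete specimen are excluded with a warning.
#'
#' @param records data frame of specimen measurements with columns `taxon` and
#'   any of `leaf_area`, `leaf_dry_mass`, `leaf_thickness`, `branch_dry_mass`,
#'   `branch_fresh_volume` (missing measurements as `NA`). Alternatively
#'   pre-computed `SLA`/`LT`/`WD` columns are accepted as-is.
#' @return Trait table: data frame with columns `taxon`, `SLA` (mm²/mg),
#'   `LT` (mm), `WD` (g/cm³); one row per taxon retained.
#' @export
derive_traits <- function(records) {
  if (!is.data.frame(records) || !"taxon" %in% names(records)) {
    stopf("`records` must be a data frame with a `taxon` column")
  }
  rec <- records
  rec$taxon <- trimws(as.character(rec$taxon))
  get <- function(nm) if (nm %in% names(rec)) rec[[nm]] else rep(NA_real_, nrow(rec))
  for (nm in c("leaf_area", "leaf_dry_mass", "branch_dry_mass",
               "branch_fresh_volume", "leaf_thickness", "SLA", "LT", "WD")) {
    v <- get(nm)
    if (any(!is.na(v) & v <= 0)) {
      stopf("non-positive %s in specimen records", nm)
    }
  }
  sla <- ifelse(!is.na(get("SLA")), get("SLA"),
                get("leaf_area") / get("leaf_dry_mass"))
  lt <- ifelse(!is.na(get("LT")), get("LT"), get("leaf_thickness"))
  wd <- ifelse(!is.na(get("WD")), get("WD"),
               get("branch_dry_mass") / get("branch_fresh_volume"))
  complete <- !is.na(sla) & !is.na(lt) & !is.na(wd)
  taxa_all <- unique(rec$taxon)
  kept <- rec$taxon[complete]
  dropped <- setdiff(taxa_all, kept)
  if (length(dropped) > 0L) {
    warnf("%d taxon/taxa dropped: no specimen with all three traits (%s%s)",
          length(dropped), paste(utils::head(dropped, 5), collapse = ", "),
          if (length(dropped) > 5) ", ..." else "")
  }
  agg <- function(x) tapply(x[complete], kept, mean)
  out <- data.frame(taxon = sort(unique(kept)), stringsAsFactors = FALSE)
  out$SLA <- as.numeric(agg(sla)[out$taxon])
  out$LT <- as.numeric(agg(lt)[out$taxon])
  out$WD <- as.numeric(agg(wd)[out$taxon])
  rownames(out) <- NULL
  out
}

#' Read / write a trait table
#'
#' @param path CSV path with columns `taxon`, `SLA`, `LT`, `WD`.
#' @return Data frame with strictly positive trait values for every taxon.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon", "SLA", "LT", "WD")
  if (!all(need %in% names(df))) {
    stopf("trait CSV must have columns %s", paste(need, collapse = ", "))
  }
  df$taxon <- trimws(df$taxon)
  if (anyDuplicated(df$taxon)) stopf("duplicate taxa in trait table")
  vals <- as.matrix(df[, c("SLA", "LT", "WD")])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stopf("trait table requires finite, strictly positive SLA, LT, WD")
  }
  df[, need]
}

#' @rdname read_traits
#' @param tt trait table data frame.
#' @export
write_traits <- function(tt, path) {
  utils::write.csv(format(tt, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plot environment table
#'
#' @param path CSV with columns `plot`, `region`, `latitude` (decimal degrees,
#'   signed), `temp_seasonality` (°C), `annual_precip` (mm/yr), `soil_pH`,
#'   `bulk_density` (g/cm³).
#' @return Validated data frame, one row per plot.
#' @export
read_env <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("plot", "region", "latitude", "temp_seasonality", "annual_precip",
            "soil_pH", "bulk_density")
  if (!all(need %in% names(df))) {
    stopf("environment CSV must have columns %s", paste(need, collapse = ", "))
  }
  df$plot <- trimws(as.character(df$plot))
  df$region <- trimws(as.character(df$region))
  if (anyDuplicated(df$plot)) stopf("duplicate plot ids in environment table")
  df[, need]
}

#' @rdname read_env
#' @param env environment table data frame.
#' @export
write_env <- function(env, path) {
  utils::write.csv(format(env, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align community, trait, tree, and environment inputs
#'
#' Determines, per diversity attribute, the usable taxon set: all community
#' taxa for TD, the community ∩ trait-table intersection for FD, and the
#' community ∩ tree-tip intersection for PD. FD and PD are later computed on
#' their subsets with relative abundances renormalised to sum to 1 within the
#' subset. Plots with fewer than two usable taxa for an attribute are flagged
#' missing for that attribute rather than failing the run.
#'
#' @param cm community matrix.
#' @param tt trait table or `NULL`.
#' @param tree an `ape::phylo` tree or `NULL`.
#' @param env environment table or `NULL`; if given, every plot must have a
#'   row and each region at least two plots.
#' @return List with elements `taxa` (named list `TD`/`FD`/`PD` of usable
#'   taxon vectors), `coverage` (data frame `plot`, `attribute`, `n_taxa`,
#'   `usable`), and the validated inputs. Counts are never altered.
#' @export
align_inputs <- function(cm, tt = NULL, tree = NULL, env = NULL) {
  cm <- validate_community(cm)
  taxa <- list(TD = colnames(cm))
  taxa$FD <- if (is.null(tt)) character(0) else intersect(colnames(cm), tt$taxon)
  taxa$PD <- if (is.null(tree)) character(0) else
    intersect(colnames(cm), tree$tip.label)
  if (!is.null(env)) {
    missing_env <- setdiff(rownames(cm), env$plot)
    if (length(missing_env) > 0L) {
      stopf("plots missing from environment table: %s",
            paste(missing_env, collapse = ", "))
    }
    env_sub <- env[env$plot %in% rownames(cm), ]
    small <- names(which(table(env_sub$region) < 2))
    if (length(small) > 0L) {
      warnf("region(s) with < 2 plots (mixed models need >= 2): %s",
            paste(small, collapse = ", "))
    }
  }
  cov <- do.call(rbind, lapply(names(taxa), function(att) {
    n <- vapply(rownames(cm), function(pl) {
      sum(cm[pl, taxa[[att]], drop = TRUE] > 0)
    }, integer(1))
    data.frame(plot = rownames(cm), attribute = att, n_taxa = n,
               usable = n >= 2L, row.names = NULL)
  }))
  list(cm = cm, traits = tt, tree = tree, env = env,
       taxa = taxa, coverage = cov)
}
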