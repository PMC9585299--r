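# Distance-based functional Hill numbers: Gower or Euclidean trait distances,
# Rao's quadratic entropy, and the effective number of functional entities.

#' Pairwise functional distance matrix from a trait table
#'
#' Default is the Gower distance over (SLA, LT, WD): each trait is
#' range-normalised, absolute differences are averaged across traits, giving
#' d in `[0, 1]`. The alternative is the Euclidean distance on z-scored
#' traits. A trait constant across all taxa carries no information under
#' range normalisation and is dropped with a warning; if all traits are
#' constant the distance is undefined and an error is raised.
#'
#' @param tt trait table (data frame with `taxon`, `SLA`, `LT`, `WD`).
#' @param method `"gower"` (default) or `"euclidean"`.
#' @return Symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
trait_distance <- function(tt, method = c("gower", "euclidean")) {
  method <- match.arg(method)
  if (nrow(tt) < 2L) stopf("need at least 2 taxa for a distance matrix")
  x <- as.matrix(tt[, c("SLA", "LT", "WD")])
  rownames(x) <- tt$taxon
  rng <- apply(x, 2, function(v) diff(range(v)))
  if (method == "gower") {
    keep <- rng > 0
    if (!any(keep)) stopf("all traits constant across taxa; distances undefined")
    if (!all(keep)) {
      warnf("constant trait(s) dropped from Gower distance: %s",
            paste(colnames(x)[!keep], collapse = ", "))
    }
    x <- sweep(x[, keep, drop = FALSE], 2, rng[keep], "/")
    d <- as.matrix(stats::dist(x, method = "manhattan")) / sum(keep)
  } else {
    keep <- rng > 0
    if (!any(keep)) stopf("all traits constant across taxa; distances undefined")
    d <- as.matrix(stats::dist(scale(x[, keep, drop = FALSE])))
  }
  dimnames(d) <- list(tt$taxon, tt$taxon)
  d
}

# Checks a functional distance matrix aligned to an abundance vector.
validate_distance <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    stopf("`d` must be a square numeric matrix")
  }
  if (any(!is.finite(d)) || any(d < 0)) stopf("distances must be finite, >= 0")
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("distance matrix must have zero diagonal")
  d
}

#' Rao's quadratic entropy
#'
#' The abundance-weighted mean pairwise functional distance
#' \eqn{Q = \sum_i \sum_j d_{ij} p_i p_j}. Q is zero exactly when all taxa
#' with positive abundance are functionally identical, in which case the
#' functional Hill numbers are undefined and downstream code reports one
#' functional entity by convention.
#'
#' @param d symmetric distance matrix.
#' @param p relative abundances aligned with the rows of `d`, summing to 1.
#' @return Scalar Q >= 0.
#' @export
rao_Q <- function(d, p) {
  d <- validate_distance(d)
  p <- validate_abundance_aligned(p, nrow(d))
  as.numeric(p %*% d %*% p)
}

validate_abundance_aligned <- function(p, n) {
  if (length(p) != n) stopf("abundance vector length %d != matrix size %d",
                            length(p), n)
  if (any(!is.finite(p)) || any(p < 0)) stopf("abundances must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) stopf("abundances must sum to 1")
  p
}

#' Functional Hill number (effective number of functional entities)
#'
#' In the pairwise-distance framework the functional diversity of order q is
#' \deqn{^qD(Q) = \left[\sum_i\sum_j \frac{d_{ij}}{Q}(p_i p_j)^q\right]^{1/(2(1-q))}}
#' with the q = 1 limit
#' \eqn{\exp(-\tfrac12 \sum_i\sum_j (d_{ij}/Q)\, p_i p_j \ln(p_i p_j))},
#' where Q is Rao's quadratic entropy. `total_fd` is \eqn{Q \cdot [^qD(Q)]^2},
#' the effective total distance. The reported "functional entities" response
#' is `equiv_species` = \eqn{^qD(Q)}, the number of equally abundant, equally
#' distinct species with the same diversity; it is invariant to rescaling the
#' distance matrix.
#'
#' @inheritParams rao_Q
#' @param q diversity order >= 0.
#' @return List with `equiv_species`, `total_fd`, and `Q`. When Q = 0 the
#'   convention `equiv_species = 1`, `total_fd = 0` applies.
#' @export
hill_functional <- function(d, p, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    stopf("`q` must be a single number >= 0")
  }
  d <- validate_distance(d)
  p <- validate_abundance_aligned(p, nrow(d))
  Q <- as.numeric(p %*% d %*% p)
  if (Q <= 0) {
    return(list(equiv_species = 1, total_fd = 0, Q = 0))
  }
  keep <- p > 0
  dk <- d[keep, keep, drop = FALSE]
  pk <- p[keep]
  pp <- outer(pk, pk)                      # p_i p_j
  w <- dk / Q
  if (abs(q - 1) < Q_ONE_EPS) {
    eq <- exp(-0.5 * sum(w * pp * log(pp)))
  } else {
    pos <- w > 0
    s <- sum(w[pos] * pp[pos]^q)
    eq <- s^(1 / (2 * (1 - q)))
  }
  list(equiv_species = eq, total_fd = Q * eq^2, Q = Q)
}

#' Functional diversity profile of a community matrix
#'
#' For each plot, restricts counts to the taxa present in the distance
#' matrix, renormalises relative abundances, and evaluates
#' [hill_functional()] at each order. The reported value is the
#' equally-distinct-species equivalent; the effective total distance is
#' returned alongside.
#'
#' @inheritParams profile_taxonomic
#' @param d functional distance matrix with taxon dimnames (see
#'   [trait_distance()]).
#' @param min_taxa plots with fewer usable taxa than this get `NA` (default 2).
#' @return Data frame `plot`, `attribute` (`"FD"`), `q`, `value`
#'   (equivalent species number), `total_fd`, `rao_q`.
#' @export
profile_functional <- function(cm, d, q_list = c(0, 1, 2), min_taxa = 2L) {
  cm <- validate_community(cm)
  d <- validate_distance(d)
  usable <- intersect(colnames(cm), rownames(d))
  out <- expand.grid(plot = rownames(cm), q = q_list,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$attribute <- "FD"
  out$value <- NA_real_
  out$total_fd <- NA_real_
  out$rao_q <- NA_real_
  for (pl in rownames(cm)) {
    x <- cm[pl, usable, drop = TRUE]
    x <- x[x > 0]
    if (length(x) < min_taxa) next
    p <- x / sum(x)
    dsub <- d[names(x), names(x), drop = FALSE]
    for (q in q_list) {
      h <- hill_functional(dsub, p, q)
      i <- out$plot == pl & out$q == q
      out$value[i] <- h$equiv_species
      out$total_fd[i] <- h$total_fd
      out$rao_q[i] <- h$Q
    }
  }
  out[order(out$plot, out$q),
      c("plot", "attribute", "q", "value", "total_fd", "rao_q")]
}

#' Combined diversity profile (TD, FD, PD)
#'
#' Convenience wrapper producing the long plot × attribute × q table from a
#' community matrix plus optional trait table (or distance matrix) and tree.
#' Attributes whose inputs are absent are skipped; plots with insufficient
#' usable taxa for FD/PD carry `NA` and are reported in the coverage table of
#' [align_inputs()].
#'
#' @inheritParams profile_taxonomic
#' @param traits trait table (used to build a Gower distance), or `NULL`.
#' @param tree `ape::phylo` tree, or `NULL`.
#' @param distance optional pre-computed distance matrix overriding `traits`.
#' @return Data frame `plot`, `attribute`, `q`, `value` in long format.
#' @export
diversity_profile <- function(cm, traits = NULL, tree = NULL,
                              q_list = c(0, 1, 2), distance = NULL) {
  parts <- list(profile_taxonomic(cm, q_list)[, c("plot", "attribute", "q", "value")])
  if (!is.null(distance) || !is.null(traits)) {
    d <- if (!is.null(distance)) distance else trait_distance(traits)
    keep <- intersect(colnames(cm), rownames(d))
    if (length(keep) >= 2) {
      parts <- c(parts, list(
        profile_functional(cm, d, q_list)[, c("plot", "attribute", "q", "value")]))
    }
  }
  if (!is.null(tree)) {
    keep <- intersect(colnames(cm), tree$tip.label)
    if (length(keep) >= 2) {
      parts <- c(parts, list(
        profile_phylogenetic(cm, tree, q_list)[, c("plot", "attribute", "q", "value")]))
    }
  }
  do.call(rbind, parts)
}
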