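# Phylogenetic Hill numbers from branch abundances. Trees are ape "phylo"
# objects; newick parsing and pruning are delegated to ape, the
# branch-abundance aggregation and the effective-number calculation are
# implemented here.

#' Read a rooted newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' diversity calculations rely on: a single rooted tree, unique tip labels,
#' and finite, non-negative branch lengths on every edge (zero lengths are
#' allowed and retained).
#'
#' @param path newick file path (or a literal newick string containing "(").
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- suppressWarnings(if (grepl("(", path, fixed = TRUE)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  })
  if (is.null(tr)) stopf("could not parse newick input")
  if (inherits(tr, "multiPhylo")) stopf("expected a single tree, got several")
  # quoted labels keep their quotes in ape; strip matched surrounding quotes
  tr$tip.label <- sub("^'(.*)'$", "\\1", tr$tip.label)
  tr$tip.label <- sub('^"(.*)"$', "\\1", tr$tip.label)
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object to validate.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("`tree` must be an ape phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stopf("duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stopf("tree has no branch lengths")
  }
  if (length(tree$edge.length) != nrow(tree$edge) ||
      any(!is.finite(tree$edge.length))) {
    bad <- which(!is.finite(tree$edge.length))[1]
    stopf("missing or non-finite branch length on edge to node %s",
          if (length(bad)) tree$edge[bad, 2] else "?")
  }
  if (any(tree$edge.length < 0)) stopf("negative branch lengths present")
  tree
}

#' Prune a tree to a taxon set
#'
#' Returns the smallest subtree containing `taxa`: unbranched internal nodes
#' are collapsed with their lengths summed, and the retained subtree keeps its
#' original root height (the root edge accumulates the collapsed depth), so
#' tip depths are preserved.
#'
#' @param tree an `ape::phylo` tree.
#' @param taxa character vector of tip labels to keep (must all be present).
#' @return The pruned `ape::phylo` tree.
#' @export
prune_to <- function(tree, taxa) {
  tree <- validate_tree(tree)
  taxa <- unique(as.character(taxa))
  absent <- setdiff(taxa, tree$tip.label)
  if (length(absent) > 0L) {
    stopf("taxa absent from tree: %s", paste(absent, collapse = ", "))
  }
  if (length(taxa) == length(tree$tip.label)) return(tree)
  depths <- node_depths(tree)
  if (length(taxa) == 1L) {
    # single-tip tree at the original depth of that tip
    tip <- taxa
    d <- depths[match(tip, tree$tip.label)]
    tr <- list(edge = matrix(c(2L, 1L), nrow = 1),
               tip.label = tip, edge.length = d, Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  sub <- ape::keep.tip(tree, taxa)
  # keep.tip collapses unbranched nodes and sums lengths, but drops the stem
  # above the new root; restore the original root height via the root edge.
  lost <- max(depths[match(taxa, tree$tip.label)]) -
    max(node_depths(sub)[seq_along(sub$tip.label)])
  if (lost > 1e-12) sub$root.edge <- (sub$root.edge %||% 0) + lost
  validate_tree(sub)
}

# Depth (root-to-node path length) of every node, tips first.
node_depths <- function(tree) {
  n_node <- max(tree$edge)
  d <- numeric(n_node)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  ord <- ape::reorder.phylo(tree, "cladewise")
  d[root] <- 0
  for (i in seq_len(nrow(ord$edge))) {
    d[ord$edge[i, 2]] <- d[ord$edge[i, 1]] + ord$edge.length[i]
  }
  d
}

#' Aggregate relative abundances onto tree branches
#'
#' For every branch i of the tree, computes the summed relative abundance
#' `a_i` of the tips descending from it (one post-order traversal), together
#' with the branch length `L_i`. The abundance-weighted mean tip depth
#' \eqn{\bar T = \sum_i L_i a_i} is attached as an attribute; on an
#' ultrametric tree with all tips present it equals the root-to-tip depth.
#' A root edge (`tree$root.edge`), if present, is included with `a = 1`.
#'
#' @param tree an `ape::phylo` tree.
#' @param p named numeric vector of relative abundances over (a subset of)
#'   the tip labels, summing to 1; unnamed vectors of length `Ntip` are taken
#'   in tip order. Tips absent from `p` get abundance 0.
#' @return Data frame of class `branch_abundances` with columns `parent`,
#'   `node`, `length`, `a`; attribute `T_bar`.
#' @export
branch_abundances <- function(tree, p) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (is.null(names(p))) {
    if (length(p) != ntip) {
      stopf("unnamed abundance vector must have one entry per tip")
    }
    names(p) <- tree$tip.label
  }
  absent <- setdiff(names(p)[p > 0], tree$tip.label)
  if (length(absent) > 0L) {
    stopf("positive-abundance taxa missing from tree: %s",
          paste(absent, collapse = ", "))
  }
  p <- p[p > 0]
  if (abs(sum(p) - 1) > 1e-9) {
    stopf("tip abundances must sum to 1 (got %.12g)", sum(p))
  }
  a_node <- numeric(max(tree$edge))
  a_node[match(names(p), tree$tip.label)] <- p
  post <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(post$edge))) {
    a_node[post$edge[i, 1]] <- a_node[post$edge[i, 1]] + a_node[post$edge[i, 2]]
  }
  out <- data.frame(parent = tree$edge[, 1], node = tree$edge[, 2],
                    length = tree$edge.length, a = a_node[tree$edge[, 2]])
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
    out <- rbind(data.frame(parent = NA_integer_, node = root,
                            length = tree$root.edge, a = 1), out)
  }
  attr(out, "T_bar") <- sum(out$length * out$a)
  class(out) <- c("branch_abundances", "data.frame")
  out
}

#' Phylogenetic Hill number (effective number of phylogenetic entities)
#'
#' From branch lengths \eqn{L_i} and branch abundances \eqn{a_i} with
#' reference depth \eqn{\bar T = \sum_i L_i a_i}, the mean phylogenetic
#' diversity of order q is
#' \deqn{^q\bar D = \left[\sum_i \frac{L_i}{\bar T} a_i^q\right]^{1/(1-q)}}
#' with the q = 1 limit \eqn{\exp(-\sum_i (L_i/\bar T) a_i \ln a_i)}, and the
#' total phylogenetic diversity (effective total branch length) is
#' \eqn{^qPD = \bar T \cdot {}^q\bar D}. At q = 0 the total equals Faith's PD,
#' the summed length of all branches with positive descendant abundance.
#'
#' @param bas a [branch_abundances()] result.
#' @param q diversity order >= 0.
#' @return List with `mean_diversity` (effective number of entities),
#'   `total_pd` (effective total branch length), and `T_bar`.
#' @export
hill_phylo <- function(bas, q) {
  if (!inherits(bas, "branch_abundances")) {
    stopf("`bas` must come from branch_abundances()")
  }
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    stopf("`q` must be a single number >= 0")
  }
  keep <- bas$a > 0 & bas$length > 0
  L <- bas$length[keep]
  a <- bas$a[keep]
  T_bar <- attr(bas, "T_bar")
  if (!length(L) || T_bar <= 0) stopf("no branches with positive length and abundance")
  if (abs(q - 1) < Q_ONE_EPS) {
    mean_d <- exp(-sum((L / T_bar) * a * log(a)))
  } else {
    # log-space power sum over branches
    mean_d <- exp(logsumexp(log(L / T_bar) + q * log(a)) / (1 - q))
  }
  list(mean_diversity = mean_d, total_pd = T_bar * mean_d, T_bar = T_bar)
}

#' Phylogenetic diversity profile of a community matrix
#'
#' For each plot, prunes abundances to the taxa present on the tree,
#' renormalises them, aggregates branch abundances, and evaluates
#' [hill_phylo()] at each order. The reported value is the total phylogenetic
#' diversity (effective total branch length; Faith's PD at q = 0); the mean
#' diversity is returned alongside.
#'
#' @inheritParams profile_taxonomic
#' @param tree an `ape::phylo` tree whose tips cover (part of) the taxa.
#' @param min_taxa plots with fewer usable taxa than this get `NA` (default 2).
#' @return Data frame `plot`, `attribute` (`"PD"`), `q`, `value` (total PD),
#'   `mean_diversity`.
#' @export
profile_phylogenetic <- function(cm, tree, q_list = c(0, 1, 2), min_taxa = 2L) {
  cm <- validate_community(cm)
  tree <- validate_tree(tree)
  usable <- intersect(colnames(cm), tree$tip.label)
  out <- expand.grid(plot = rownames(cm), q = q_list,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$attribute <- "PD"
  out$value <- NA_real_
  out$mean_diversity <- NA_real_
  for (pl in rownames(cm)) {
    x <- cm[pl, usable, drop = TRUE]
    x <- x[x > 0]
    if (length(x) < min_taxa) next
    bas <- branch_abundances(tree, x / sum(x))
    for (q in q_list) {
      h <- hill_phylo(bas, q)
      i <- out$plot == pl & out$q == q
      out$value[i] <- h$total_pd
      out$mean_diversity[i] <- h$mean_diversity
    }
  }
  out[order(out$plot, out$q),
      c("plot", "attribute", "q", "value", "mean_diversity")]
}
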