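# Shared fixtures and independent oracles, built in code.

# Hand-checkable 3-tip tree: tips A, B at depth 2, C at depth 2.
worked_tree <- function() read_newick("((A:1,B:1):1,C:2);")

random_abundance <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Random rooted tree with positive branch lengths and a random positive
# abundance vector over a subset of its tips.
random_tree_case <- function(max_tips = 50) {
  n <- sample(3:max_tips, 1)
  tr <- ape::rtree(n)
  keep <- sample(n, sample(2:n, 1))
  p <- random_abundance(length(keep))
  names(p) <- tr$tip.label[keep]
  list(tree = tr, p = p)
}

# Brute-force Faith PD: sum of lengths of branches with at least one
# positive-abundance descendant tip, found by explicit clade extraction.
faith_bruteforce <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  total <- 0
  for (i in seq_len(nrow(tree$edge))) {
    child <- tree$edge[i, 2]
    desc <- if (child <= ntip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    if (any(desc %in% taxa)) total <- total + tree$edge.length[i]
  }
  total
}

# Brute-force functional Hill number: explicit double loop.
hill_functional_bruteforce <- function(d, p, q) {
  n <- length(p)
  Q <- 0
  for (i in 1:n) for (j in 1:n) Q <- Q + d[i, j] * p[i] * p[j]
  if (Q <= 0) return(1)
  s <- 0
  for (i in 1:n) for (j in 1:n) {
    if (d[i, j] > 0) {
      s <- s + (d[i, j] / Q) *
        (if (abs(q - 1) < 1e-8) -p[i] * p[j] * log(p[i] * p[j])
         else (p[i] * p[j])^q)
    }
  }
  if (abs(q - 1) < 1e-8) exp(0.5 * s) else s^(1 / (2 * (1 - q)))
}

# Fabricated ModelFit carrying just what selection / pseudo-R2 need.
fake_fit <- function(aicc_val = NA, logLik = NA, n = NA, k = 2L,
                     n_slopes = 1L, formula = "y ~ x", converged = TRUE) {
  co <- matrix(0, n_slopes + 1L, 4,
               dimnames = list(c("(Intercept)", paste0("x", seq_len(n_slopes))),
                               c("Estimate", "Std. Error", "z value", "Pr(>|z|)")))
  structure(list(kind = "nb_glm", coefficients = co, aicc = aicc_val,
                 logLik = logLik, n = n, k = as.integer(k),
                 formula = formula, converged = converged),
            class = "ModelFit")
}

# Small community matrix used across data-model tests.
small_community <- function() {
  m <- matrix(c(3, 0, 1, 0, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("A", "B", "C")))
  storage.mode(m) <- "double"
  m
}
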