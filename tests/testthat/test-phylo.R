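test_that("newick reading validates structure and preserves labels", {
  tr <- worked_tree()
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(nrow(tr$edge), 4)
  d <- divgrad:::node_depths(tr)
  expect_equal(unname(d[1:3]), c(2, 2, 2))

  expect_error(read_newick("((A:1,B:1):1,C:2)"), regexp = ".")
  tq <- read_newick("(('Inga edulis':1,B:1):1,C:2);")
  expect_true("Inga edulis" %in% tq$tip.label)
  expect_error(read_newick("((A:1,B:1):1,C);"), "branch length")
})

test_that("pruning keeps depths, collapses paths, and is an identity on all tips", {
  tr <- worked_tree()
  pr <- prune_to(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  re <- if (is.null(pr$root.edge)) 0 else pr$root.edge
  expect_equal(unname(divgrad:::node_depths(pr)[1:2]) + re, c(2, 2))

  expect_equal(sort(prune_to(tr, c("A", "B", "C"))$edge.length),
               sort(tr$edge.length))
  one <- prune_to(tr, "A")
  expect_equal(sum(one$edge.length), 2)
  expect_error(prune_to(tr, c("A", "Z")), "Z")
})

test_that("branch abundances match the hand-worked aggregation", {
  bas <- branch_abundances(worked_tree(), c(A = 0.25, B = 0.25, C = 0.5))
  expect_equal(attr(bas, "T_bar"), 2.0, tolerance = 1e-12)
  expect_equal(sort(paste(bas$length, bas$a)),
               sort(c("1 0.25", "1 0.25", "1 0.5", "2 0.5")))

  # star tree: each tip its own branch, a_i = p_i, T_bar = depth
  star <- read_newick("(A:3,B:3,C:3,D:3);")
  p <- c(A = 0.1, B = 0.2, C = 0.3, D = 0.4)
  bs <- branch_abundances(star, p)
  expect_equal(sort(bs$a), sort(unname(p)))
  expect_equal(attr(bs, "T_bar"), 3)

  # abundance concentrated on one tip of an ultrametric tree
  b1 <- branch_abundances(worked_tree(), c(C = 1))
  expect_equal(attr(b1, "T_bar"), 2)
})

test_that("phylogenetic Hill numbers reproduce hand values and the star identity", {
  bas <- branch_abundances(worked_tree(), c(A = 0.25, B = 0.25, C = 0.5))
  h0 <- hill_phylo(bas, 0)
  expect_equal(h0$total_pd, 5.0, tolerance = 1e-12)
  expect_equal(h0$mean_diversity, 2.5, tolerance = 1e-12)
  h2 <- hill_phylo(bas, 2)
  expect_equal(h2$mean_diversity, 1 / 0.4375, tolerance = 1e-9)
  expect_equal(h2$total_pd, 2 / 0.4375, tolerance = 1e-9)

  # star tree of depth T: mean = taxonomic qD, total = T * qD
  set.seed(7)
  p <- random_abundance(6)
  names(p) <- paste0("t", 1:6)
  star <- read_newick(paste0("(", paste(names(p), ":4", sep = "",
                                        collapse = ","), ");"))
  bs <- branch_abundances(star, p)
  for (q in c(0, 1, 2)) {
    expect_equal(hill_phylo(bs, q)$mean_diversity, hill_taxonomic(p, q),
                 tolerance = 1e-9)
    expect_equal(hill_phylo(bs, q)$total_pd, 4 * hill_taxonomic(p, q),
                 tolerance = 1e-9)
  }
})

test_that("q = 0 total PD equals brute-force Faith PD on random trees", {
  skip_if_not_installed("picante")
  set.seed(8)
  for (i in 1:100) {
    cs <- random_tree_case(50)
    bas <- branch_abundances(cs$tree, cs$p)
    expect_equal(hill_phylo(bas, 0)$total_pd,
                 faith_bruteforce(cs$tree, names(cs$p)), tolerance = 1e-9)
  }
  # independent package cross-check on a handful of cases
  for (i in 1:5) {
    cs <- random_tree_case(30)
    com <- matrix(0, 1, length(cs$tree$tip.label),
                  dimnames = list("p1", cs$tree$tip.label))
    com[1, names(cs$p)] <- 1
    oracle <- picante::pd(com, cs$tree, include.root = TRUE)$PD
    bas <- branch_abundances(cs$tree, cs$p)
    expect_equal(hill_phylo(bas, 0)$total_pd, oracle, tolerance = 1e-9)
  }
})

test_that("joining two equal disjoint ultrametric trees doubles mean diversity", {
  set.seed(9)
  t1 <- ape::rcoal(8)
  t1$tip.label <- paste0("a", 1:8)
  depth <- max(divgrad:::node_depths(t1)[1:8])
  t1$edge.length <- t1$edge.length / depth     # depth 1
  s1 <- sub(";", "", ape::write.tree(t1))
  s2 <- gsub("a", "b", s1)
  joined <- read_newick(paste0("(", s1, ":0,", s2, ":0);"))
  p <- random_abundance(8)
  p1 <- p; names(p1) <- paste0("a", 1:8)
  pj <- c(p / 2, p / 2)
  names(pj) <- c(paste0("a", 1:8), paste0("b", 1:8))
  for (q in c(0, 1, 2)) {
    single <- hill_phylo(branch_abundances(t1, p1), q)$mean_diversity
    double <- hill_phylo(branch_abundances(joined, pj), q)$mean_diversity
    expect_equal(double, 2 * single, tolerance = 1e-9)
  }
})

test_that("pruning is consistent with zero-abundance tips, and qD monotone in q", {
  set.seed(10)
  for (i in 1:25) {
    cs <- random_tree_case(30)
    full <- hill_phylo(branch_abundances(cs$tree, cs$p), sample(c(0, 1, 2), 1))
    pruned_tree <- prune_to(cs$tree, names(cs$p))
    pruned <- hill_phylo(branch_abundances(pruned_tree, cs$p),
                         q <- sample(c(0, 1, 2), 1))
    full_q <- hill_phylo(branch_abundances(cs$tree, cs$p), q)
    expect_equal(pruned$total_pd, full_q$total_pd, tolerance = 1e-9)
    expect_equal(pruned$mean_diversity, full_q$mean_diversity, tolerance = 1e-9)
  }
  qgrid <- seq(0, 3, by = 0.25)
  for (i in 1:20) {
    cs <- random_tree_case(30)
    bas <- branch_abundances(cs$tree, cs$p)
    vals <- vapply(qgrid, function(q) hill_phylo(bas, q)$mean_diversity,
                   numeric(1))
    expect_true(all(diff(vals) <= 1e-9))
    d1 <- hill_phylo(bas, 1)$mean_diversity
    expect_lt(abs(hill_phylo(bas, 1 + 1e-6)$mean_diversity - d1), 1e-4)
  }
})
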