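quartet_matrix <- function() {
  # additive distances on the quartet ((a,b),(c,d)) with internal edge 2
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 2
  m["a", "c"] <- m["c", "a"] <- 5
  m["a", "d"] <- m["d", "a"] <- 6
  m["b", "c"] <- m["c", "b"] <- 5
  m["b", "d"] <- m["d", "b"] <- 6
  m["c", "d"] <- m["d", "c"] <- 3
  m
}

test_that("neighbor joining recovers additive topologies", {
  tr <- nj_tree(quartet_matrix())
  truth <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(rf_error(tr, truth), 0)
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("neighbor joining agrees with a textbook implementation", {
  set.seed(21)
  for (i in 1:5) {
    m <- sample(5:7, 1)
    genomes <- lapply(seq_len(m), function(i) random_genome(15))
    d <- outer(seq_len(m), seq_len(m),
               Vectorize(function(i, j) dcj_distance(genomes[[i]],
                                                     genomes[[j]])))
    # break Q-matrix ties so both implementations face a unique argmin
    jit <- matrix(stats::runif(m * m, 0, 1e-3), m, m)
    d <- d + jit + t(jit)
    diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:m), paste0("t", 1:m))
    expect_true(same_topology(nj_tree(d), oracle_nj_tree(d)))
  }
})

test_that("Robinson-Foulds error implements the published formula", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  expect_equal(rf_error(t1, t1), 0)
  # 5-leaf trees sharing the ab split but differing in the second one
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  expect_equal(rf_error(t1, t2), (1 + 1) / (2 * 3) * 100)
  # trees differing in both internal bipartitions
  t3 <- ape::read.tree(text = "((a,c),(b,d),e);")
  expect_equal(rf_error(t1, t3), (2 + 2) / (2 * 3) * 100)
  expect_error(rf_error(t1, ape::read.tree(text = "((a,b),(c,x),e);")),
               "different leaf")

  set.seed(22)
  for (i in 1:10) {
    m <- sample(4:8, 1)
    labels <- paste0("t", seq_len(m))
    topos <- dcjmedian:::enumerate_topologies(labels)
    a <- topos[[sample.int(length(topos), 1)]]
    b <- topos[[sample.int(length(topos), 1)]]
    expect_equal(rf_error(a, b), rf_error(b, a))
    if (requireNamespace("phangorn", quietly = TRUE)) {
      an <- ape::read.tree(text = dcjmedian:::phylo_to_newick(a))
      bn <- ape::read.tree(text = dcjmedian:::phylo_to_newick(b))
      expect_equal(rf_error(a, b) / 100 * 2 * (m - 2),
                   as.numeric(phangorn::RF.dist(an, bn)))
    }
  }
})

test_that("circular lower bound halves the circular distance sum", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(circular_lower_bound(1:3, d), 0)
  set.seed(23)
  genomes <- lapply(1:3, function(i) random_genome(12))
  inst <- make_instance(genomes[[1]], genomes[[2]], genomes[[3]])
  dm <- matrix(c(0, inst$d12, inst$d13, inst$d12, 0, inst$d23,
                 inst$d13, inst$d23, 0), 3, 3)
  expect_equal(circular_lower_bound(1:3, dm), inst$median_lb)
})

test_that("tree scoring matches the median solver on three leaves", {
  set.seed(24)
  sim <- simulate_triplet(triplet_sim_config(n_genes = 30, r = 2, seed = 4))
  tree <- structure(list(edge = rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
                         tip.label = c("G1", "G2", "G3"), Nnode = 1L),
                    class = "phylo")
  lg <- sim$leaves
  names(lg) <- tree$tip.label
  set.seed(99)
  sc <- score_tree(tree, lg, solver_config(max_generations = 100L))
  set.seed(98)
  med <- solve_median(sim$instance, solver_config(max_generations = 100L))
  expect_equal(sc$score, med$score)

  # identical leaves: zero score everywhere
  id <- identity_genome(20)
  lg0 <- list(a = id, b = id, c = id, d = id)
  tr0 <- dcjmedian:::enumerate_topologies(names(lg0))[[1]]
  expect_equal(score_tree(tr0, lg0)$score, 0L)
  init <- initialize_internal_genomes(tr0, lg0)
  for (v in 5:6) expect_true(genomes_equal(init[[v]], id))
})

test_that("scored trees stay between the circular bound and event count", {
  set.seed(25)
  sim <- simulate_tree_dataset(tree_sim_config(n_leaves = 5, n_genes = 60,
                                               r = 3, seed = 31))
  res <- score_tree(sim$tree, sim$leaf_genomes,
                    solver_config(max_generations = 120L))
  dm <- dcjmedian:::cpp_pairwise_distances(
    lapply(sim$leaf_genomes, `[[`, "nb"))
  dimnames(dm) <- list(names(sim$leaf_genomes), names(sim$leaf_genomes))
  bound <- circular_lower_bound(
    dcjmedian:::tree_circular_order(sim$tree), dm)
  expect_gte(res$score, ceiling(bound))
  expect_lte(res$score, sum(sim$edge_events) * 2L)
})

test_that("search recovers simulated quartets and prunes exactly", {
  set.seed(26)
  sim <- simulate_tree_dataset(tree_sim_config(n_leaves = 4, n_genes = 100,
                                               r = 5, seed = 41))
  res <- search_trees(sim$leaf_genomes,
                      search_config(solver_config(max_generations = 150L),
                                    seed = 7))
  expect_equal(rf_error(res$best_tree, sim$tree), 0)

  # identical leaves: any topology scores zero
  id <- identity_genome(15)
  lg <- list(a = id, b = id, c = id, d = id)
  res0 <- search_trees(lg, search_config(seed = 1))
  expect_equal(res0$best_score, 0L)

  # pruned search equals unpruned exhaustive best score (5 taxa)
  sim5 <- simulate_tree_dataset(tree_sim_config(n_leaves = 5, n_genes = 60,
                                                r = 3, seed = 51))
  res5 <- search_trees(sim5$leaf_genomes,
                       search_config(solver_config(max_generations = 120L),
                                     seed = 13))
  topos <- dcjmedian:::enumerate_topologies(names(sim5$leaf_genomes))
  set.seed(13)
  all_scores <- vapply(topos, function(tr)
    score_tree(tr, sim5$leaf_genomes,
               solver_config(max_generations = 120L))$score, 1L)
  expect_equal(res5$best_score, min(all_scores))
})

test_that("internal nodes match across trees by leaf tripartition", {
  sim <- simulate_tree_dataset(tree_sim_config(n_leaves = 6, n_genes = 40,
                                               r = 2, seed = 61))
  v <- match_internal_node(sim$tree, sim$tree, sim$root_node)
  expect_equal(v, sim$root_node)
})

test_that("newick files round-trip topology and sidecar genomes", {
  p <- withr::local_tempfile()
  tri <- dcjmedian:::enumerate_topologies(c("a", "b", "c"))[[1]]
  write_newick(tri, p)
  expect_equal(n_distinct <- length(read_newick(p)$tip.label), 3L)

  sim <- simulate_tree_dataset(tree_sim_config(n_leaves = 7, n_genes = 25,
                                               r = 1, seed = 71))
  q <- withr::local_tempfile()
  write_newick(sim$tree, q, genomes = sim$node_genomes)
  back <- read_newick(q)
  expect_equal(rf_error(back, sim$tree), 0)
  side <- read_gene_order_file(paste0(q, ".genes"))
  expect_length(side, sim$tree$Nnode)

  bad <- withr::local_tempfile()
  writeLines("((a,b,;", bad)
  expect_error(read_newick(bad), "parse error")
})
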