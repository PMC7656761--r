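worked_pair <- function() {
  list(g1 = genome_from_gene_orders(1:5),
       g2 = genome_from_gene_orders(c(3, -2, -1, -4, 5)))
}

test_that("adjacency graph of the five-gene worked example", {
  f <- worked_pair()
  ag <- build_adjacency_graph(f$g1, f$g2)
  expect_equal(ag$C, 1L)
  expect_equal(ag$I, 2L)
  expect_equal(ag$distance, 3L)
  expect_equal(dcj_distance(f$g1, f$g2), 3L)
})

test_that("identical genomes decompose into 2-cycles and matched telomeres", {
  g <- genome_from_gene_orders(1:7)
  ag <- build_adjacency_graph(g, g)
  expect_equal(ag$C, 6L)
  expect_equal(ag$I, 2L)
  expect_equal(ag$distance, 0L)
  expect_equal(dcj_distance(g, g), 0L)
})

test_that("components partition the extremities of both genomes", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    ag <- build_adjacency_graph(random_genome(n), random_genome(n))
    covered <- sort(unlist(ag$components$extremities))
    expect_identical(covered, seq_len(2L * n))
    expect_equal(sum(ag$components$edges), 2L * n)
  }
})

test_that("distance errors on mismatched gene sets", {
  expect_error(dcj_distance(genome_from_gene_orders(1:3),
                            genome_from_gene_orders(1:4)),
               "different gene sets")
})

test_that("distance is a metric and bounded by n", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    a <- random_genome(n); b <- random_genome(n); c <- random_genome(n)
    dab <- dcj_distance(a, b)
    expect_gte(dab, 0L)
    expect_lte(dab, n)
    expect_equal(dab, dcj_distance(b, a))
    expect_lte(dab, dcj_distance(a, c) + dcj_distance(c, b))
  }
})

test_that("distance agrees with the breadth-first search oracle", {
  id3 <- identity_genome(3)
  for (g in all_linear_genomes(3)) {
    expect_equal(dcj_distance(id3, g), bfs_dcj_distance(id3, g))
  }
  set.seed(5)
  for (i in 1:15) {
    n <- sample(4:5, 1)
    a <- random_linear_genome(n)
    b <- random_linear_genome(n)
    expect_equal(dcj_distance(a, b), bfs_dcj_distance(a, b))
  }
})

test_that("every one-step neighbour moves distance by at most one", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(2:4, 1)
    g <- random_genome(n)
    x <- random_genome(n)
    dg <- dcj_distance(g, x)
    for (h in enumerate_dcj_neighbors(g)) {
      expect_lte(abs(dcj_distance(h, x) - dg), 1L)
    }
  }
})

test_that("apply_dcj performs cuts, joins, and inverts cleanly", {
  g <- genome_from_gene_orders(c(1, 2))
  cut <- dcj_op(list(c(ext_head(1L), ext_tail(2L))),
                list(ext_head(1L), ext_tail(2L)))
  after <- apply_dcj(g, cut)
  expect_setequal(telomere_set(after),
                  c(ext_tail(1L), ext_head(1L), ext_tail(2L), ext_head(2L)))

  join <- dcj_op(list(ext_tail(1L), ext_head(2L)),
                 list(c(ext_tail(1L), ext_head(2L))))
  joined <- apply_dcj(g, join)
  expect_true(ext_head(2L) == joined$nb[ext_tail(1L)])

  expect_error(apply_dcj(after, cut), "not present")

  # an operation followed by its inverse restores the genome
  set.seed(31)
  for (i in 1:10) {
    g <- random_genome(sample(2:5, 1))
    ops <- enumerate_dcj_neighbors(g, as_ops = TRUE)
    op <- ops[[sample.int(length(ops), 1)]]
    inv <- dcj_op(op$products, op$operands)
    expect_true(genomes_equal(apply_dcj(apply_dcj(g, op), inv), g))
  }
})

test_that("optimal steps all decrease the distance by exactly one", {
  f <- worked_pair()
  steps <- optimal_dcj_steps(f$g1, f$g2)
  expect_gt(length(steps), 0L)
  for (op in steps) {
    expect_equal(dcj_distance(apply_dcj(f$g1, op), f$g2), 2L)
  }
  expect_length(optimal_dcj_steps(f$g1, f$g1), 0L)

  set.seed(13)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    a <- random_genome(n); b <- random_genome(n)
    d <- dcj_distance(a, b)
    if (d == 0) next
    for (op in optimal_dcj_steps(a, b)) {
      expect_equal(dcj_distance(apply_dcj(a, op), b), d - 1L)
    }
  }
})

test_that("sampled intermediates satisfy the telescoping identity", {
  f <- worked_pair()
  expect_true(genomes_equal(sample_intermediate(f$g1, f$g2, 0), f$g1))
  end <- sample_intermediate(f$g1, f$g2, 3)
  expect_equal(dcj_distance(end, f$g2), 0L)
  expect_error(sample_intermediate(f$g1, f$g2, 4), "exceeds")

  set.seed(3)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    a <- random_genome(n); b <- random_genome(n)
    d <- dcj_distance(a, b)
    if (d == 0) next
    k <- sample.int(d, 1)
    m <- sample_intermediate(a, b, k)
    expect_equal(dcj_distance(a, m), k)
    expect_equal(dcj_distance(m, b), d - k)
  }
})
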