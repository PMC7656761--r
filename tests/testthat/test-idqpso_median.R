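small_instance <- function(n = 20, r = 2, seed = 1) {
  simulate_triplet(triplet_sim_config(n_genes = n, r = r, seed = seed))
}

test_that("instances carry pairwise distances and the lower bound", {
  g <- genome_from_gene_orders(1:6)
  inst <- make_instance(g, g, g)
  expect_equal(c(inst$d12, inst$d13, inst$d23), c(0L, 0L, 0L))
  expect_equal(inst$median_lb, 0)

  set.seed(2)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    inst <- make_instance(random_genome(n), random_genome(n),
                          random_genome(n))
    expect_equal(inst$median_lb, (inst$d12 + inst$d13 + inst$d23) / 2)
    # every leaf genome's fitness is bounded below by medianLB
    for (leaf in list(inst$g1, inst$g2, inst$g3)) {
      expect_gte(median_fitness(leaf, inst), ceiling(inst$median_lb))
    }
  }
})

test_that("fitness is the summed distance and respects the lower bound", {
  set.seed(3)
  inst <- make_instance(random_genome(10), random_genome(10),
                        random_genome(10))
  expect_equal(median_fitness(inst$g1, inst), inst$d12 + inst$d13)
  g <- genome_from_gene_orders(1:5)
  expect_equal(median_fitness(g, make_instance(g, g, g)), 0L)
  for (i in 1:50) {
    cand <- random_genome(10)
    expect_gte(median_fitness(cand, inst), ceiling(inst$median_lb))
  }
})

test_that("initial pool has exactly 36M entries on sorting paths", {
  set.seed(4)
  sim <- small_instance(n = 15, r = 3)
  inst <- sim$instance
  xs <- initialize_population(inst, solver_config(population = 1L))
  pool <- attr(xs, "pool")
  expect_length(pool, 36L)
  expect_length(xs, 1L)

  xs3 <- initialize_population(inst, solver_config(population = 3L))
  expect_length(attr(xs3, "pool"), 108L)

  # each pool candidate telescopes on at least one ordered leaf pair
  leaves <- list(inst$g1, inst$g2, inst$g3)
  for (cand in pool) {
    ok <- FALSE
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      dij <- dcj_distance(leaves[[i]], leaves[[j]])
      if (dcj_distance(leaves[[i]], cand) +
          dcj_distance(cand, leaves[[j]]) == dij) ok <- TRUE
    }
    expect_true(ok)
  }

  g <- genome_from_gene_orders(1:8)
  degen <- initialize_population(make_instance(g, g, g),
                                 solver_config(population = 2L))
  for (cand in attr(degen, "pool")) expect_true(genomes_equal(cand, g))
})

test_that("cbest is the particle closest to the mean fitness", {
  expect_equal(select_cbest(c(10, 20, 30)), 2L)
  expect_equal(select_cbest(c(7, 7, 7)), 1L)
  set.seed(5)
  for (i in 1:50) {
    f <- sample.int(100, sample(1:12, 1), replace = TRUE)
    idx <- select_cbest(f)
    dist <- abs(f - mean(f))
    expect_equal(dist[idx], min(dist))
    ties <- which(dist == min(dist))
    expect_equal(f[idx], min(f[ties]))
  }
})

test_that("mbest applies the second average over the better half", {
  # second mean of {20, 10} is 15; both candidates at distance 5,
  # tie broken toward the lower fitness
  expect_equal(select_mbest(2L, c(10, 20, 30)), 1L)
  expect_equal(select_mbest(1L, c(5, 20, 30)), 1L)  # B empty -> cbest
  set.seed(6)
  for (i in 1:50) {
    f <- sample.int(100, sample(2:12, 1), replace = TRUE)
    ic <- select_cbest(f)
    im <- select_mbest(ic, f)
    better <- which(f < f[ic])
    if (length(better) == 0L) {
      expect_equal(im, ic)
    } else {
      cand <- c(ic, better)
      m2 <- mean(c(f[ic], f[better]))
      dist <- abs(f[cand] - m2)
      expect_true(im %in% cand)
      expect_equal(abs(f[im] - m2), min(dist))
    }
  }
})

test_that("personal bests improve strictly and gbest never degrades", {
  state <- list(xs = list("a", "b"), fx = c(5L, 9L),
                pbest = NULL, fpbest = NULL)
  inst <- NULL
  state <- update_pbest(state, inst)
  expect_identical(state$pbest, state$xs)   # first generation: assign
  expect_equal(state$fgbest, 5L)

  # equal fitness keeps the incumbent
  state$xs <- list("a2", "b2")
  state$fx <- c(5L, 8L)
  state <- update_pbest(state, inst)
  expect_identical(state$pbest[[1]], "a")
  expect_identical(state$pbest[[2]], "b2")
})

test_that("the local attractor lands a sampled fraction along the path", {
  set.seed(7)
  sim <- small_instance(n = 30, r = 4, seed = 9)
  inst <- sim$instance
  cfg <- solver_config()
  pbest <- inst$g1
  gbest <- inst$g2
  fp <- median_fitness(pbest, inst)
  fg <- median_fitness(gbest, inst)

  expect_true(genomes_equal(update_pid(pbest, fp, gbest, fp + 1L, cfg),
                            pbest))  # guard: gbest not better
  expect_true(genomes_equal(update_pid(pbest, fp, pbest, fp, cfg), pbest))

  d <- dcj_distance(pbest, gbest)
  allowed <- unique(pmin(pmax(floor(cfg$fractions * d + 0.5), 1L), d))
  for (i in 1:20) {
    pid <- update_pid(pbest, 100L, gbest, 1L, cfg)
    expect_true(dcj_distance(pbest, pid) %in% allowed)
  }
})

test_that("the position update obeys its guards", {
  set.seed(8)
  sim <- small_instance(n = 25, r = 3, seed = 2)
  inst <- sim$instance
  x <- inst$g1
  # x = mbest = pid: nothing can move
  out <- update_xid(x, x, x, inst)
  expect_true(genomes_equal(out, x))
  # both guards blocked by worse fitness
  worse <- inst$g2
  if (median_fitness(worse, inst) >= median_fitness(x, inst)) {
    expect_true(genomes_equal(update_xid(x, worse, worse, inst), x))
  }
})

test_that("solve handles degenerate instances and leaf-attained bounds", {
  g <- genome_from_gene_orders(1:10)
  res <- solve_median(make_instance(g, g, g), solver_config(seed = 1))
  expect_equal(res$score, 0L)
  expect_equal(res$generations, 1L)

  set.seed(9)
  g1 <- random_genome(12)
  g2 <- random_genome(12)
  inst <- make_instance(g1, g2, g2)
  res <- solve_median(inst, solver_config(seed = 2))
  expect_equal(res$score, inst$d12)  # median = g2 attains medianLB
})

test_that("solve is seed-deterministic with a non-increasing history", {
  sim <- small_instance(n = 30, r = 5, seed = 12)
  cfg <- solver_config(population = 8L, max_generations = 40L, seed = 99L)
  r1 <- solve_median(sim$instance, cfg)
  r2 <- solve_median(sim$instance, cfg)
  expect_identical(r1$history, r2$history)
  expect_true(genomes_equal(r1$median, r2$median))
  expect_true(all(diff(r1$history) <= 0))
  expect_gte(r1$score, ceiling(sim$instance$median_lb))
  expect_equal(r1$score, median_fitness(r1$median, sim$instance))
})

test_that("solve attains the exhaustive median optimum on tiny instances", {
  set.seed(10)
  candidates <- all_genomes(3)
  for (i in 1:10) {
    inst <- make_instance(random_linear_genome(3), random_linear_genome(3),
                          random_linear_genome(3))
    best <- brute_force_median_score(inst, candidates)
    res <- solve_median(inst, solver_config(population = 6L,
                                            max_generations = 60L,
                                            cap_rule = "max"))
    expect_equal(res$score, best)
  }
})

test_that("median results serialize to JSON plus a gene-order file", {
  sim <- small_instance(n = 15, r = 2, seed = 3)
  res <- solve_median(sim$instance, solver_config(seed = 5))
  stem <- file.path(withr::local_tempdir(), "median")
  write_median_result(res, sim$instance, stem)
  rec <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(rec$score, res$score)
  back <- read_gene_order_file(paste0(stem, ".genes"))
  expect_true(genomes_equal(back[[1]], res$median))
})
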