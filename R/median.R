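# Discrete quantum-behaved particle-swarm solver for the DCJ median
# problem: find a genome minimizing the summed DCJ distance to three
# given genomes.  The continuous QPSO position update degenerates in
# discrete gene-order space (mu fixed at 0.5, beta*ln(1/u) fixed at 1) to
# sorting walks along optimal DCJ paths: particles move by sampling
# intermediates toward the mean-best and local-attractor genomes.

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Build a DCJ median problem instance
#'
#' @param g1,g2,g3 `dcj_genome`s over the same gene set.
#' @return a `dcj_median_instance`: the genomes, pairwise distances
#'   `d12`, `d13`, `d23`, and the circular-ordering lower bound
#'   `median_lb = (d12 + d13 + d23)/2` (a half-integer); any candidate
#'   median's score is at least `ceiling(median_lb)`.
#' @export
make_instance <- function(g1, g2, g3) {
  stopifnot(is_genome(g1), is_genome(g2), is_genome(g3))
  check_same_genes(g1, g2); check_same_genes(g1, g3)
  d12 <- cpp_dcj_distance(g1$nb, g2$nb)
  d13 <- cpp_dcj_distance(g1$nb, g3$nb)
  d23 <- cpp_dcj_distance(g2$nb, g3$nb)
  structure(list(g1 = g1, g2 = g2, g3 = g3,
                 d12 = d12, d13 = d13, d23 = d23,
                 median_lb = (d12 + d13 + d23) / 2),
            class = "dcj_median_instance")
}

#' @export
print.dcj_median_instance <- function(x, ...) {
  cat("<dcj_median_instance: n =", x$g1$n, ", d12 =", x$d12, ", d13 =",
      x$d13, ", d23 =", x$d23, ", medianLB =", x$median_lb, ">\n")
  invisible(x)
}

#' Median score (fitness) of a candidate median genome
#'
#' The sum of the three DCJ distances from `gm` to the instance genomes.
#'
#' @param gm candidate `dcj_genome`.
#' @param inst a [make_instance()] result.
#' @return non-negative integer, at least `ceiling(inst$median_lb)`.
#' @export
median_fitness <- function(gm, inst) {
  stopifnot(is_genome(gm), inherits(inst, "dcj_median_instance"))
  check_same_genes(gm, inst$g1)
  cpp_fitness3(gm$nb, inst$g1$nb, inst$g2$nb, inst$g3$nb)
}

#' Solver configuration
#'
#' @param population swarm size M.
#' @param max_generations hard generation cap.
#' @param fractions sorting-path fractions used by initialization and the
#'   local-attractor update.
#' @param mu attractor weight; fixed at 0.5 in the discrete solver (both
#'   the personal and global best contribute equally) and kept for
#'   documentation.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param lb_stop stop as soon as the best score reaches
#'   `ceiling(median_lb)`.
#' @param iter_cap_factor the effective generation cap is
#'   `min(max_generations, ceiling(iter_cap_factor * median_lb))` under
#'   `cap_rule = "min"` (the default), or the max of the two.
#' @param cap_rule `"min"` or `"max"`; see above.
#' @param escape the local-optimum escape move (a short sorting walk from
#'   each particle's position toward a uniformly chosen instance genome):
#'   `"always"` applies it every generation after the two-stage position
#'   update (the default; without it the strict-improvement guards freeze
#'   the swarm once fitness values tie), `"stagnation"` applies it only
#'   after `stagnation_generations` without improvement, `"none"`
#'   disables it.
#' @param escape_geom_p success probability of the geometric law for the
#'   escape walk length (`k = 1 + rgeom(escape_geom_p)`); near 1 means
#'   almost always a single optimal step.
#' @param stagnation_generations stagnation window for
#'   `escape = "stagnation"`.
#' @return a `dcj_solver_config` list.
#' @export
solver_config <- function(population = 20L, max_generations = 2150L,
                          fractions = (1:6) / 10, mu = 0.5, seed = NULL,
                          lb_stop = TRUE, iter_cap_factor = 1.5,
                          cap_rule = c("min", "max"),
                          escape = c("always", "stagnation", "none"),
                          escape_geom_p = 0.75,
                          stagnation_generations = 50L) {
  stopifnot(population >= 1L, max_generations >= 1L,
            all(fractions > 0), all(fractions <= 1),
            escape_geom_p > 0, escape_geom_p <= 1)
  structure(list(population = as.integer(population),
                 max_generations = as.integer(max_generations),
                 fractions = fractions, mu = mu, seed = seed,
                 lb_stop = isTRUE(lb_stop),
                 iter_cap_factor = iter_cap_factor,
                 cap_rule = match.arg(cap_rule),
                 escape = match.arg(escape),
                 escape_geom_p = escape_geom_p,
                 stagnation_generations = as.integer(stagnation_generations)),
            class = "dcj_solver_config")
}

#' Initialize the particle positions from the 36M sorting-path pool
#'
#' For each of M repetitions, for each ordered pair of distinct instance
#' genomes (6 pairs) and each fraction f (6 values), a candidate is
#' sampled `round(f * d)` optimal steps along the sorting path, giving a
#' pool of 36M candidates; each particle then draws its initial position
#' uniformly (with replacement) from the pool.
#'
#' @param inst a [make_instance()] result.
#' @param cfg a [solver_config()].
#' @return list of M `dcj_genome`s with the full pool attached as
#'   attribute `"pool"`.
#' @export
initialize_population <- function(inst, cfg = solver_config()) {
  stopifnot(inherits(inst, "dcj_median_instance"))
  leaves <- list(inst$g1, inst$g2, inst$g3)
  dmat <- matrix(c(0, inst$d12, inst$d13,
                   inst$d12, 0, inst$d23,
                   inst$d13, inst$d23, 0), 3, 3)
  pairs <- list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  pool <- vector("list", 36L * cfg$population)
  idx <- 0L
  for (rep in seq_len(cfg$population)) {
    for (pr in pairs) {
      d <- dmat[pr[1], pr[2]]
      for (f in cfg$fractions) {
        k <- min(max(round_half_up(f * d), 0L), d)
        idx <- idx + 1L
        pool[[idx]] <- sample_intermediate(leaves[[pr[1]]],
                                           leaves[[pr[2]]], k)
      }
    }
  }
  draws <- sample.int(length(pool), cfg$population, replace = TRUE)
  structure(pool[draws], pool = pool)
}

#' Select the first-average candidate (cbest)
#'
#' The particle whose fitness is closest to the mean fitness of the whole
#' population, with distance measured as `|f_i - mean|`.  Ties go to the
#' lower fitness, then the lower index.
#'
#' @param fitness_values integer vector of personal-best fitness values.
#' @return particle index.
#' @export
select_cbest <- function(fitness_values) {
  stopifnot(length(fitness_values) >= 1L)
  m <- mean(fitness_values)
  order(abs(fitness_values - m), fitness_values,
        seq_along(fitness_values))[1L]
}

#' Select the mean-best particle (mbest) by the second average
#'
#' Let B be the particles with fitness strictly better (lower) than the
#' cbest fitness; the second mean averages the cbest fitness with those of
#' B, and mbest is the member of `{cbest} U B` closest to it (ties toward
#' lower fitness, then lower index).  When B is empty, mbest is cbest.
#'
#' @param cbest_index index returned by [select_cbest()].
#' @param fitness_values integer vector of personal-best fitness values.
#' @return particle index.
#' @export
select_mbest <- function(cbest_index, fitness_values) {
  fc <- fitness_values[cbest_index]
  better <- which(fitness_values < fc)
  if (length(better) == 0L) return(cbest_index)
  cand <- c(cbest_index, better)
  m2 <- mean(c(fc, fitness_values[better]))
  fv <- fitness_values[cand]
  cand[order(abs(fv - m2), fv, cand)][1L]
}

#' Update the local attractor (P_id) of one particle
#'
#' When the global best has a strictly better score than the particle's
#' personal best, the attractor is sampled on the sorting path from the
#' personal best toward the global best, `round(f * d)` steps away with f
#' drawn uniformly from `cfg$fractions` (clamped to `[1, d]`); otherwise
#' the personal best is kept.
#'
#' @param pbest,gbest `dcj_genome`s (personal and global best).
#' @param fpbest,fgbest their fitness values.
#' @param cfg a [solver_config()].
#' @return a `dcj_genome`.
#' @export
update_pid <- function(pbest, fpbest, gbest, fgbest, cfg = solver_config()) {
  if (fgbest >= fpbest) return(pbest)
  d <- dcj_distance(pbest, gbest)
  if (d == 0L) return(pbest)
  f <- cfg$fractions[[sample.int(length(cfg$fractions), 1L)]]
  k <- min(max(round_half_up(f * d), 1L), d)
  sample_intermediate(pbest, gbest, k)
}

#' Update the position (X_id) of one particle
#'
#' Two-stage sorting walk: if the mean-best genome has a strictly better
#' score than the particle's position, the position moves a uniformly
#' random number of optimal steps (1..d) toward it; the result then moves
#' toward the local attractor under the same rule.
#'
#' @param x current position (`dcj_genome`).
#' @param mbest mean-best genome.
#' @param pid local attractor genome.
#' @param inst a [make_instance()] result.
#' @param fx,fmbest,fpid optional precomputed fitness values.
#' @return the new position (`dcj_genome`).
#' @export
update_xid <- function(x, mbest, pid, inst, fx = NULL, fmbest = NULL,
                       fpid = NULL) {
  if (is.null(fx)) fx <- median_fitness(x, inst)
  if (is.null(fmbest)) fmbest <- median_fitness(mbest, inst)
  xp <- x
  fxp <- fx
  if (fmbest < fx) {
    d <- dcj_distance(x, mbest)
    if (d > 0L) {
      xp <- sample_intermediate(x, mbest, sample.int(d, 1L))
      fxp <- median_fitness(xp, inst)
    }
  }
  if (is.null(fpid)) fpid <- median_fitness(pid, inst)
  if (fpid < fxp) {
    d <- dcj_distance(xp, pid)
    if (d > 0L) xp <- sample_intermediate(xp, pid, sample.int(d, 1L))
  }
  xp
}

#' Refresh personal bests and the global best of a swarm state
#'
#' Per-particle, the personal best is replaced by the current position
#' only on strict fitness improvement; the global best is the
#' lowest-fitness personal best (ties to the lower index), so its fitness
#' is non-increasing across generations.
#'
#' @param state a swarm state as built by [solve_median()] internals:
#'   list with `xs`, `fx`, `pbest`, `fpbest`.
#' @param inst a [make_instance()] result.
#' @return the updated state with `gbest`/`fgbest` refreshed.
#' @export
update_pbest <- function(state, inst) {
  if (is.null(state$pbest)) {
    state$pbest <- state$xs
    state$fpbest <- state$fx
  } else {
    imp <- state$fx < state$fpbest
    state$pbest[imp] <- state$xs[imp]
    state$fpbest[imp] <- state$fx[imp]
  }
  ib <- which.min(state$fpbest)
  state$gbest <- state$pbest[[ib]]
  state$fgbest <- state$fpbest[ib]
  state
}

#' Solve a DCJ median problem with the discrete swarm
#'
#' Runs the full solver: 36M sorting-path initialization, per-generation
#' personal-best / mean-best (two fitness averages) / global-best updates,
#' local-attractor sampling, the two-stage position walk, and the
#' leafward escape probe (see [solver_config()]).  The search stops when
#' the best score reaches `ceiling(median_lb)` (if `lb_stop`), or at the
#' effective generation cap.
#'
#' @param inst a [make_instance()] result.
#' @param cfg a [solver_config()].
#' @return a `dcj_median_result`: `median` (genome), `score`,
#'   `generations`, `history` (best score per generation, non-increasing),
#'   `median_lb`, and the configuration.
#' @examples
#' set.seed(1)
#' leaves <- simulate_triplet(triplet_sim_config(n_genes = 30, r = 3))
#' res <- solve_median(leaves$instance, solver_config(seed = 1))
#' res$score >= ceiling(leaves$instance$median_lb)
#' @export
solve_median <- function(inst, cfg = solver_config()) {
  stopifnot(inherits(inst, "dcj_median_instance"),
            inherits(cfg, "dcj_solver_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lb <- inst$median_lb
  lb_int <- as.integer(ceiling(lb))
  cap <- if (cfg$cap_rule == "min") {
    min(cfg$max_generations, as.integer(ceiling(cfg$iter_cap_factor * lb)))
  } else {
    max(cfg$max_generations, as.integer(ceiling(cfg$iter_cap_factor * lb)))
  }
  cap <- max(1L, cap)

  xs <- initialize_population(inst, cfg)
  attr(xs, "pool") <- NULL
  fit <- function(g) cpp_fitness3(g$nb, inst$g1$nb, inst$g2$nb, inst$g3$nb)
  state <- list(xs = xs, fx = vapply(xs, fit, 1L),
                pbest = NULL, fpbest = NULL)
  state <- update_pbest(state, inst)
  history <- state$fgbest
  t <- 1L
  stagnant <- 0L
  leaves <- list(inst$g1, inst$g2, inst$g3)
  escape_one <- function(i) {
    leaf <- leaves[[sample.int(3L, 1L)]]
    d <- dcj_distance(state$xs[[i]], leaf)
    if (d > 0L) {
      k <- min(d, 1L + stats::rgeom(1L, cfg$escape_geom_p))
      state$xs[[i]] <<- sample_intermediate(state$xs[[i]], leaf, k)
      state$fx[i] <<- fit(state$xs[[i]])
    }
  }

  while (t < cap && !(cfg$lb_stop && state$fgbest <= lb_int)) {
    ic <- select_cbest(state$fpbest)
    im <- select_mbest(ic, state$fpbest)
    mbest <- state$pbest[[im]]
    fmbest <- state$fpbest[im]
    for (i in seq_len(cfg$population)) {
      pid <- update_pid(state$pbest[[i]], state$fpbest[i],
                        state$gbest, state$fgbest, cfg)
      state$xs[[i]] <- update_xid(state$xs[[i]], mbest, pid, inst,
                                  fx = state$fx[i], fmbest = fmbest)
      state$fx[i] <- fit(state$xs[[i]])
      if (cfg$escape == "always") escape_one(i)
    }
    prev <- state$fgbest
    state <- update_pbest(state, inst)
    t <- t + 1L
    history <- c(history, state$fgbest)
    stagnant <- if (state$fgbest < prev) 0L else stagnant + 1L
    if (cfg$escape == "stagnation" &&
        stagnant >= cfg$stagnation_generations) {
      for (i in seq_len(cfg$population)) escape_one(i)
      stagnant <- 0L
    }
  }
  structure(list(median = state$gbest, score = state$fgbest,
                 generations = t, history = history,
                 median_lb = lb, config = cfg),
            class = "dcj_median_result")
}

#' @export
print.dcj_median_result <- function(x, ...) {
  cat("<dcj_median_result: score =", x$score, ", medianLB =", x$median_lb,
      ", generations =", x$generations, ">\n")
  invisible(x)
}

#' Serialize a median result
#'
#' Writes `<stem>.json` (instance digest, configuration, score, history,
#' and median gene order) and `<stem>.genes` (the median genome in
#' gene-order format).
#'
#' @param res a [solve_median()] result.
#' @param inst the instance it was solved on.
#' @param stem output path stem.
#' @return the JSON path, invisibly.
#' @export
write_median_result <- function(res, inst, stem) {
  stopifnot(inherits(res, "dcj_median_result"))
  gpath <- paste0(stem, ".genes")
  write_gene_order_file(list(median = res$median), gpath)
  rec <- list(
    instance = list(n = inst$g1$n, d12 = inst$d12, d13 = inst$d13,
                    d23 = inst$d23, median_lb = inst$median_lb),
    config = unclass(res$config)[c("population", "max_generations",
                                   "fractions", "mu", "lb_stop",
                                   "iter_cap_factor", "cap_rule")],
    seed = res$config$seed,
    score = res$score,
    generations = res$generations,
    history = res$history,
    median_gene_order = format(res$median)
  )
  jpath <- paste0(stem, ".json")
  jsonlite::write_json(rec, jpath, auto_unbox = TRUE, digits = NA)
  invisible(jpath)
}
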