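# Seeded rearrangement simulators: random inversions/transpositions on
# signed gene orders, median triplets (identity ancestor, fixed or
# Poisson event counts per edge), and random binary trees with genomes
# populated outward from an identity root.

#' Identity genome
#'
#' A single linear chromosome `(1, 2, ..., n)`.
#'
#' @param n number of genes (>= 1).
#' @return a `dcj_genome`.
#' @export
identity_genome <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  genome_from_gene_orders(seq_len(n))
}

# -- event primitives on signed vectors (single chromosome) ------------

invert_segment <- function(v, i, j) {
  v[i:j] <- -rev(v[i:j])
  v
}

transpose_segment <- function(v, i, j, p) {
  # move segment [i, j] so it follows position p (p outside [i-1, j])
  seg <- v[i:j]
  rest <- v[-(i:j)]
  at <- if (p < i) p else p - (j - i + 1L)
  append(rest, seg, after = at)
}

sample_inversion_vec <- function(v) {
  k <- length(v)
  i <- sample.int(k, 1L)
  j <- sample.int(k, 1L)
  invert_segment(v, min(i, j), max(i, j))
}

sample_transposition_vec <- function(v) {
  k <- length(v)
  if (k < 3L) stop("transposition needs a chromosome with >= 3 genes")
  repeat {
    i <- sample.int(k, 1L)
    j <- sample.int(k, 1L)
    if (j < i) { tmp <- i; i <- j; j <- tmp }
    if (j - i + 1L >= k) next       # segment must move within the chromosome
    gaps <- c(if (i >= 2L) 0:(i - 2L), if (j < k) (j + 1L):k)
    if (length(gaps) == 0L) next
    p <- gaps[sample.int(length(gaps), 1L)]
    return(transpose_segment(v, i, j, p))
  }
}

apply_events_vec <- function(v, count, inversion_fraction) {
  for (e in seq_len(count)) {
    if (inversion_fraction >= 1 || stats::runif(1) < inversion_fraction) {
      v <- sample_inversion_vec(v)
    } else {
      v <- sample_transposition_vec(v)
    }
  }
  v
}

# -- genome-level event operations -------------------------------------

pick_segment_chromosome <- function(chrs, min_len = 1L) {
  lens <- vapply(chrs, function(ch) length(ch$genes), 1L)
  ok <- which(lens >= min_len)
  if (length(ok) == 0L) return(NULL)
  w <- lens[ok] * (lens[ok] + 1L) / 2
  ok[sample.int(length(ok), 1L, prob = w)]
}

#' Random inversion
#'
#' Reverses (with sign flip) a uniformly chosen chromosome-internal
#' segment.  An inversion is a single DCJ operation, so the distance to
#' the input is at most 1.
#'
#' @param g a `dcj_genome`.
#' @return a new `dcj_genome`.
#' @export
random_inversion <- function(g) {
  stopifnot(is_genome(g))
  chrs <- gene_orders_from_genome(g)
  ci <- pick_segment_chromosome(chrs)
  chrs[[ci]]$genes <- sample_inversion_vec(chrs[[ci]]$genes)
  genome_from_gene_orders(chrs, name = g$name)
}

#' Random transposition
#'
#' Moves a uniformly chosen segment to a uniformly chosen non-overlapping
#' position within the same chromosome (a transposition costs at most 2
#' DCJ operations).
#'
#' @param g a `dcj_genome` with at least one chromosome of >= 3 genes.
#' @return a new `dcj_genome`.
#' @export
random_transposition <- function(g) {
  stopifnot(is_genome(g))
  chrs <- gene_orders_from_genome(g)
  ci <- pick_segment_chromosome(chrs, min_len = 3L)
  if (is.null(ci)) stop("no chromosome with >= 3 genes")
  chrs[[ci]]$genes <- sample_transposition_vec(chrs[[ci]]$genes)
  genome_from_gene_orders(chrs, name = g$name)
}

#' Median-triplet simulation configuration
#'
#' @param n_genes genes per genome (single linear chromosome).
#' @param r events per edge: the exact count under `count_law = "fixed"`
#'   (the default reading of "average events per edge"), or the Poisson
#'   mean under `"poisson"`.
#' @param inversion_fraction probability that an event is an inversion
#'   (the remainder are transpositions).
#' @param count_law `"fixed"` or `"poisson"`.
#' @param seed optional integer seed.
#' @return a `dcj_triplet_sim_config`.
#' @export
triplet_sim_config <- function(n_genes = 1000L, r = 100L,
                               inversion_fraction = 1,
                               count_law = c("fixed", "poisson"),
                               seed = NULL) {
  stopifnot(n_genes >= 2L, r >= 0, inversion_fraction >= 0,
            inversion_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes), r = r,
                 inversion_fraction = inversion_fraction,
                 count_law = match.arg(count_law), seed = seed),
            class = "dcj_triplet_sim_config")
}

#' Simulate a median triplet
#'
#' The ancestor is the identity genome; each of the three leaves is
#' produced by applying events independently along its own edge.
#'
#' @param cfg a [triplet_sim_config()].
#' @return list with `instance` (a [make_instance()] over the leaves),
#'   `leaves` (list of 3 genomes), and `true_ancestor`.
#' @export
simulate_triplet <- function(cfg = triplet_sim_config()) {
  stopifnot(inherits(cfg, "dcj_triplet_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  anc <- seq_len(cfg$n_genes)
  leaves <- lapply(1:3, function(i) {
    count <- if (cfg$count_law == "fixed") round_half_up(cfg$r)
             else stats::rpois(1L, cfg$r)
    v <- apply_events_vec(anc, count, cfg$inversion_fraction)
    genome_from_gene_orders(v, name = paste0("G", i))
  })
  list(instance = make_instance(leaves[[1]], leaves[[2]], leaves[[3]]),
       leaves = leaves,
       true_ancestor = genome_from_gene_orders(anc, name = "ancestor"))
}

#' Tree simulation configuration
#'
#' @param n_leaves number of leaves (>= 3).
#' @param n_genes genes per genome.
#' @param r expected events per edge; the realized per-edge count is
#'   `round(uniform(0.1 r, 1.9 r))`.
#' @param inversion_fraction probability an event is an inversion (1 for
#'   inversion-only, 0.9 for the 90/10 inversion/transposition mix).
#' @param seed optional integer seed.
#' @return a `dcj_tree_sim_config`.
#' @export
tree_sim_config <- function(n_leaves = 12L, n_genes = 1000L, r = 20,
                            inversion_fraction = 1, seed = NULL) {
  stopifnot(n_leaves >= 3L, n_genes >= 2L, r >= 0,
            inversion_fraction >= 0, inversion_fraction <= 1)
  structure(list(n_leaves = as.integer(n_leaves),
                 n_genes = as.integer(n_genes), r = r,
                 inversion_fraction = inversion_fraction, seed = seed),
            class = "dcj_tree_sim_config")
}

# uniform unrooted binary topology by sequential random leaf attachment;
# returns an ape "phylo" object with tips t1..tk
random_unrooted_topology <- function(n_leaves) {
  labels <- paste0("t", seq_len(n_leaves))
  # adjacency list over node ids; start from the 3-leaf star
  nxt <- n_leaves + 1L            # internal node ids from n_leaves+1
  edges <- rbind(c(nxt, 1L), c(nxt, 2L), c(nxt, 3L))
  for (leaf in seq(4L, length.out = max(0L, n_leaves - 3L))) {
    ei <- sample.int(nrow(edges), 1L)
    u <- edges[ei, 1L]; v <- edges[ei, 2L]
    nxt <- nxt + 1L
    edges <- edges[-ei, , drop = FALSE]
    edges <- rbind(edges, c(u, nxt), c(nxt, v), c(nxt, leaf))
  }
  structure(list(edge = edges, tip.label = labels,
                 Nnode = n_leaves - 2L),
            class = "phylo")
}

#' Simulate genomes along a random binary tree
#'
#' Draws a uniform unrooted binary topology, picks one internal node as
#' the root, assigns it the identity genome, and populates every other
#' node outward: each edge receives `round(uniform(0.1 r, 1.9 r))` events
#' drawn per the inversion/transposition mix.  All internal truth is
#' retained for evaluation.
#'
#' @param cfg a [tree_sim_config()].
#' @return list with `tree` (ape `phylo`, unrooted), `leaf_genomes`
#'   (named list), `node_genomes` (list indexed by node id),
#'   `root_node` (internal node id carrying the identity genome),
#'   `root_genome`, and `edge_events` (events drawn per edge).
#' @export
simulate_tree_dataset <- function(cfg = tree_sim_config()) {
  stopifnot(inherits(cfg, "dcj_tree_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- random_unrooted_topology(cfg$n_leaves)
  n_nodes <- cfg$n_leaves + tree$Nnode
  root <- cfg$n_leaves + sample.int(tree$Nnode, 1L)
  # undirected adjacency over nodes
  nbrs <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    nbrs[[u]] <- c(nbrs[[u]], v)
    nbrs[[v]] <- c(nbrs[[v]], u)
  }
  orders <- vector("list", n_nodes)
  orders[[root]] <- seq_len(cfg$n_genes)
  edge_events <- integer(nrow(tree$edge))
  queue <- root
  visited <- logical(n_nodes)
  visited[root] <- TRUE
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in nbrs[[u]]) {
      if (visited[v]) next
      visited[v] <- TRUE
      count <- round_half_up(stats::runif(1L, 0.1 * cfg$r, 1.9 * cfg$r))
      ei <- which((tree$edge[, 1L] == u & tree$edge[, 2L] == v) |
                  (tree$edge[, 1L] == v & tree$edge[, 2L] == u))
      edge_events[ei] <- count
      orders[[v]] <- apply_events_vec(orders[[u]], count,
                                      cfg$inversion_fraction)
      queue <- c(queue, v)
    }
  }
  genomes <- lapply(seq_len(n_nodes), function(i) {
    nm <- if (i <= cfg$n_leaves) tree$tip.label[i] else paste0("N", i)
    genome_from_gene_orders(orders[[i]], name = nm)
  })
  leaf_genomes <- genomes[seq_len(cfg$n_leaves)]
  names(leaf_genomes) <- tree$tip.label
  list(tree = tree, leaf_genomes = leaf_genomes, node_genomes = genomes,
       root_node = root, root_genome = genomes[[root]],
       edge_events = edge_events)
}
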