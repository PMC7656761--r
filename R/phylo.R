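# Gene-order phylogeny layer: neighbor-joining seed tree, iterative
# (GRAPPA-style) tree scoring with the swarm median solver, the
# circular-ordering lower bound, bounded tree search, Robinson-Foulds
# error, and Newick I/O.
#
# Trees are "phylo"-structured lists (edge matrix, tip.label, Nnode) as
# used by ape; all traversal here works from the edge matrix directly, so
# trees built by this package or parsed by ape are equally acceptable.

n_tips <- function(tree) length(tree$tip.label)

tree_adjacency <- function(tree) {
  n <- n_tips(tree) + tree$Nnode
  nbrs <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    nbrs[[u]] <- c(nbrs[[u]], v)
    nbrs[[v]] <- c(nbrs[[v]], u)
  }
  nbrs
}

# tip label sets hanging below each node when the tree is rooted at `root`
descendant_tips <- function(tree, root = n_tips(tree) + 1L) {
  nbrs <- tree_adjacency(tree)
  nt <- n_tips(tree)
  n <- nt + tree$Nnode
  parent <- integer(n)
  order <- integer(0)
  queue <- root
  parent[root] <- -1L
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    order <- c(order, u)
    for (v in nbrs[[u]]) {
      if (v != parent[u]) { parent[v] <- u; queue <- c(queue, v) }
    }
  }
  tips <- vector("list", n)
  for (u in rev(order)) {
    if (u <= nt) tips[[u]] <- tree$tip.label[u]
    else {
      kids <- nbrs[[u]][nbrs[[u]] != parent[u]]
      tips[[u]] <- sort(unlist(tips[kids]))
    }
  }
  list(tips = tips, parent = parent, preorder = order)
}

# canonical keys of the non-trivial bipartitions of an unrooted tree
tree_bipartitions <- function(tree) {
  nt <- n_tips(tree)
  if (nt < 4L) return(character(0))
  dt <- descendant_tips(tree)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1L]
  keys <- character(0)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    if (u <= nt || v <= nt) next            # pendant edge: trivial split
    child <- if (dt$parent[v] == u) v else u
    side <- dt$tips[[child]]
    if (anchor %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2L || length(side) > nt - 2L) next
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds error rate between two unrooted trees
#'
#' `RF = (FP + FN) / (2 (n - 2)) * 100`, where FP counts internal
#' bipartitions of `inferred` absent from `truth` and FN the converse.
#'
#' @param inferred,truth trees (phylo-structured) over identical leaf
#'   label sets, with at least 4 leaves.
#' @return percentage in `[0, 100]`.
#' @export
rf_error <- function(inferred, truth) {
  if (!setequal(inferred$tip.label, truth$tip.label))
    stop("trees have different leaf label sets")
  n <- n_tips(inferred)
  if (n < 4L) stop("Robinson-Foulds error needs >= 4 leaves")
  b1 <- tree_bipartitions(inferred)
  b2 <- tree_bipartitions(truth)
  fp <- length(setdiff(b1, b2))
  fn <- length(setdiff(b2, b1))
  (fp + fn) / (2 * (n - 2)) * 100
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}), returned unrooted; used to
#' seed the tree search with a best-so-far score.
#'
#' @param dist symmetric zero-diagonal matrix with row/column names, or a
#'   `dist` object; at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(stats::as.dist(d))
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr
}

#' Circular-ordering lower bound
#'
#' For genomes arranged in a circular order `o`, any tree whose planar
#' embedding induces `o` has score `w` with `2 w >= sum of consecutive
#' pairwise distances`, so half the circular sum lower-bounds the score.
#'
#' @param order circular ordering of the taxa: integer indices or labels
#'   into `dist`.
#' @param dist symmetric pairwise DCJ distance matrix.
#' @return half-integer lower bound.
#' @export
circular_lower_bound <- function(order, dist) {
  d <- as.matrix(dist)
  if (is.character(order)) order <- match(order, rownames(d))
  stopifnot(!anyNA(order), length(order) == nrow(d))
  nxt <- c(order[-1L], order[1L])
  sum(d[cbind(order, nxt)]) / 2
}

# leaf order of a planar embedding: tips in DFS visit order
tree_circular_order <- function(tree) {
  dt <- descendant_tips(tree)
  nbrs <- tree_adjacency(tree)
  nt <- n_tips(tree)
  out <- integer(0)
  visit <- function(u, parent) {
    if (u <= nt) { out <<- c(out, u); return(invisible()) }
    for (v in nbrs[[u]]) if (v != parent) visit(v, u)
  }
  visit(nt + 1L, -1L)
  tree$tip.label[out]
}

# breadth-first edge-count distances from one node to all nodes
node_path_lengths <- function(nbrs, from) {
  n <- length(nbrs)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in nbrs[[u]]) {
      if (is.na(dist[v])) { dist[v] <- dist[u] + 1L; queue <- c(queue, v) }
    }
  }
  dist
}

#' Seed internal genomes from each node's three nearest leaves
#'
#' For every internal node, the three topologically nearest leaves (ties
#' broken lexicographically by label) define a median instance whose
#' solution initializes the node genome.
#'
#' @param tree phylo-structured tree (unrooted binary).
#' @param leaf_genomes named list of `dcj_genome`s covering
#'   `tree$tip.label`.
#' @param solver a [solver_config()] for the median solves.
#' @return list mapping internal node id to `dcj_genome`.
#' @export
initialize_internal_genomes <- function(tree, leaf_genomes,
                                        solver = solver_config()) {
  nt <- n_tips(tree)
  stopifnot(all(tree$tip.label %in% names(leaf_genomes)))
  nbrs <- tree_adjacency(tree)
  solver$seed <- NULL   # seeding is the caller's responsibility
  genomes <- vector("list", nt + tree$Nnode)
  for (v in (nt + 1L):(nt + tree$Nnode)) {
    pl <- node_path_lengths(nbrs, v)[seq_len(nt)]
    ord <- order(pl, tree$tip.label)
    picks <- tree$tip.label[ord[1:3]]
    inst <- make_instance(leaf_genomes[[picks[1]]], leaf_genomes[[picks[2]]],
                          leaf_genomes[[picks[3]]])
    genomes[[v]] <- solve_median(inst, solver)$median
  }
  genomes
}

#' Score a tree by iterative median refinement
#'
#' GRAPPA-style scoring: internal genomes are seeded from each node's
#' three nearest leaves, then nodes are revisited in depth-first
#' post-order, re-solving the median of each node's three current
#' neighbour genomes and keeping strictly better assignments, until a
#' full sweep makes no change.  The score is the sum of DCJ edge lengths;
#' it never increases across sweeps.
#'
#' @param tree phylo-structured unrooted binary tree.
#' @param leaf_genomes named list of `dcj_genome`s covering the tips.
#' @param solver a [solver_config()] for the median solves (population 20
#'   and 500 generations are the scoring defaults).
#' @param max_sweeps safety cap on refinement sweeps.
#' @return list with `score`, `internal_genomes` (list by node id), and
#'   `sweeps`.
#' @export
score_tree <- function(tree, leaf_genomes,
                       solver = solver_config(max_generations = 500L),
                       max_sweeps = 10L) {
  nt <- n_tips(tree)
  if (tree$Nnode != nt - 2L)
    stop("tree is not an unrooted binary topology")
  stopifnot(all(tree$tip.label %in% names(leaf_genomes)))
  solver$seed <- NULL
  nbrs <- tree_adjacency(tree)
  genomes <- initialize_internal_genomes(tree, leaf_genomes, solver)
  for (i in seq_len(nt)) genomes[[i]] <- leaf_genomes[[tree$tip.label[i]]]

  # depth-first post-order over internal nodes from a fixed root
  dt <- descendant_tips(tree)
  internal_po <- rev(dt$preorder)
  internal_po <- internal_po[internal_po > nt]

  edge_sum <- function() {
    s <- 0L
    for (i in seq_len(nrow(tree$edge))) {
      s <- s + cpp_dcj_distance(genomes[[tree$edge[i, 1L]]]$nb,
                                genomes[[tree$edge[i, 2L]]]$nb)
    }
    s
  }
  sweeps <- 0L
  repeat {
    changed <- FALSE
    sweeps <- sweeps + 1L
    for (v in internal_po) {
      nb3 <- nbrs[[v]]
      inst <- make_instance(genomes[[nb3[1]]], genomes[[nb3[2]]],
                            genomes[[nb3[3]]])
      cur <- cpp_fitness3(genomes[[v]]$nb, inst$g1$nb, inst$g2$nb,
                          inst$g3$nb)
      if (cur <= ceiling(inst$median_lb)) next   # already optimal here
      res <- solve_median(inst, solver)
      if (res$score < cur) {
        genomes[[v]] <- res$median
        changed <- TRUE
      }
    }
    if (!changed || sweeps >= max_sweeps) break
  }
  list(score = edge_sum(), internal_genomes = genomes[(nt + 1L):(nt + tree$Nnode)],
       all_genomes = genomes, sweeps = sweeps)
}

# all unrooted binary topologies over the given labels, by leaf insertion
enumerate_topologies <- function(labels) {
  m <- length(labels)
  stopifnot(m >= 3L)
  base <- list(rbind(c(m + 1L, 1L), c(m + 1L, 2L), c(m + 1L, 3L)))
  trees <- base
  nxt_internal <- m + 2L
  for (leaf in seq(4L, length.out = max(0L, m - 3L))) {
    out <- list()
    for (ed in trees) {
      for (i in seq_len(nrow(ed))) {
        u <- ed[i, 1L]; v <- ed[i, 2L]
        ne <- rbind(ed[-i, , drop = FALSE],
                    c(u, nxt_internal), c(nxt_internal, v),
                    c(nxt_internal, leaf))
        out[[length(out) + 1L]] <- ne
      }
    }
    trees <- out
    nxt_internal <- nxt_internal + 1L
  }
  lapply(trees, function(ed) {
    structure(list(edge = ed, tip.label = labels, Nnode = m - 2L),
              class = "phylo")
  })
}

#' Tree search configuration
#'
#' @param solver [solver_config()] for median solves during scoring.
#' @param mode `"exhaustive"` enumerates every unrooted binary topology
#'   (guarded to at most `max_exhaustive_taxa` taxa); `"sorted"` scores
#'   topologies in ascending lower-bound order until `time_budget`.
#' @param time_budget wall-clock seconds for `"sorted"` mode.
#' @param max_exhaustive_taxa enumeration guard (default 9).
#' @param max_sweeps refinement sweep cap per scored tree.
#' @param seed optional seed applied once at search start.
#' @return a `dcj_search_config`.
#' @export
search_config <- function(solver = solver_config(population = 20L,
                                                 max_generations = 500L),
                          mode = c("exhaustive", "sorted"),
                          time_budget = Inf, max_exhaustive_taxa = 9L,
                          max_sweeps = 10L, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "sorted" && !(time_budget > 0)) stop("time_budget must be > 0")
  structure(list(solver = solver, mode = mode, time_budget = time_budget,
                 max_exhaustive_taxa = as.integer(max_exhaustive_taxa),
                 max_sweeps = as.integer(max_sweeps), seed = seed),
            class = "dcj_search_config")
}

#' Search tree space with lower-bound pruning
#'
#' Scores the neighbor-joining tree first as the best-so-far, then
#' enumerates unrooted binary topologies, pruning every tree whose
#' circular-ordering lower bound (computed on its own planar embedding
#' ordering) exceeds the best score; in `"sorted"` mode topologies are
#' scored in ascending bound order until the time budget runs out.
#'
#' @param leaf_genomes named list of `dcj_genome`s (>= 3 taxa).
#' @param cfg a [search_config()].
#' @return list with `best_tree`, `best_score`, `internal_genomes` (by
#'   node id of `best_tree`), `nj_tree`, `dist` (pairwise DCJ matrix) and
#'   `log` (one row per topology: bound, score, status).
#' @export
search_trees <- function(leaf_genomes, cfg = search_config()) {
  stopifnot(inherits(cfg, "dcj_search_config"))
  m <- length(leaf_genomes)
  if (m < 3L) stop("need at least 3 taxa")
  labels <- names(leaf_genomes)
  if (is.null(labels)) stop("leaf_genomes must be named")
  if (m > cfg$max_exhaustive_taxa)
    stop("topology enumeration is guarded to ", cfg$max_exhaustive_taxa,
         " taxa (", m, " requested)")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]

  dmat <- cpp_pairwise_distances(lapply(leaf_genomes, `[[`, "nb"))
  dimnames(dmat) <- list(labels, labels)

  njt <- nj_tree(dmat)
  nj_res <- score_tree(njt, leaf_genomes, cfg$solver, cfg$max_sweeps)
  best_tree <- njt
  best_res <- nj_res
  best_score <- nj_res$score
  nj_key <- paste(sort(tree_bipartitions(njt)), collapse = ";")

  topos <- enumerate_topologies(labels)
  bounds <- vapply(topos, function(tr)
    circular_lower_bound(tree_circular_order(tr), dmat), 1)
  ord <- if (cfg$mode == "sorted") order(bounds) else seq_along(topos)

  log <- data.frame(topology = seq_along(topos), bound = bounds,
                    score = NA_real_, status = "unvisited",
                    stringsAsFactors = FALSE)
  for (i in ord) {
    if (cfg$mode == "sorted" &&
        proc.time()[["elapsed"]] - t0 > cfg$time_budget) {
      log$status[log$status == "unvisited"] <- "out_of_budget"
      break
    }
    tr <- topos[[i]]
    if (paste(sort(tree_bipartitions(tr)), collapse = ";") == nj_key) {
      log$score[i] <- nj_res$score
      log$status[i] <- "nj"
      next
    }
    if (bounds[i] >= best_score) {
      # score >= ceiling(bound) >= best: this topology cannot improve the
      # best score (sharper than pruning only strictly larger bounds)
      log$status[i] <- "pruned"
      next
    }
    res <- score_tree(tr, leaf_genomes, cfg$solver, cfg$max_sweeps)
    log$score[i] <- res$score
    log$status[i] <- "scored"
    if (res$score < best_score) {
      best_score <- res$score
      best_tree <- tr
      best_res <- res
    }
  }
  list(best_tree = best_tree, best_score = best_score,
       internal_genomes = best_res$internal_genomes,
       all_genomes = best_res$all_genomes,
       nj_tree = njt, dist = dmat, log = log)
}

# the three leaf-label sets separated by an internal node
node_tripartition <- function(tree, node) {
  nt <- n_tips(tree)
  stopifnot(node > nt)
  dt <- descendant_tips(tree, root = node)
  nbrs <- tree_adjacency(tree)
  parts <- lapply(nbrs[[node]], function(v) dt$tips[[v]])
  parts <- lapply(parts, sort)
  keys <- vapply(parts, paste, "", collapse = "|")
  paste(sort(keys), collapse = " / ")
}

#' Match an internal node between two trees by leaf tripartition
#'
#' Finds the internal node of `tree` that induces the same three-way leaf
#' partition as `ref_node` does in `ref_tree` (possible whenever the two
#' topologies agree around that node).
#'
#' @param tree tree to search in.
#' @param ref_tree reference tree.
#' @param ref_node internal node id in `ref_tree`.
#' @return the matching node id in `tree`, or `NA` if none.
#' @export
match_internal_node <- function(tree, ref_tree, ref_node) {
  key <- node_tripartition(ref_tree, ref_node)
  nt <- n_tips(tree)
  for (v in (nt + 1L):(nt + tree$Nnode)) {
    if (node_tripartition(tree, v) == key) return(v)
  }
  NA_integer_
}

#' Distance from an inferred ancestor to the simulated root genome
#'
#' Matches the internal node of the search result's best tree to the
#' simulated root node (by leaf tripartition) and returns the DCJ
#' distance between the inferred genome there and the true root genome.
#'
#' @param search_result a [search_trees()] result.
#' @param truth a [simulate_tree_dataset()] result.
#' @return integer DCJ distance, or `NA` if the topologies disagree
#'   around the root.
#' @export
root_ancestor_distance <- function(search_result, truth) {
  v <- match_internal_node(search_result$best_tree, truth$tree,
                           truth$root_node)
  if (is.na(v)) return(NA_integer_)
  dcj_distance(search_result$all_genomes[[v]], truth$root_genome)
}

# -- Newick I/O --------------------------------------------------------

phylo_to_newick <- function(tree, internal_labels = FALSE) {
  nbrs <- tree_adjacency(tree)
  nt <- n_tips(tree)
  root <- nt + 1L
  rec <- function(u, parent) {
    if (u <= nt) return(tree$tip.label[u])
    kids <- nbrs[[u]][nbrs[[u]] != parent]
    lab <- if (internal_labels) paste0("N", u) else ""
    paste0("(", paste(vapply(kids, rec, "", u), collapse = ","), ")", lab)
  }
  paste0(rec(root, -1L), ";")
}

#' Write a tree in Newick format
#'
#' Optionally writes internal-node genomes to a sidecar gene-order file
#' keyed by `N<id>` labels that are then embedded in the Newick string.
#'
#' @param tree phylo-structured tree.
#' @param path output path.
#' @param genomes optional list of genomes indexed by node id (as in
#'   `search_trees()$all_genomes`).
#' @param genome_path sidecar path (default `paste0(path, ".genes")`).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, genomes = NULL, genome_path = NULL) {
  writeLines(phylo_to_newick(tree, internal_labels = !is.null(genomes)),
             path)
  if (!is.null(genomes)) {
    if (is.null(genome_path)) genome_path <- paste0(path, ".genes")
    nt <- n_tips(tree)
    ids <- (nt + 1L):(nt + tree$Nnode)
    gl <- genomes[ids]
    names(gl) <- paste0("N", ids)
    write_gene_order_file(gl, genome_path)
  }
  invisible(path)
}

#' Read a tree from a Newick file
#'
#' Parses with \pkg{ape} and unroots binary-rooted trees so the result is
#' comparable with package-built topologies.
#'
#' @param path file path.
#' @return an unrooted `phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (ape::is.rooted(tr) && n_tips(tr) >= 3L) tr <- ape::unroot(tr)
  tr
}
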