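# Test oracles and fixture generators, independent of the implementation
# paths they check.

genome_nb <- function(nb) dcjmedian:::new_genome(as.integer(nb))

gkey <- function(g) paste(g$nb, collapse = ",")

# random multichromosomal genome over genes 1..n
random_genome <- function(n, p_split = 0.2, p_circ = 0.3) {
  perm <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
  cuts <- if (n > 1) which(stats::runif(n - 1) < p_split) else integer(0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  chrs <- lapply(seq_along(starts), function(i) {
    list(genes = perm[starts[i]:ends[i]],
         circular = stats::runif(1) < p_circ)
  })
  genome_from_gene_orders(chrs)
}

# random single-linear-chromosome genome (signed permutation)
random_linear_genome <- function(n) {
  genome_from_gene_orders(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

# all single-linear-chromosome genomes on n genes, deduplicated up to
# reversal (adjacency-set equality)
all_linear_genomes <- function(n) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  out <- list()
  seen <- character(0)
  for (i in seq_len(nrow(perms))) {
    for (j in seq_len(nrow(signs))) {
      g <- genome_from_gene_orders(perms[i, ] * signs[j, ])
      k <- gkey(g)
      if (!(k %in% seen)) {
        seen <- c(seen, k)
        out[[length(out) + 1L]] <- g
      }
    }
  }
  out
}

# every genome on n genes: all partial matchings of the 2n extremities
all_genomes <- function(n) {
  res <- list()
  rec <- function(nb, avail) {
    if (length(avail) == 0L) {
      res[[length(res) + 1L]] <<- genome_nb(nb)
      return(invisible())
    }
    e <- avail[1L]
    rec(nb, avail[-1L])                 # e is a telomere
    for (f in avail[-1L]) {
      nb2 <- nb
      nb2[e] <- f
      nb2[f] <- e
      rec(nb2, setdiff(avail, c(e, f)))
    }
  }
  rec(integer(2L * n), seq_len(2L * n))
  res
}

# breadth-first DCJ distance over the one-step neighbourhood
# (meet-in-the-middle; independent of the adjacency-graph formula)
bfs_dcj_distance <- function(a, b, max_depth = 16L) {
  if (gkey(a) == gkey(b)) return(0L)
  side <- function(g) {
    e <- new.env(parent = emptyenv())
    assign(gkey(g), 0L, envir = e)
    list(frontier = list(g), seen = e, depth = 0L)
  }
  s <- list(side(a), side(b))
  repeat {
    i <- if (length(s[[1]]$frontier) <= length(s[[2]]$frontier)) 1L else 2L
    j <- 3L - i
    newf <- list()
    nd <- s[[i]]$depth + 1L
    for (g in s[[i]]$frontier) {
      for (h in enumerate_dcj_neighbors(g)) {
        k <- gkey(h)
        if (exists(k, envir = s[[j]]$seen, inherits = FALSE)) {
          return(nd + get(k, envir = s[[j]]$seen))
        }
        if (!exists(k, envir = s[[i]]$seen, inherits = FALSE)) {
          assign(k, nd, envir = s[[i]]$seen)
          newf[[length(newf) + 1L]] <- h
        }
      }
    }
    s[[i]]$frontier <- newf
    s[[i]]$depth <- nd
    if (nd > max_depth || length(newf) == 0L) {
      stop("BFS oracle exceeded max depth")
    }
  }
}

# exhaustive DCJ median score over every genome on n genes (tiny n only)
brute_force_median_score <- function(inst, candidates = NULL) {
  if (is.null(candidates)) candidates <- all_genomes(inst$g1$n)
  min(vapply(candidates, function(g) median_fitness(g, inst), 1L))
}

# textbook neighbor joining producing a newick string, as an oracle for
# the ape-backed nj_tree()
oracle_nj_tree <- function(d) {
  d <- as.matrix(d)
  nodes <- rownames(d)
  D <- d
  while (length(nodes) > 3L) {
    m <- length(nodes)
    rs <- rowSums(D)
    Q <- matrix(Inf, m, m)
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) Q[i, j] <- (m - 2) * D[i, j] - rs[i] - rs[j]
    }
    ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- ij[[1L]]; j <- ij[[2L]]
    merged <- paste0("(", nodes[i], ",", nodes[j], ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes <- c(nodes[keep], merged)
  }
  ape::read.tree(text = paste0("(", paste(nodes, collapse = ","), ");"))
}

same_topology <- function(t1, t2) {
  setequal(dcjmedian:::tree_bipartitions(t1), dcjmedian:::tree_bipartitions(t2))
}
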