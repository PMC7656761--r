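# DCJ distance, adjacency graph, DCJ operations, and sorting-path sampling.

#' Adjacency graph of two genomes
#'
#' The bipartite graph whose vertices are the adjacencies/telomeres of the
#' two genomes and whose edges are the 2n gene extremities.  Components are
#' cycles or paths; with `C` cycles and `I` odd-length paths the DCJ
#' distance is `n - (C + I/2)`.
#'
#' @param a,b `dcj_genome` objects over the same gene set.
#' @return a `dcj_adjacency_graph`: list with `n`, `C`, `I`, `distance`,
#'   and `components` (data.frame of component type and edge count, with
#'   the ordered extremity chain of each component as a list column).
#' @examples
#' g1 <- genome_from_gene_orders(1:5)
#' g2 <- genome_from_gene_orders(c(3, -2, -1, -4, 5))
#' ag <- build_adjacency_graph(g1, g2)
#' c(ag$C, ag$I, ag$distance)  # 1 2 3
#' @export
build_adjacency_graph <- function(a, b) {
  stopifnot(is_genome(a), is_genome(b))
  check_same_genes(a, b)
  comp <- cpp_components(a$nb, b$nb)
  C <- sum(comp$type == "cycle")
  I <- sum(comp$type == "odd_path")
  stopifnot(I %% 2L == 0L)
  structure(list(
    n = a$n, C = C, I = I,
    distance = a$n - C - I %/% 2L,
    components = data.frame(type = comp$type, edges = comp$edges,
                            extremities = I(comp$extremities))
  ), class = "dcj_adjacency_graph")
}

#' @export
print.dcj_adjacency_graph <- function(x, ...) {
  cat("<dcj_adjacency_graph: n =", x$n, ", C =", x$C, ", I =", x$I,
      ", distance =", x$distance, ">\n")
  print(table(x$components$type))
  invisible(x)
}

#' DCJ distance between two genomes
#'
#' `n - (C + I/2)` from the adjacency graph: the minimum number of
#' double-cut-and-join operations transforming one genome into the other.
#'
#' @param a,b `dcj_genome` objects over the same gene set.
#' @return non-negative integer.
#' @export
dcj_distance <- function(a, b) {
  stopifnot(is_genome(a), is_genome(b))
  check_same_genes(a, b)
  cpp_dcj_distance(a$nb, b$nb)
}

#' Construct a DCJ operation
#'
#' An operation is described by the genome elements it consumes
#' (`operands`) and the elements that replace them (`products`); each
#' element is an integer vector of 1 (telomere) or 2 (adjacency)
#' extremity codes.  The kind is derived from the operand/product shapes:
#' rejoining two adjacencies, rejoining an adjacency and a telomere,
#' joining two telomeres, or cutting an adjacency.
#'
#' @param operands,products lists of integer extremity vectors.
#' @return a `dcj_operation`.
#' @export
dcj_op <- function(operands, products) {
  operands <- lapply(operands, as.integer)
  products <- lapply(products, as.integer)
  if (!setequal(unlist(operands), unlist(products)))
    stop("products must cover exactly the operand extremities")
  sizes <- function(x) sort(vapply(x, length, 1L))
  so <- sizes(operands); sp <- sizes(products)
  kind <-
    if (identical(so, c(2L, 2L))) "rejoin-adjacencies"
    else if (identical(so, c(1L, 2L)) && identical(sp, c(1L, 2L)))
      "rejoin-adjacency-telomere"
    else if (identical(so, c(1L, 1L))) "join-telomeres"
    else if (identical(so, 2L) && identical(sp, c(1L, 1L))) "cut-adjacency"
    else stop("not one of the four DCJ operation shapes")
  structure(list(kind = kind, operands = operands, products = products),
            class = "dcj_operation")
}

#' @export
print.dcj_operation <- function(x, ...) {
  fmt <- function(els) paste(vapply(els, function(e)
    paste0("{", paste(ext_label(e), collapse = ","), "}"), ""),
    collapse = " ")
  cat("<dcj_operation ", x$kind, ": ", fmt(x$operands), " -> ",
      fmt(x$products), ">\n", sep = "")
  invisible(x)
}

element_in_genome <- function(g, el) {
  if (length(el) == 1L) g$nb[el] == 0L else g$nb[el[1L]] == el[2L]
}

#' Apply a DCJ operation to a genome
#'
#' @param g a `dcj_genome`.
#' @param op a [dcj_op()] whose operands are present in `g`.
#' @return a new `dcj_genome`; `g` is untouched.
#' @export
apply_dcj <- function(g, op) {
  stopifnot(is_genome(g), inherits(op, "dcj_operation"))
  for (el in op$operands) {
    if (!element_in_genome(g, el)) {
      stop("operand {", paste(ext_label(el), collapse = ","),
           "} not present in genome")
    }
  }
  nb <- g$nb
  for (el in op$operands) nb[el] <- 0L
  for (el in op$products) {
    if (length(el) == 2L) { nb[el[1L]] <- el[2L]; nb[el[2L]] <- el[1L] }
  }
  validate_genome(new_genome(nb, g$name))
}

#' Enumerate all one-step DCJ neighbours of a genome
#'
#' All genomes reachable by exactly one DCJ operation: both rejoin
#' variants of every adjacency pair, both rejoin variants of every
#' adjacency/telomere pair, every telomere-pair join, and every adjacency
#' cut.  Intended for small genomes (used as the oracle edge set for
#' breadth-first distance checks); the neighbourhood grows quadratically.
#'
#' @param g a `dcj_genome`.
#' @param as_ops return the list of [dcj_op()]s instead of genomes.
#' @return list of distinct `dcj_genome`s (the input excluded), or ops.
#' @export
enumerate_dcj_neighbors <- function(g, as_ops = FALSE) {
  stopifnot(is_genome(g))
  nb <- g$nb
  adjs <- lapply(which(nb > seq_along(nb)), function(e) c(e, nb[e]))
  tels <- as.list(which(nb == 0L))
  ops <- list()
  add <- function(operands, products) {
    ops[[length(ops) + 1L]] <<- dcj_op(operands, products)
  }
  na <- length(adjs)
  if (na >= 2L) {
    for (i in seq_len(na - 1L)) {
      for (j in (i + 1L):na) {
        p <- adjs[[i]]; q <- adjs[[j]]
        add(list(p, q), list(c(p[1], q[1]), c(p[2], q[2])))
        add(list(p, q), list(c(p[1], q[2]), c(p[2], q[1])))
      }
    }
  }
  for (p in adjs) {
    for (t in tels) {
      add(list(p, t), list(c(p[1], t), p[2]))
      add(list(p, t), list(c(p[2], t), p[1]))
    }
    add(list(p), list(p[1], p[2]))  # cut
  }
  nt <- length(tels)
  if (nt >= 2L) {
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        add(list(tels[[i]], tels[[j]]), list(c(tels[[i]], tels[[j]])))
      }
    }
  }
  if (as_ops) return(ops)
  res <- lapply(ops, function(op) apply_dcj(g, op))
  keys <- vapply(res, genome_key, "")
  res <- res[!duplicated(keys) & keys != genome_key(g)]
  res
}

#' Enumerate all optimal DCJ sorting steps toward a target
#'
#' Every operation that, applied to `current`, decreases the DCJ distance
#' to `target` by exactly one: the complete set, obtained by filtering the
#' one-step neighbourhood, so it is intended for small genomes (tests,
#' oracles).  The production sorting-path sampler
#' ([sample_intermediate()]) draws uniformly from the same set without
#' materializing it.
#'
#' @param current,target `dcj_genome`s over the same gene set.
#' @return list of [dcj_op()]s; empty when `current` equals `target`.
#' @export
optimal_dcj_steps <- function(current, target) {
  stopifnot(is_genome(current), is_genome(target))
  check_same_genes(current, target)
  d0 <- cpp_dcj_distance(current$nb, target$nb)
  if (d0 == 0L) return(list())
  ops <- enumerate_dcj_neighbors(current, as_ops = TRUE)
  keep <- vapply(ops, function(op) {
    cpp_dcj_distance(apply_dcj(current, op)$nb, target$nb) == d0 - 1L
  }, TRUE)
  ops[keep]
}

#' Sample a genome on an optimal DCJ sorting path
#'
#' Performs `k` DCJ steps from `source` toward `target`, each chosen
#' uniformly at random among the optimal operations found by scanning the
#' current adjacency graph, so that the result `R` satisfies
#' `d(source, R) = k` and `d(R, target) = d(source, target) - k`.
#' Randomness comes from the R random number generator (seedable with
#' [set.seed()]).
#'
#' @param source,target `dcj_genome`s over the same gene set.
#' @param k number of steps, between 0 and `dcj_distance(source, target)`.
#' @return a `dcj_genome`.
#' @export
sample_intermediate <- function(source, target, k) {
  stopifnot(is_genome(source), is_genome(target))
  check_same_genes(source, target)
  k <- as.integer(k)
  if (k < 0L) stop("k must be non-negative")
  if (k == 0L) return(source)
  d <- cpp_dcj_distance(source$nb, target$nb)
  if (k > d) stop("k (", k, ") exceeds the DCJ distance (", d, ")")
  new_genome(cpp_sample_path(source$nb, target$nb, k))
}
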