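# Genome representation: adjacency/telomere view of signed gene orders.
#
# A genome over genes 1..n is stored as an integer "neighbour" vector `nb`
# of length 2n over gene extremities.  Gene g owns its tail extremity
# 2g - 1 and its head extremity 2g; nb[e] is the extremity adjacent to e
# (an adjacency {e, nb[e]}), or 0 when e is a telomere.  This encodes the
# set-of-adjacencies-and-telomeres view exactly: every extremity appears
# in exactly one adjacency or telomere.
#
# Orientation convention (fixed package-wide): a positively signed gene
# written left-to-right faces its tail to the left neighbour and its head
# to the right, so consecutive (+a, +b) yields the adjacency {a.h, b.t}.

#' Extremity helpers
#'
#' Gene extremities are encoded as integers: gene `g` has tail `2g - 1`
#' and head `2g`.  `ext_label()` renders the printable form `"g.t"` /
#' `"g.h"`; `parse_extremity()` inverts it.
#'
#' @param g positive integer gene identifier(s).
#' @param e integer extremity code(s).
#' @param x character vector like `"3.h"`.
#' @return integer extremity codes, gene ids, or labels.
#' @examples
#' ext_label(ext_head(3))   # "3.h"
#' parse_extremity("3.h") == ext_head(3)
#' @name extremities
NULL

#' @rdname extremities
#' @export
ext_tail <- function(g) 2L * as.integer(g) - 1L

#' @rdname extremities
#' @export
ext_head <- function(g) 2L * as.integer(g)

#' @rdname extremities
#' @export
ext_gene <- function(e) (as.integer(e) + 1L) %/% 2L

#' @rdname extremities
#' @export
ext_is_head <- function(e) as.integer(e) %% 2L == 0L

#' @rdname extremities
#' @export
ext_label <- function(e) {
  paste0(ext_gene(e), ifelse(ext_is_head(e), ".h", ".t"))
}

#' @rdname extremities
#' @export
parse_extremity <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+)\\.([ht])$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed extremity label: ", x[bad][1])
  g <- as.integer(vapply(m, `[`, "", 2L))
  if (any(g < 1L)) stop("gene identifiers must be >= 1")
  ifelse(vapply(m, `[`, "", 3L) == "h", ext_head(g), ext_tail(g))
}

new_genome <- function(nb, name = NULL) {
  structure(list(n = length(nb) %/% 2L, nb = as.integer(nb), name = name),
            class = "dcj_genome")
}

#' Is an object a genome?
#' @param x object.
#' @export
is_genome <- function(x) inherits(x, "dcj_genome")

#' Build a genome from signed gene orders
#'
#' Each chromosome is a vector of signed gene identifiers (or a list with
#' elements `genes` and `circular`).  Plain integer vectors are taken as
#' linear chromosomes.  Gene identifiers must form the set `1..n` with no
#' repeats; 0 is invalid.
#'
#' @param chromosomes a single signed integer vector, or a list of signed
#'   integer vectors / `list(genes =, circular =)` records.
#' @param name optional genome label.
#' @return a `dcj_genome`.
#' @examples
#' g1 <- genome_from_gene_orders(c(1, 2, 3, 4, 5))
#' g2 <- genome_from_gene_orders(c(3, -2, -1, -4, 5))
#' dcj_distance(g1, g2)  # 3
#' @export
genome_from_gene_orders <- function(chromosomes, name = NULL) {
  if (is.numeric(chromosomes)) chromosomes <- list(chromosomes)
  chrs <- lapply(chromosomes, function(ch) {
    if (is.list(ch)) {
      list(genes = as.integer(ch$genes), circular = isTRUE(ch$circular))
    } else {
      list(genes = as.integer(ch), circular = FALSE)
    }
  })
  genes <- unlist(lapply(chrs, `[[`, "genes"))
  if (length(genes) == 0L) stop("genome has no genes")
  if (any(vapply(chrs, function(ch) length(ch$genes) == 0L, TRUE)))
    stop("empty chromosome")
  if (any(genes == 0L)) stop("gene identifier 0 is invalid")
  ids <- abs(genes)
  if (anyDuplicated(ids)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- length(ids)
  if (!setequal(ids, seq_len(n))) {
    stop("gene identifiers must form the set 1..n; missing: ",
         paste(setdiff(seq_len(n), ids), collapse = ", "))
  }
  nb <- integer(2L * n)
  left_ext  <- function(g) if (g > 0L) ext_tail(g) else ext_head(-g)
  right_ext <- function(g) if (g > 0L) ext_head(g) else ext_tail(-g)
  for (ch in chrs) {
    v <- ch$genes
    k <- length(v)
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        a <- right_ext(v[i]); b <- left_ext(v[i + 1L])
        nb[a] <- b; nb[b] <- a
      }
    }
    if (ch$circular) {
      a <- right_ext(v[k]); b <- left_ext(v[1L])
      nb[a] <- b; nb[b] <- a
    }
  }
  g <- new_genome(nb, name)
  validate_genome(g)
  g
}

#' Validate genome internal structure
#'
#' Checks that the neighbour vector is a telomere-augmented involution:
#' every extremity of every gene appears in exactly one adjacency or
#' telomere.  Called by every constructor.
#'
#' @param g a `dcj_genome`.
#' @return `g`, invisibly.
#' @export
validate_genome <- function(g) {
  stopifnot(is_genome(g))
  nb <- g$nb
  if (length(nb) != 2L * g$n) stop("neighbour vector has wrong length")
  adj <- which(nb > 0L)
  if (any(nb[adj] < 1L | nb[adj] > 2L * g$n)) stop("extremity out of range")
  if (any(nb[nb[adj]] != adj)) stop("adjacency map is not symmetric")
  if (any(nb[adj] == adj)) stop("extremity adjacent to itself")
  invisible(g)
}

#' Decompose a genome into signed gene-order chromosomes
#'
#' Inverse of [genome_from_gene_orders()] up to chromosome order,
#' chromosome reversal, and circular rotation.  Linear chromosomes are
#' reported starting from the telomere whose first gene reads positively
#' when possible, circular chromosomes from their smallest gene id read
#' positively; chromosomes are sorted by smallest contained gene id.
#'
#' @param g a `dcj_genome`.
#' @return list of `list(genes =, circular =)` records.
#' @export
gene_orders_from_genome <- function(g) {
  stopifnot(is_genome(g))
  nb <- g$nb
  n2 <- 2L * g$n
  seen <- logical(n2)
  out <- list()
  walk <- function(start) {
    # `start` is the outward-facing extremity of the first gene
    genes <- integer(0)
    e <- start
    repeat {
      gid <- ext_gene(e)
      genes <- c(genes, if (ext_is_head(e)) -gid else gid)
      other <- if (ext_is_head(e)) ext_tail(gid) else ext_head(gid)
      seen[c(e, other)] <<- TRUE
      nxt <- nb[other]
      if (nxt == 0L || seen[nxt]) return(list(genes = genes, end = nxt))
      e <- nxt
    }
  }
  # linear chromosomes: start at telomeres
  for (e in which(nb == 0L)) {
    if (seen[e]) next
    res <- walk(e)
    v <- res$genes
    w <- -rev(v)
    if (v[1] < 0 && w[1] > 0) v <- w
    out[[length(out) + 1L]] <- list(genes = v, circular = FALSE)
  }
  # circular chromosomes: canonical start at smallest gene, read forward
  for (e in seq_len(n2)) {
    if (seen[e] || nb[e] == 0L) next
    gid <- ext_gene(e)
    res <- walk(ext_tail(gid))  # enter via tail => first gene positive
    out[[length(out) + 1L]] <- list(genes = res$genes, circular = TRUE)
  }
  first_id <- vapply(out, function(ch) min(abs(ch$genes)), 1)
  out <- out[order(first_id)]
  out <- lapply(out, function(ch) {
    if (ch$circular) {
      i <- which(abs(ch$genes) == min(abs(ch$genes)))
      v <- c(ch$genes[i:length(ch$genes)], ch$genes[seq_len(i - 1L)])
      if (v[1] < 0) v <- c(-v[1], -rev(v[-1]))
      ch$genes <- v
    }
    ch
  })
  out
}

#' Adjacency set of a genome
#'
#' Returns the two-extremity elements only (telomeres excluded), as used
#' by the adjacency-accuracy metric.
#'
#' @param g a `dcj_genome`.
#' @param labels return printable `"g.h|g.t"` keys instead of a matrix.
#' @return an integer matrix with one adjacency per row (columns are the
#'   two extremity codes, smaller first), or a character vector of keys.
#' @export
adjacency_set <- function(g, labels = FALSE) {
  stopifnot(is_genome(g))
  e <- which(g$nb > 0L & g$nb > seq_along(g$nb))
  m <- cbind(first = e, second = as.integer(g$nb[e]))
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (!labels) return(m)
  paste(ext_label(m[, 1L]), ext_label(m[, 2L]), sep = "|")
}

#' Telomeres of a genome
#' @param g a `dcj_genome`.
#' @return integer vector of telomeric extremity codes.
#' @export
telomere_set <- function(g) which(g$nb == 0L)

#' Test two genomes for equality as adjacency/telomere sets
#' @param a,b `dcj_genome` objects.
#' @export
genomes_equal <- function(a, b) {
  is_genome(a) && is_genome(b) && identical(a$nb, b$nb)
}

genome_key <- function(g) paste(g$nb, collapse = ",")

check_same_genes <- function(a, b) {
  if (a$n != b$n) {
    stop("genomes are over different gene sets (", a$n, " vs ", b$n,
         " genes)")
  }
}

#' @export
print.dcj_genome <- function(x, ...) {
  chrs <- gene_orders_from_genome(x)
  cat("<dcj_genome", if (!is.null(x$name)) paste0(" '", x$name, "'"), ": ",
      x$n, " genes, ", length(chrs), " chromosome(s)>\n", sep = "")
  for (ch in chrs) {
    cat(" ", paste(ch$genes, collapse = " "),
        if (ch$circular) "@" else "$", "\n")
  }
  invisible(x)
}

#' @export
format.dcj_genome <- function(x, ...) {
  chrs <- gene_orders_from_genome(x)
  paste(vapply(chrs, function(ch) {
    paste(c(ch$genes, if (ch$circular) "@" else "$"), collapse = " ")
  }, ""), collapse = " ")
}
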