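# GRAPPA-style gene-order file format.
#
# Lines beginning ">" start a genome and carry its name; subsequent
# whitespace-separated signed integers form chromosomes; "$" terminates a
# linear chromosome and "@" a circular one; a new header or end-of-file
# closes the current genome (pending genes become a linear chromosome);
# "#" starts a comment line.

#' Read genomes from a gene-order file
#'
#' @param path file path.
#' @param require_same_genes check that all genomes share one gene set
#'   (the default; disable to read unrelated genomes from one file).
#' @return a list of [dcj_genome][genome_from_gene_orders] objects, named
#'   by their headers.
#' @examples
#' p <- tempfile()
#' writeLines(c(">A", "1 2 3 $", ">B", "1 -3 2 $"), p)
#' gs <- read_gene_order_file(p)
#' dcj_distance(gs$A, gs$B)
#' @export
read_gene_order_file <- function(path, require_same_genes = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  genomes <- list()
  cur_name <- NULL
  cur_chrs <- list()
  cur_genes <- integer(0)
  cur_line <- 0L
  flush_genome <- function() {
    if (is.null(cur_name)) return()
    if (length(cur_genes) > 0L) {
      cur_chrs[[length(cur_chrs) + 1L]] <<-
        list(genes = cur_genes, circular = FALSE)
      cur_genes <<- integer(0)
    }
    if (length(cur_chrs) == 0L) {
      stop("line ", cur_line, ": genome '", cur_name, "' has no genes")
    }
    g <- tryCatch(genome_from_gene_orders(cur_chrs, name = cur_name),
                  error = function(e) {
                    stop("genome '", cur_name, "' ending at line ", cur_line,
                         ": ", conditionMessage(e), call. = FALSE)
                  })
    genomes[[cur_name]] <<- g
    cur_chrs <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, ">")) {
      flush_genome()
      cur_name <- trimws(substring(ln, 2L))
      if (cur_name == "") cur_name <- paste0("genome", length(genomes) + 1L)
      cur_line <- i
      next
    }
    if (is.null(cur_name)) {
      stop("line ", i, ": gene data before any '>' header")
    }
    for (tok in strsplit(ln, "[[:space:]]+")[[1]]) {
      if (tok == "$" || tok == "@") {
        if (length(cur_genes) == 0L) {
          stop("line ", i, ": chromosome terminator with no genes")
        }
        cur_chrs[[length(cur_chrs) + 1L]] <-
          list(genes = cur_genes, circular = tok == "@")
        cur_genes <- integer(0)
      } else if (grepl("^[-+]?[0-9]+$", tok)) {
        cur_genes <- c(cur_genes, as.integer(tok))
      } else {
        stop("line ", i, ": malformed token '", tok, "'")
      }
    }
    cur_line <- i
  }
  flush_genome()
  if (length(genomes) == 0L) stop("no genomes in ", path)
  if (require_same_genes && length(genomes) > 1L) {
    ns <- vapply(genomes, `[[`, 1L, "n")
    if (length(unique(ns)) != 1L) {
      stop("genomes have inconsistent gene sets: ",
           paste(names(genomes), "has", ns, "genes", collapse = "; "))
    }
  }
  genomes
}

#' Write genomes to a gene-order file
#'
#' Output is deterministic (chromosomes in canonical decomposition order)
#' and parseable by [read_gene_order_file()].
#'
#' @param genomes a `dcj_genome` or list of them; unnamed genomes are
#'   labelled `genome1`, `genome2`, ...
#' @param path file path.
#' @export
write_gene_order_file <- function(genomes, path) {
  if (is_genome(genomes)) genomes <- list(genomes)
  nms <- names(genomes)
  if (is.null(nms)) nms <- rep("", length(genomes))
  lines <- character(0)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    stopifnot(is_genome(g))
    nm <- if (nzchar(nms[i])) nms[i] else
      if (!is.null(g$name)) g$name else paste0("genome", i)
    lines <- c(lines, paste0(">", nm))
    for (ch in gene_orders_from_genome(g)) {
      lines <- c(lines, paste(c(ch$genes, if (ch$circular) "@" else "$"),
                              collapse = " "))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
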