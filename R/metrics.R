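# Evaluation criteria for inferred median genomes: adjacency accuracy
# (intersection over union of adjacency sets), DCJ distance to the true
# ancestor, and batch reporting.

#' Adjacency accuracy between an inferred and a true genome
#'
#' Intersection-over-union of the two adjacency sets.  Telomeres are
#' excluded by default (the sets contain two-extremity adjacencies only);
#' set `include_telomeres = TRUE` for a sensitivity check that counts
#' them as singleton elements.
#'
#' @param gm inferred `dcj_genome`.
#' @param gt true `dcj_genome` over the same gene set.
#' @param include_telomeres count telomeres as set elements too.
#' @return ratio in `[0, 1]`; 1 exactly when the sets are equal.
#' @export
adjacency_accuracy <- function(gm, gt, include_telomeres = FALSE) {
  stopifnot(is_genome(gm), is_genome(gt))
  check_same_genes(gm, gt)
  a <- adjacency_set(gm, labels = TRUE)
  b <- adjacency_set(gt, labels = TRUE)
  if (include_telomeres) {
    a <- c(a, paste0("tel:", telomere_set(gm)))
    b <- c(b, paste0("tel:", telomere_set(gt)))
  }
  u <- union(a, b)
  if (length(u) == 0L) {
    if (genomes_equal(gm, gt)) return(1)
    stop("both genomes have empty adjacency sets but differ")
  }
  length(intersect(a, b)) / length(u)
}

#' DCJ distance from an inferred median to the true ancestor
#'
#' @param gm inferred `dcj_genome`.
#' @param gt true ancestor `dcj_genome`.
#' @return non-negative integer.
#' @export
distance_to_true <- function(gm, gt) dcj_distance(gm, gt)

#' Tabulate evaluation records for a batch of median results
#'
#' @param results list of [solve_median()] results.
#' @param truths list of true ancestor `dcj_genome`s (same length).
#' @param ids optional dataset identifiers.
#' @param r,runtime,seed optional per-dataset annotations recycled into
#'   the table.
#' @return data.frame with one row per dataset (median score, distance to
#'   the true ancestor, adjacency accuracy, runtime, seed) and the column
#'   means as attribute `"means"`.
#' @export
evaluate_batch <- function(results, truths, ids = NULL, r = NA, runtime = NA,
                           seed = NA) {
  if (length(results) != length(truths))
    stop("results and truths have different lengths")
  if (length(results) == 0L) {
    return(structure(data.frame(id = character(0), r = numeric(0),
                                n = integer(0), score = integer(0),
                                distance_to_true = integer(0),
                                adjacency_accuracy = numeric(0),
                                runtime = numeric(0), seed = integer(0)),
                     means = NULL))
  }
  if (is.null(ids)) ids <- paste0("dataset", seq_along(results))
  tab <- data.frame(
    id = ids,
    r = rep_len(r, length(results)),
    n = vapply(truths, `[[`, 1L, "n"),
    score = vapply(results, `[[`, 1L, "score"),
    distance_to_true = mapply(function(res, gt)
      distance_to_true(res$median, gt), results, truths),
    adjacency_accuracy = mapply(function(res, gt)
      adjacency_accuracy(res$median, gt), results, truths),
    runtime = rep_len(runtime, length(results)),
    seed = rep_len(seed, length(results)),
    stringsAsFactors = FALSE
  )
  num <- c("score", "distance_to_true", "adjacency_accuracy", "runtime")
  attr(tab, "means") <- colMeans(tab[num], na.rm = TRUE)
  tab
}

#' Write an evaluation table
#'
#' @param tab an [evaluate_batch()] table.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(tab, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(records = tab,
                              means = as.list(attr(tab, "means"))),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
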