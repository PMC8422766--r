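#' Pairwise distance matrix between two chromosome sets
#'
#' Computes D1 or D2 between every chromosome of one species and every
#' chromosome of another, from pre-computed k-mer spectra. D2 is the default
#' for inter-species comparisons: the strand chosen for each chromosome in
#' an assembly is arbitrary, and only D2 is invariant under that choice.
#'
#' @param set_1,set_2 lists of [count_kmers()] spectra, all sharing one `k`.
#' @param measure `"D2"` (default) or `"D1"`.
#' @return object of class `kmer_distance_matrix`: list with `values`
#'   (numeric matrix, rows = set_1, cols = set_2, dimnames from the spectra
#'   source ids), `row_ids`, `col_ids`, `k`, `measure`.
#' @export
distance_matrix <- function(set_1, set_2, measure = c("D2", "D1")) {
  measure <- match.arg(measure)
  if (length(set_1) == 0L || length(set_2) == 0L) {
    stop("empty chromosome set")
  }
  ks <- vapply(c(set_1, set_2), `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("all spectra must share the same k")
  fun <- if (measure == "D1") d1 else d2
  vals <- matrix(NA_real_, nrow = length(set_1), ncol = length(set_2))
  for (i in seq_along(set_1)) {
    for (j in seq_along(set_2)) {
      vals[i, j] <- fun(set_1[[i]], set_2[[j]])$value
    }
  }
  row_ids <- make.unique(vapply(set_1, `[[`, character(1), "source_id"))
  col_ids <- make.unique(vapply(set_2, `[[`, character(1), "source_id"))
  dimnames(vals) <- list(row_ids, col_ids)
  structure(
    list(values = vals, row_ids = row_ids, col_ids = col_ids,
         k = ks[1L], measure = measure),
    class = "kmer_distance_matrix"
  )
}

#' @export
print.kmer_distance_matrix <- function(x, ...) {
  cat(sprintf("<kmer_distance_matrix> %s (k=%d), %d x %d\n",
              x$measure, x$k, nrow(x$values), ncol(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Greedy matched-pair summary of a distance matrix
#'
#' Summarises the distance structure between two chromosome sets by a
#' greedy minimum-weight matching on the bipartite graph whose edges are
#' matrix cells:
#' edges with distance above `threshold` are discarded; then the globally
#' minimal remaining edge is selected repeatedly, each selection removing
#' both endpoint chromosomes (and all their incident edges), until no edge
#' remains. The selected distances form a non-decreasing vector whose first
#' entry is the minimum and whose median is reported alongside it. Ties on
#' the minimal value are broken lexicographically on (row id, column id)
#' for determinism.
#'
#' `remove = "edges"` gives the alternative reading in which a selection
#' removes only the chosen edge, so the result is simply every
#' sub-threshold edge in ascending order (chromosomes may then repeat).
#'
#' @param matrix a [distance_matrix()] result, or a plain numeric matrix
#'   with dimnames.
#' @param threshold discard edges with distance strictly greater than this
#'   (default 1).
#' @param remove `"vertices"` (matching; default) or `"edges"`.
#' @return object of class `match_result`: list with `pairs` (data frame
#'   `row_id`, `col_id`, `distance` in selection order), `distance_vector`,
#'   `minimum`, `median` and `status` (`"ok"` or
#'   `"no edges under threshold"`, in which case the result is empty rather
#'   than an error).
#' @examples
#' m <- matrix(c(0.2, 0.4, 0.5, 0.3), 2, 2,
#'             dimnames = list(c("r1", "r2"), c("c1", "c2")))
#' matched_pairs(m)$distance_vector  # 0.2 0.3
#' @export
matched_pairs <- function(matrix, threshold = 1,
                          remove = c("vertices", "edges")) {
  remove <- match.arg(remove)
  if (inherits(matrix, "kmer_distance_matrix")) {
    vals <- matrix$values
  } else {
    vals <- as.matrix(matrix)
    if (is.null(rownames(vals))) rownames(vals) <- paste0("r", seq_len(nrow(vals)))
    if (is.null(colnames(vals))) colnames(vals) <- paste0("c", seq_len(ncol(vals)))
  }
  if (length(vals) == 0L) stop("empty distance matrix")
  idx <- which(vals <= threshold, arr.ind = TRUE)
  empty <- data.frame(row_id = character(), col_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(idx) == 0L) {
    return(structure(
      list(pairs = empty, distance_vector = numeric(0),
           minimum = NA_real_, median = NA_real_,
           status = "no edges under threshold"),
      class = "match_result"))
  }
  edges <- data.frame(
    row_id = rownames(vals)[idx[, "row"]],
    col_id = colnames(vals)[idx[, "col"]],
    distance = vals[idx], stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$distance, edges$row_id, edges$col_id), , drop = FALSE]
  if (remove == "vertices") {
    # taking edges in (distance, row, col) order and skipping consumed
    # endpoints reproduces the iterative minimal-edge selection exactly
    sel <- logical(nrow(edges))
    used_r <- character(0); used_c <- character(0)
    for (e in seq_len(nrow(edges))) {
      if (edges$row_id[e] %in% used_r || edges$col_id[e] %in% used_c) next
      sel[e] <- TRUE
      used_r <- c(used_r, edges$row_id[e])
      used_c <- c(used_c, edges$col_id[e])
    }
    pairs <- edges[sel, , drop = FALSE]
  } else {
    pairs <- edges
  }
  rownames(pairs) <- NULL
  v <- pairs$distance
  structure(
    list(pairs = pairs, distance_vector = v,
         minimum = v[1L], median = stats::median(v), status = "ok"),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<match_result> %s\n", x$status))
  } else {
    cat(sprintf("<match_result> %d pair(s); min=%.6g median=%.6g\n",
                nrow(x$pairs), x$minimum, x$median))
  }
  invisible(x)
}

#' k-mer distance ratio (KDR) between unmasked and masked runs
#'
#' Ratio of the minimal matched-pair distance computed on unmasked genomes
#' to the one computed on masked versions of the same genomes (same
#' chromosome sets, same k). Low-complexity regions removed by masking are
#' weakly constrained by selection and diverge fast, so masking reduces
#' inter-genome distances; the ratio aggregates that differential mutation
#' load and tracks evolutionary separation on both short and long scales.
#'
#' @param unmasked,masked [matched_pairs()] results from the unmasked and
#'   masked runs.
#' @return object of class `kdr_result`: list with `unmasked_min`,
#'   `masked_min` and their ratio `kdr`.
#' @export
kdr <- function(unmasked, masked) {
  stopifnot(inherits(unmasked, "match_result"), inherits(masked, "match_result"))
  if (unmasked$status != "ok" || masked$status != "ok") {
    stop("empty match result: cannot form a KDR")
  }
  if (masked$minimum <= 0) stop("ratio undefined (identical masked genomes)")
  structure(
    list(unmasked_min = unmasked$minimum, masked_min = masked$minimum,
         kdr = unmasked$minimum / masked$minimum),
    class = "kdr_result"
  )
}

#' @export
print.kdr_result <- function(x, ...) {
  cat(sprintf("<kdr_result> unmasked %.6g / masked %.6g = KDR %.4g\n",
              x$unmasked_min, x$masked_min, x$kdr))
  invisible(x)
}

#' Pearson correlation of distances against proximities
#'
#' Product-moment correlation with its two-sided p-value, for relating a
#' vector of k-mer distances (one per strain pair) to the matching synteny
#' proximities. Strongly negative correlations indicate that small k-mer
#' distances go with large shared-synteny fractions, i.e. that the k-mer
#' distances behave as evolutionary distances.
#'
#' @param distances,proximities numeric vectors of equal length >= 3, no
#'   missing values, neither constant.
#' @return list with `r` (correlation coefficient), `p_value` and `n`.
#' @export
correlate <- function(distances, proximities) {
  if (length(distances) != length(proximities)) {
    stop("distance and proximity vectors must have equal length")
  }
  if (length(distances) < 3L) stop("need at least 3 observations")
  if (anyNA(distances) || anyNA(proximities)) stop("missing values not allowed")
  if (stats::sd(distances) == 0 || stats::sd(proximities) == 0) {
    stop("constant input vector: correlation undefined")
  }
  ct <- stats::cor.test(distances, proximities, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(distances))
}

#' Write a distance matrix as TSV with row and column headers
#'
#' @param matrix a `kmer_distance_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "kmer_distance_matrix"))
  df <- data.frame(id = matrix$row_ids, matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a match result as TSV plus a JSON summary
#'
#' The TSV lists the selected pairs (rank, row id, column id, distance); the
#' JSON records `minimum`, `median` and `n_pairs`.
#'
#' @param result a `match_result`.
#' @param tsv_path,json_path output file paths (either may be `NULL` to
#'   skip).
#' @return `result`, invisibly.
#' @export
write_match_result <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "match_result"))
  if (!is.null(tsv_path)) {
    df <- cbind(rank = seq_len(nrow(result$pairs)), result$pairs)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(minimum = result$minimum, median = result$median,
           n_pairs = nrow(result$pairs), status = result$status),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
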