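#' Parse a 12-column tabular alignment file
#'
#' Reads the standard tabular local-alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, tab-separated, the BLAST "outfmt 6" dialect). Query
#' coordinates are always forward (`qstart <= qend`); a subject interval
#' with `sstart > send` marks a reverse-orientation hit. Coordinates are
#' 1-based inclusive and preserved as read.
#'
#' @param path path to the tab-separated table.
#' @return data frame of hits with the standard column names (empty for an
#'   empty file).
#' @export
parse_alignment_table <- function(path) {
  stopifnot(file.exists(path))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- stats::setNames(
    data.frame(character(), character(), numeric(), integer(), integer(),
               integer(), integer(), integer(), integer(), integer(),
               numeric(), numeric(), stringsAsFactors = FALSE), cols)
  if (length(lines) == 0L) return(empty)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d", i, nf[i]))
  }
  df <- read.delim(text = lines, header = FALSE, col.names = cols,
                   colClasses = "character", stringsAsFactors = FALSE)
  num_cols <- cols[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      stop(sprintf("line %d: non-numeric value '%s' in column %s",
                   which(is.na(v))[1L], df[[cc]][which(is.na(v))[1L]], cc))
    }
    df[[cc]] <- v
  }
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  if (any(df$qstart > df$qend)) {
    stop(sprintf("line %d: qstart > qend (query coordinates must be forward)",
                 which(df$qstart > df$qend)[1L]))
  }
  df
}

#' Extract synteny blocks from alignment hits
#'
#' Keeps hits whose identity percentage is strictly greater than
#' `identity_threshold` (the default 90 demands high similarity between the
#' compared chromosomes; the exact value is a convention, not a tuned
#' quantity) and whose alignment length is at least `min_block_length`.
#' Each surviving hit becomes a synteny block on the query chromosome:
#' a direct block (same strand in both genomes, `sstart < send`) or an
#' inverse block (opposite strands, `sstart > send`).
#'
#' @param hits data frame from [parse_alignment_table()].
#' @param identity_threshold percent identity cutoff (strict `>`).
#' @param min_block_length minimum alignment length to keep (default 0: no
#'   length filter).
#' @return data frame with columns `start`, `end` (1-based inclusive, query
#'   coordinates), `identity_pct` and `orientation` (`"direct"`/`"inverse"`).
#' @export
extract_blocks <- function(hits, identity_threshold = 90, min_block_length = 0L) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 100,
            min_block_length >= 0)
  keep <- hits$pident > identity_threshold & hits$length >= min_block_length
  hits <- hits[keep, , drop = FALSE]
  out <- data.frame(
    start = hits$qstart, end = hits$qend,
    identity_pct = hits$pident,
    orientation = ifelse(hits$sstart > hits$send, "inverse", "direct"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$start, out$end), , drop = FALSE]
}

# total bases covered by [start, end] intervals, optionally unioned first
.covered_length <- function(blocks, merge) {
  if (nrow(blocks) == 0L) return(0L)
  if (merge) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(blocks$start, blocks$end))))
  } else {
    sum(blocks$end - blocks$start + 1L)
  }
}

#' Synteny proximities between two chromosomes
#'
#' Computes the total covered lengths of direct and inverse synteny blocks
#' (`L_DSB`, `L_ISB`) and the proximities
#' `P_DSYN = L_DSB / min(L1, L2)` and
#' `P_SYN = (L_DSB + L_ISB) / min(L1, L2)`.
#' Block intervals are expected on the shorter chromosome (the usual query
#' choice), so that coverage and the denominator refer to the same
#' sequence. By default overlapping intervals are merged within each
#' orientation class before summing, preventing repeated alignment segments
#' from being double-counted; set `merge_overlaps = FALSE` for the raw sum.
#'
#' @param blocks data frame from [extract_blocks()] or [true_blocks()].
#' @param length_1,length_2 lengths of the two compared chromosomes (>= 1).
#' @param merge_overlaps union intervals within each orientation class
#'   before measuring coverage.
#' @param id_1,id_2 optional chromosome identifiers carried into the result.
#' @return object of class `proximity_result`: list with `l_dsb`, `l_isb`,
#'   `min_length`, `p_dsyn`, `p_syn`, `id_1`, `id_2`.
#' @examples
#' b <- data.frame(start = c(1, 501), end = c(1000, 1500),
#'                 identity_pct = 99, orientation = "direct")
#' proximities(b, 10000, 12000)$p_dsyn  # 0.15
#' @export
proximities <- function(blocks, length_1, length_2, merge_overlaps = TRUE,
                        id_1 = "", id_2 = "") {
  if (length_1 < 1 || length_2 < 1) stop("chromosome lengths must be >= 1")
  direct <- blocks[blocks$orientation == "direct", , drop = FALSE]
  inverse <- blocks[blocks$orientation == "inverse", , drop = FALSE]
  l_dsb <- .covered_length(direct, merge_overlaps)
  l_isb <- .covered_length(inverse, merge_overlaps)
  min_length <- min(length_1, length_2)
  structure(
    list(id_1 = id_1, id_2 = id_2, l_dsb = l_dsb, l_isb = l_isb,
         min_length = min_length,
         p_dsyn = l_dsb / min_length,
         p_syn = (l_dsb + l_isb) / min_length),
    class = "proximity_result"
  )
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity_result> %s vs %s: L_DSB=%d L_ISB=%d / %d; P_DSYN=%.4f P_SYN=%.4f\n",
              x$id_1, x$id_2, x$l_dsb, x$l_isb, x$min_length,
              x$p_dsyn, x$p_syn))
  invisible(x)
}

#' Run the external aligner on two genomes
#'
#' Optional convenience hook that invokes `blastn` (pairwise mode, tabular
#' 12-column output) with the shorter genome as query and the longer as
#' subject, so that downstream block coordinates live on the shorter
#' sequence as [proximities()] expects. Every downstream stage also accepts
#' a pre-computed table through [parse_alignment_table()], so the external
#' tool is never required.
#'
#' @param fasta_1,fasta_2 paths to the two genome FASTA files.
#' @param work_dir directory for the output table.
#' @param aligner executable name (default `"blastn"`).
#' @return path to the tabular output file.
#' @export
run_aligner <- function(fasta_1, fasta_2, work_dir = tempdir(),
                        aligner = "blastn") {
  exe <- Sys.which(aligner)
  if (!nzchar(exe)) {
    stop(sprintf(paste0("external tool missing: '%s' not found on PATH; ",
                        "run the aligner yourself and load its tabular output ",
                        "with parse_alignment_table()"), aligner))
  }
  len <- function(p) sum(vapply(read_fasta(p, "raw"), `[[`, numeric(1), "length"))
  if (len(fasta_1) <= len(fasta_2)) {
    query <- fasta_1; subject <- fasta_2
  } else {
    query <- fasta_2; subject <- fasta_1
  }
  out <- file.path(work_dir, "alignment_hits.tsv")
  status <- system2(exe, c("-query", shQuote(query), "-subject", shQuote(subject),
                           "-outfmt", "6", "-out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) {
    if (file.exists(out)) unlink(out)
    stop(sprintf("%s exited with status %d", aligner, status))
  }
  out
}

#' Write synteny blocks as BED-like TSV
#'
#' Columns: chromosome, start (0-based, half-open — converted from the
#' package's 1-based inclusive intervals), end, orientation, identity. The
#' half-open convention means `end - start` equals the block length.
#'
#' @param blocks data frame of blocks.
#' @param chrom chromosome name for the first column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, chrom, path) {
  df <- data.frame(chrom = chrom, start = blocks$start - 1L, end = blocks$end,
                   orientation = blocks$orientation,
                   identity = blocks$identity_pct, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a proximity result as a TSV row
#'
#' @param result a `proximity_result`.
#' @param path output file path.
#' @param append append to an existing table instead of writing a header.
#' @return `path`, invisibly.
#' @export
write_proximity_tsv <- function(result, path, append = FALSE) {
  df <- data.frame(id_1 = result$id_1, id_2 = result$id_2,
                   L_DSB = result$l_dsb, L_ISB = result$l_isb,
                   min_length = result$min_length,
                   P_DSYN = result$p_dsyn, P_SYN = result$p_syn,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !append, append = append)
  invisible(path)
}
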