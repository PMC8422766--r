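#' Construct a genome record
#'
#' A `genome_record` holds one chromosomal sequence together with its id and
#' the masking mode it was loaded under. Sequences are plain character
#' strings over `A,C,G,T,N` plus lowercase `a,c,g,t,n` for soft-masked
#' (low-complexity / repeat) bases.
#'
#' @param id chromosome identifier (first whitespace-delimited FASTA header
#'   token when read from file).
#' @param sequence nucleotide string.
#' @param masking_mode one of `"raw"`, `"unmasked"`, `"masked"`.
#' @return an object of class `genome_record` with fields `id`, `sequence`,
#'   `length` and `masking_mode`.
#' @seealso [read_fasta()], [apply_masking()]
#' @export
genome_record <- function(id, sequence, masking_mode = "raw") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  masking_mode <- match.arg(masking_mode, c("raw", "unmasked", "masked"))
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         masking_mode = masking_mode),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp (%s)\n", x$id, x$length,
              x$masking_mode))
  invisible(x)
}

# map IUPAC ambiguity codes (and any other stray letter) to N, warning once
.sanitize_alphabet <- function(s, id) {
  n_other <- nchar(gsub("[ACGTN]", "", s))
  if (n_other > 0L) {
    message(sprintf("%s: %d non-ACGTN character(s) mapped to N", id, n_other))
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

#' Apply a masking mode to a genome record
#'
#' Masking semantics unify soft masking (lowercase) and hard masking (N):
#' \describe{
#'   \item{`raw`}{sequence kept verbatim.}
#'   \item{`unmasked`}{all letters uppercased; soft-masked bases are treated
#'     as ordinary sequence.}
#'   \item{`masked`}{every lowercase (soft-masked) base is replaced by `N`,
#'     then the result is uppercased, so masked tracts are excluded from
#'     k-mer windows exactly like hard-masked ones.}
#' }
#' In the `unmasked` and `masked` modes any residual non-ACGTN letter
#' (IUPAC ambiguity codes) is mapped to `N` with a logged count; the k-mer
#' distance definitions assume a four-letter alphabet. Masking never changes
#' coordinates: the record length is preserved.
#'
#' @param record a [genome_record()].
#' @param masking_mode `"raw"`, `"unmasked"` or `"masked"`.
#' @return a `genome_record` with the transformation applied.
#' @examples
#' r <- genome_record("chr", "acgtACGT")
#' apply_masking(r, "masked")$sequence   # "NNNNACGT"
#' @export
apply_masking <- function(record, masking_mode = c("raw", "unmasked", "masked")) {
  masking_mode <- match.arg(masking_mode)
  s <- record$sequence
  if (masking_mode == "unmasked") {
    s <- .sanitize_alphabet(toupper(s), record$id)
  } else if (masking_mode == "masked") {
    s <- .sanitize_alphabet(toupper(gsub("[a-z]", "N", s)), record$id)
  }
  genome_record(record$id, s, masking_mode)
}

#' Read chromosomal sequences from a FASTA file
#'
#' Reads a (plain or gzip-compressed) FASTA file into a list of
#' [genome_record()] objects, one per entry, in file order. The record id is
#' the first whitespace-delimited token after `>`. Case is preserved on
#' input so that soft masking information survives, then the requested
#' masking mode is applied (see [apply_masking()]).
#'
#' @param path path to a FASTA file, optionally gzip-compressed.
#' @param masking_mode `"raw"` (verbatim), `"unmasked"` (uppercase
#'   everything) or `"masked"` (lowercase -> `N`, then uppercase).
#' @param min_length drop entries shorter than this many bases. Useful as a
#'   proxy for excluding unplaced scaffolds and alt contigs from
#'   per-chromosome analyses.
#' @return list of `genome_record`s (possibly empty, with a warning, for an
#'   empty file).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_fasta(fa, "masked")[[1]]$sequence  # "NNNNACGT"
#' @export
read_fasta <- function(path, masking_mode = c("raw", "unmasked", "masked"),
                       min_length = 0L) {
  masking_mode <- match.arg(masking_mode)
  stopifnot(file.exists(path), min_length >= 0)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L) {
    warning(sprintf("empty FASTA file: %s", path))
    return(list())
  }
  if (!startsWith(trimws(first[nonblank[1L]]), ">")) {
    stop(sprintf("malformed FASTA (%s): sequence line before first header at line %d",
                 path, nonblank[1L]))
  }
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "DNA")
  recs <- lapply(seq_along(seqs), function(i) {
    r <- genome_record(names(seqs)[i], as.character(seqs[[i]]), "raw")
    apply_masking(r, masking_mode)
  })
  recs[vapply(recs, function(r) r$length >= min_length, logical(1))]
}

#' Write genome records to a FASTA file
#'
#' Case (soft masking) is preserved as stored in the records.
#'
#' @param records a `genome_record` or list of them.
#' @param path output file path.
#' @param width line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqinr::write.fasta(
    sequences = lapply(records, function(r) r$sequence),
    names = vapply(records, function(r) r$id, character(1)),
    file.out = path, as.string = TRUE, nbchar = width
  )
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Returns the sequence of the opposite strand read 5' to 3'. `N`
#' self-complements. The operation is an involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param s string over `A,C,G,T,N` (uppercase).
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("AAGT")  # "ACTT"
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(s, bad, bad), bad))
  }
  if (nchar(s) == 0L) return(s)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}
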