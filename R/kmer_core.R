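#' Count k-mers along a single strand
#'
#' Slides a window of length `k` along the given strand (read 5' to 3') and
#' counts every one of the 4^k possible k-mers, in lexicographic order over
#' the alphabet A < C < G < T. Windows containing any non-ACGT base (hard- or
#' soft-masked positions converted to `N`, ambiguity codes) contribute
#' nothing and are tallied separately in `skipped_windows`. Counting is
#' case-insensitive: soft-masked lowercase bases count as ordinary bases
#' unless the record was loaded in `masked` mode, which replaces them by `N`.
#'
#' The number of windows is `N = L - k + 1` for a linear sequence. For
#' bacterial chromosomes a circular scan is available: `circular = TRUE`
#' appends the first `k - 1` bases so that `N = L`. The default is linear.
#'
#' @param record a [genome_record()] (or a plain nucleotide string).
#' @param k word length, between 1 and 12. The 4^k count table must fit in
#'   memory; above the advisory [kl_limit()] the computation is still
#'   performed, since inversion-symmetry failure beyond that point is a
#'   statistical statement, not a hard bound.
#' @param circular append the first `k - 1` bases to close the scan over the
#'   origin of a circular chromosome.
#' @return an object of class `kmer_spectrum`: list with `k`, `counts`
#'   (named integer vector of length 4^k), `total_valid` (number of
#'   all-ACGT windows, the frequency denominator), `skipped_windows` and
#'   `source_id`.
#' @examples
#' s <- count_kmers(genome_record("x", "ACGT"), 1)
#' s$counts          # A=1 C=1 G=1 T=1
#' s$total_valid     # 4
#' @export
count_kmers <- function(record, k, circular = FALSE) {
  if (is.character(record)) record <- genome_record("seq", record)
  stopifnot(inherits(record, "genome_record"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 12L) {
    stop("k must be a single integer between 1 and 12")
  }
  L <- record$length
  if (k > L) stop(sprintf("sequence shorter than k (%d < %d)", L, k))
  s <- toupper(record$sequence)
  if (circular && k > 1L) s <- paste0(s, substr(s, 1L, k - 1L))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                 width = k)
  n_windows <- if (circular) L else max(L - k + 1L, 0L)
  total_valid <- sum(counts)
  structure(
    list(k = k, counts = counts, total_valid = total_valid,
         skipped_windows = n_windows - total_valid,
         source_id = record$id),
    class = "kmer_spectrum"
  )
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> %s: k=%d, %d valid windows, %d skipped, %.1f%% k-mers missing\n",
              x$source_id, x$k, x$total_valid, x$skipped_windows,
              100 * missing_fraction(x)))
  invisible(x)
}

#' Single-strand k-mer frequencies
#'
#' Empirical frequency of each k-mer: its count divided by the number of
#' valid (all-ACGT) windows. Dividing by the valid-window total rather than
#' by `L - k + 1` keeps the frequencies summing to 1 in the presence of
#' masked bases, so distances stay within \[0, 2\] for masked genomes too;
#' for an unmasked pure-ACGT sequence the two denominators coincide.
#'
#' @param spectrum a [count_kmers()] result with `total_valid > 0`.
#' @return object of class `kmer_frequencies`: list with `k`, `freqs`
#'   (sums to 1) and `combined = FALSE`.
#' @export
kmer_frequencies <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (spectrum$total_valid <= 0L) stop("no valid k-mer windows")
  structure(
    list(k = spectrum$k, freqs = spectrum$counts / spectrum$total_valid,
         combined = FALSE, source_id = spectrum$source_id),
    class = "kmer_frequencies"
  )
}

# permutation p with p[i] = 1-based rank of reverse_complement(kmer_i),
# computed arithmetically in base 4 (A=0, C=1, G=2, T=3) and cached per k
.rc_permutation <- function(k) {
  key <- paste0("rc", k)
  if (!is.null(.kmerdist_cache[[key]])) return(.kmerdist_cache[[key]])
  x <- 0:(4^k - 1)
  r <- numeric(length(x))
  for (t in seq_len(k)) {
    r <- r * 4 + (3 - x %% 4)
    x <- x %/% 4
  }
  p <- as.integer(r + 1)
  .kmerdist_cache[[key]] <- p
  p
}

#' Strand-symmetrized (combined) k-mer frequencies
#'
#' For each k-mer m adds the frequency of its reverse complement M, giving
#' the frequency vector seen when both strands of the chromosome are read 5'
#' to 3'. Entries sum to 2 (each single-strand frequency is counted twice
#' across the pairing); a palindromic k-mer's entry equals twice its
#' single-strand frequency.
#'
#' @inheritParams kmer_frequencies
#' @return object of class `kmer_frequencies` with `combined = TRUE`
#'   (entries sum to 2).
#' @export
combined_frequencies <- function(spectrum) {
  f <- kmer_frequencies(spectrum)
  p <- .rc_permutation(spectrum$k)
  comb <- f$freqs + f$freqs[p]
  names(comb) <- names(f$freqs)
  structure(
    list(k = spectrum$k, freqs = comb, combined = TRUE,
         source_id = spectrum$source_id),
    class = "kmer_frequencies"
  )
}

.check_pair <- function(spec_1, spec_2) {
  stopifnot(inherits(spec_1, "kmer_spectrum"), inherits(spec_2, "kmer_spectrum"))
  if (spec_1$k != spec_2$k) {
    stop(sprintf("mismatched k: %d vs %d", spec_1$k, spec_2$k))
  }
  if (spec_1$total_valid <= 0L || spec_2$total_valid <= 0L) {
    stop("no valid k-mer windows")
  }
}

.distance_result <- function(spec_1, spec_2, measure, value) {
  structure(
    list(k = spec_1$k, measure = measure, value = value,
         id_1 = spec_1$source_id, id_2 = spec_2$source_id,
         missing_fraction_1 = missing_fraction(spec_1),
         missing_fraction_2 = missing_fraction(spec_2)),
    class = "kmer_distance"
  )
}

#' Single-strand k-mer distance D1
#'
#' L1 norm of the difference between the single-strand k-mer frequency
#' vectors of two chromosomes:
#' `D1 = sum_i |f_i(S1) - f_i(S2)|` over all 4^k k-mers. D1 compares one
#' strand of each chromosome; it is zero when the two strands have identical
#' k-mer frequencies, including the case where one is the reverse complement
#' of the other (inversion symmetry). Values lie in \[0, 2\].
#'
#' @param spec_1,spec_2 [count_kmers()] spectra with equal `k`.
#' @return object of class `kmer_distance` with fields `k`, `measure`,
#'   `value`, `id_1`, `id_2` and the two missing-k-mer fractions.
#' @examples
#' a <- count_kmers(genome_record("a", "ACGT"), 1)
#' b <- count_kmers(genome_record("b", "AAAA"), 1)
#' d1(a, b)$value  # 1.5
#' @export
d1 <- function(spec_1, spec_2) {
  .check_pair(spec_1, spec_2)
  f1 <- kmer_frequencies(spec_1)$freqs
  f2 <- kmer_frequencies(spec_2)$freqs
  .distance_result(spec_1, spec_2, "D1", sum(abs(f1 - f2)))
}

#' Double-strand k-mer distance D2
#'
#' L1 norm of the difference between the strand-symmetrized frequency
#' vectors (see [combined_frequencies()]), divided by 2 because reading both
#' strands doubles the effective number of counts:
#' `D2 = sum_i |f_i(S1) + F_i(S1) - f_i(S2) - F_i(S2)| / 2`, with `F_i` the
#' frequency of the reverse complement of k-mer i. D2 is independent of the
#' (arbitrary) strand choice for each chromosome and is insensitive to
#' segmental inversions, which only perturb the windows straddling the
#' breakpoints. Always `D2 <= D1`; values lie in \[0, 2\].
#'
#' @inheritParams d1
#' @return a `kmer_distance` object with `measure = "D2"`.
#' @examples
#' a <- count_kmers(genome_record("a", "ACGT"), 1)
#' b <- count_kmers(genome_record("b", "AAAA"), 1)
#' d2(a, b)$value  # 1.0
#' @export
d2 <- function(spec_1, spec_2) {
  .check_pair(spec_1, spec_2)
  c1 <- combined_frequencies(spec_1)$freqs
  c2 <- combined_frequencies(spec_2)$freqs
  .distance_result(spec_1, spec_2, "D2", sum(abs(c1 - c2)) / 2)
}

#' @export
print.kmer_distance <- function(x, ...) {
  cat(sprintf("<kmer_distance> %s(k=%d) %s vs %s = %.6g\n",
              x$measure, x$k, x$id_1, x$id_2, x$value))
  invisible(x)
}

#' Fraction of missing k-mers
#'
#' Proportion of the 4^k possible k-mers that never occur on the strand
#' (count zero). A diagnostic for whether `k` is small enough relative to
#' the chromosome length for distance comparisons to be meaningful: the
#' monotonicity of the distances in `k` is only guaranteed while all k-mers
#' are realized.
#'
#' @param spectrum a [count_kmers()] result.
#' @return fraction in \[0, 1\].
#' @export
missing_fraction <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  mean(spectrum$counts == 0L)
}

#' Advisory upper k for inversion-symmetry-based comparisons
#'
#' Heuristic limit `KL = floor(0.7 * ln(L))` with `L` the length of the
#' shorter chromosome, derived from the empirical logarithmic growth of the
#' largest k at which inversion symmetry holds within 10%. Advisory only:
#' all operations accept any k in \[1, 12\]. Note the heuristic can exceed
#' the k values typically quoted for bacteria (7-8); it should be read as an
#' upper bound on sensible k, not a recommendation.
#'
#' @param length_1,length_2 chromosome lengths (>= 2).
#' @return integer advisory limit.
#' @examples
#' kl_limit(4639675, 4639675)  # 10
#' @export
kl_limit <- function(length_1, length_2) {
  if (length_1 < 2 || length_2 < 2) stop("chromosome lengths must be >= 2")
  # small epsilon guards floor() against representation error at integers
  as.integer(floor(0.7 * log(min(length_1, length_2)) + 1e-9))
}

#' Export / import a k-mer spectrum as TSV
#'
#' Two-column table (`kmer`, `count`) preceded by `#`-prefixed header lines
#' recording `k`, `total_valid`, `skipped_windows` and `source_id`, so a
#' spectrum round-trips exactly.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_spectrum_tsv` returns the spectrum.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#k=%d", spectrum$k),
               sprintf("#total_valid=%d", spectrum$total_valid),
               sprintf("#skipped_windows=%d", spectrum$skipped_windows),
               sprintf("#source_id=%s", spectrum$source_id),
               "kmer\tcount"), con)
  writeLines(paste(names(spectrum$counts), spectrum$counts, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- sub("^#", "", hdr)
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  tab <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                    stringsAsFactors = FALSE)
  counts <- as.integer(tab$count)
  names(counts) <- tab$kmer
  structure(
    list(k = as.integer(vals[["k"]]), counts = counts,
         total_valid = as.integer(vals[["total_valid"]]),
         skipped_windows = as.integer(vals[["skipped_windows"]]),
         source_id = vals[["source_id"]]),
    class = "kmer_spectrum"
  )
}

#' Serialize distance results as TSV rows
#'
#' @param distances a `kmer_distance` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(distances, path) {
  if (inherits(distances, "kmer_distance")) distances <- list(distances)
  df <- do.call(rbind, lapply(distances, function(d) {
    data.frame(id_1 = d$id_1, id_2 = d$id_2, k = d$k, measure = d$measure,
               value = d$value, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
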