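#' Describe a synthetic genome-evolution scenario
#'
#' Bundles the parameters of the generator: an ancestor composition, a
#' per-site substitution rate, a number of non-overlapping segmental
#' inversions with a length range, and optionally low-complexity tracts
#' (tandem repeats, emitted soft-masked) with their own count and length
#' range. Identical seeds reproduce identical outputs bit for bit.
#'
#' @param ancestor_length ancestor sequence length (>= 1).
#' @param base_composition probabilities for A, C, G, T; must sum to 1.
#' @param substitution_rate per-site substitution probability in \[0, 1).
#' @param n_inversions number of non-overlapping segmental inversions.
#' @param inversion_length_range integer pair (min, max) inversion length.
#' @param n_low_complexity_tracts number of low-complexity tracts for
#'   [plant_low_complexity()].
#' @param tract_length_range integer pair (min, max) tract length.
#' @param seed RNG seed controlling every random draw of the scenario.
#' @return object of class `evolution_scenario`.
#' @export
evolution_scenario <- function(ancestor_length,
                               base_composition = c(0.25, 0.25, 0.25, 0.25),
                               substitution_rate = 0,
                               n_inversions = 0L,
                               inversion_length_range = c(1000L, 10000L),
                               n_low_complexity_tracts = 0L,
                               tract_length_range = c(500L, 2000L),
                               seed = 1L) {
  stopifnot(ancestor_length >= 1,
            length(base_composition) == 4L, all(base_composition >= 0),
            abs(sum(base_composition) - 1) <= 1e-9,
            substitution_rate >= 0, substitution_rate < 1,
            n_inversions >= 0L,
            length(inversion_length_range) == 2L,
            inversion_length_range[1] >= 1L,
            inversion_length_range[1] <= inversion_length_range[2],
            n_low_complexity_tracts >= 0L,
            length(tract_length_range) == 2L,
            tract_length_range[1] >= 1L,
            tract_length_range[1] <= tract_length_range[2],
            seed == as.integer(seed))
  structure(
    list(ancestor_length = as.integer(ancestor_length),
         base_composition = base_composition,
         substitution_rate = substitution_rate,
         n_inversions = as.integer(n_inversions),
         inversion_length_range = as.integer(inversion_length_range),
         n_low_complexity_tracts = as.integer(n_low_complexity_tracts),
         tract_length_range = as.integer(tract_length_range),
         seed = as.integer(seed)),
    class = "evolution_scenario"
  )
}

#' Draw a random genome
#'
#' I.i.d. draws from the given base composition; a pure function of
#' `(length, base_composition, seed)`.
#'
#' @param length sequence length (>= 1).
#' @param base_composition probabilities for A, C, G, T summing to 1.
#' @param seed RNG seed.
#' @param id record identifier.
#' @return a [genome_record()].
#' @export
random_genome <- function(length, base_composition = c(0.25, 0.25, 0.25, 0.25),
                          seed = 1L, id = "synthetic") {
  stopifnot(length >= 1, length(base_composition) == 4L,
            all(base_composition >= 0),
            abs(sum(base_composition) - 1) <= 1e-9)
  s <- withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = base_composition), collapse = ""))
  genome_record(id, s, "raw")
}

# rejection-sample n non-overlapping [start, end] segments with lengths in
# len_range on a sequence of seq_length bases; draws from the current RNG
.sample_nonoverlapping <- function(seq_length, n, len_range,
                                   max_tries = 200L * max(n, 1L)) {
  starts <- integer(0); ends <- integer(0)
  tries <- 0L
  while (length(starts) < n) {
    if (tries >= max_tries) {
      stop(sprintf(paste0("could not place %d non-overlapping segments of ",
                          "length %d-%d on %d bases after %d tries; ",
                          "request fewer or shorter segments"),
                   n, len_range[1], len_range[2], seq_length, max_tries))
    }
    tries <- tries + 1L
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(len_range[1]:len_range[2], 1L)
    if (len > seq_length) next
    a <- sample.int(seq_length - len + 1L, 1L)
    b <- a + len - 1L
    if (any(a <= ends & b >= starts)) next
    starts <- c(starts, a); ends <- c(ends, b)
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
# alternatives[b, j]: the j-th base different from b
.ALTERNATIVES <- t(vapply(.BASES, function(b) setdiff(.BASES, b),
                          character(3)))

.ground_truth <- function(inverted = NULL, substituted = integer(0),
                          masked = NULL) {
  empty <- data.frame(start = integer(0), end = integer(0))
  structure(
    list(inverted_intervals = if (is.null(inverted)) empty else inverted,
         substituted_positions = substituted,
         masked_intervals = if (is.null(masked)) empty else masked),
    class = "ground_truth"
  )
}

#' Evolve a descendant strain from an ancestor
#'
#' Applies the scenario's segmental inversions (each segment replaced in
#' place by its reverse complement) followed by i.i.d. point substitutions
#' (each hit site redrawn uniformly among the three other bases), and
#' returns the descendant together with exact ground truth. Substitutions
#' are applied after the inversions, so all ground-truth positions live on
#' the descendant coordinate system. Inversion segments are sampled without
#' overlap by rejection; `N` positions are never substituted.
#'
#' With no substitutions, an inversion conserves the strand-symmetrized
#' k-mer content except in the windows straddling its two breakpoints —
#' the mechanism that keeps the D2 distance essentially blind to
#' rearrangements by inversion.
#'
#' @param ancestor a [genome_record()] over A, C, G, T, N (uppercase).
#' @param scenario an [evolution_scenario()].
#' @return list with `descendant` (a `genome_record`) and `truth` (class
#'   `ground_truth`: `inverted_intervals`, `substituted_positions`,
#'   `masked_intervals`).
#' @export
evolve_strain <- function(ancestor, scenario) {
  stopifnot(inherits(ancestor, "genome_record"),
            inherits(scenario, "evolution_scenario"))
  withr::with_seed(scenario$seed, {
    chars <- strsplit(ancestor$sequence, "", fixed = TRUE)[[1]]
    L <- length(chars)
    inv <- if (scenario$n_inversions > 0L) {
      .sample_nonoverlapping(L, scenario$n_inversions,
                             scenario$inversion_length_range)
    } else {
      data.frame(start = integer(0), end = integer(0))
    }
    for (i in seq_len(nrow(inv))) {
      seg <- chars[inv$start[i]:inv$end[i]]
      chars[inv$start[i]:inv$end[i]] <- rev(unname(.COMPLEMENT[seg]))
    }
    sub_pos <- integer(0)
    if (scenario$substitution_rate > 0) {
      eligible <- which(chars %in% .BASES)
      hit <- eligible[runif(length(eligible)) < scenario$substitution_rate]
      if (length(hit) > 0L) {
        pick <- sample.int(3L, length(hit), replace = TRUE)
        chars[hit] <- .ALTERNATIVES[cbind(match(chars[hit], .BASES), pick)]
        sub_pos <- sort(hit)
      }
    }
    descendant <- genome_record(paste0(ancestor$id, "_desc"),
                                paste(chars, collapse = ""), "raw")
    list(descendant = descendant,
         truth = .ground_truth(inverted = inv, substituted = sub_pos))
  })
}

#' Ground-truth synteny blocks from a simulated strain pair
#'
#' Converts the generator's exact event record into the synteny blocks an
#' aligner would report for the ancestor/descendant pair: unchanged
#' segments between inversion breakpoints become direct blocks, inverted
#' segments become inverse blocks, and each block's identity percentage is
#' `100 * (1 - substitutions inside block / block length)`, mirroring what
#' a local alignment of the corresponding segments would show.
#'
#' @param truth `ground_truth` from [evolve_strain()].
#' @param length sequence length the events act on.
#' @param min_block drop blocks shorter than this (default 0).
#' @return data frame of blocks (`start`, `end`, `identity_pct`,
#'   `orientation`) in the [extract_blocks()] format.
#' @export
true_blocks <- function(truth, length, min_block = 0L) {
  stopifnot(inherits(truth, "ground_truth"), length >= 1)
  inv <- truth$inverted_intervals
  inv <- inv[order(inv$start), , drop = FALSE]
  dir_start <- c(1L, inv$end + 1L)
  dir_end <- c(inv$start - 1L, as.integer(length))
  keep <- dir_end >= dir_start
  blocks <- rbind(
    data.frame(start = dir_start[keep], end = dir_end[keep],
               orientation = rep("direct", sum(keep)),
               stringsAsFactors = FALSE),
    data.frame(start = inv$start, end = inv$end,
               orientation = rep("inverse", nrow(inv)),
               stringsAsFactors = FALSE)
  )
  subs <- truth$substituted_positions
  n_in <- vapply(seq_len(nrow(blocks)), function(i) {
    sum(subs >= blocks$start[i] & subs <= blocks$end[i])
  }, numeric(1))
  len <- blocks$end - blocks$start + 1L
  blocks$identity_pct <- 100 * (1 - n_in / len)
  blocks <- blocks[len >= min_block, c("start", "end", "identity_pct",
                                       "orientation")]
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

# fill the given tracts with tandem repeats of fresh random 1-3-mer motifs,
# lowercased (soft-masked); draws from the current RNG stream
.fill_tracts <- function(chars, tracts) {
  for (i in seq_len(nrow(tracts))) {
    a <- tracts$start[i]; b <- tracts$end[i]
    motif <- sample(.BASES, sample.int(3L, 1L), replace = TRUE)
    chars[a:b] <- tolower(rep_len(motif, b - a + 1L))
  }
  chars
}

#' Plant soft-masked low-complexity tracts in a genome
#'
#' Overwrites sampled non-overlapping tracts with short tandem repeats
#' (random 1-3-mer motifs) and emits them lowercase, so that loading the
#' result in `masked` mode (see [apply_masking()]) removes exactly those
#' tracts while `unmasked` mode keeps them. This emulates the
#' low-complexity fraction of eukaryotic genomes, which diverges rapidly
#' because it is weakly constrained by selection, and makes the
#' masked/unmasked contrast behind the KDR statistic testable.
#'
#' @param genome a [genome_record()].
#' @param scenario an [evolution_scenario()] supplying
#'   `n_low_complexity_tracts`, `tract_length_range` and `seed`.
#' @param tracts optional data frame (`start`, `end`) of pre-chosen tract
#'   intervals; when supplied only the repeat content is drawn, which lets
#'   related strains share tract positions while diverging in tract
#'   content.
#' @return list with `genome` (soft-masked `genome_record`) and `truth`
#'   (`ground_truth` whose `masked_intervals` are the planted tracts).
#' @export
plant_low_complexity <- function(genome, scenario, tracts = NULL) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(scenario, "evolution_scenario"))
  withr::with_seed(scenario$seed, {
    if (is.null(tracts)) {
      if (scenario$n_low_complexity_tracts == 0L) {
        return(list(genome = genome, truth = .ground_truth()))
      }
      tracts <- .sample_nonoverlapping(genome$length,
                                       scenario$n_low_complexity_tracts,
                                       scenario$tract_length_range)
    }
    stopifnot(all(tracts$start >= 1L), all(tracts$end <= genome$length),
              all(tracts$start <= tracts$end))
    chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
    chars <- .fill_tracts(chars, tracts)
    list(genome = genome_record(genome$id, paste(chars, collapse = ""), "raw"),
         truth = .ground_truth(masked = tracts))
  })
}

#' Write ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(inverted_intervals = truth$inverted_intervals,
         substituted_positions = truth$substituted_positions,
         masked_intervals = truth$masked_intervals),
    path, digits = NA)
  invisible(path)
}
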