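# Independent brute-force oracles used to cross-check the package's
# rank-encoded implementations. Deliberately naive: substring maps keyed by
# k-mer strings, no lexicographic rank arithmetic.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# local string reverse complement (independent of the package's)
oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# named frequency vector of the k-mers actually observed (ACGT windows only)
oracle_freqs <- function(s, k) {
  L <- nchar(s)
  words <- substring(s, 1:(L - k + 1), k:L)
  words <- words[!grepl("[^ACGT]", words)]
  tab <- table(words)
  as.numeric(tab / sum(tab)) |> stats::setNames(names(tab))
}

.lookup0 <- function(f, keys) {
  v <- f[keys]
  v[is.na(v)] <- 0
  unname(v)
}

oracle_d1 <- function(s1, s2, k) {
  f1 <- oracle_freqs(s1, k)
  f2 <- oracle_freqs(s2, k)
  keys <- union(names(f1), names(f2))
  sum(abs(.lookup0(f1, keys) - .lookup0(f2, keys)))
}

oracle_d2 <- function(s1, s2, k) {
  f1 <- oracle_freqs(s1, k)
  f2 <- oracle_freqs(s2, k)
  keys <- union(names(f1), names(f2))
  keys <- union(keys, vapply(keys, oracle_rc, character(1)))
  rc_keys <- vapply(keys, oracle_rc, character(1))
  c1 <- .lookup0(f1, keys) + .lookup0(f1, rc_keys)
  c2 <- .lookup0(f2, keys) + .lookup0(f2, rc_keys)
  sum(abs(c1 - c2)) / 2
}

# sequence with exact inversion symmetry under a circular window scan:
# the circular concatenation x + rc(x) is invariant (up to rotation) under
# reverse complementation, so every k-mer count equals its inverse's count
exact_is_sequence <- function(half_length) {
  x <- random_dna(half_length)
  paste0(x, oracle_rc(x))
}

# literal step-by-step simulation of the matched-pair algorithm:
# drop edges above the threshold, then repeatedly take the minimal edge
# (ties broken lexicographically on row then column id) and delete both
# endpoint chromosomes, until the graph is exhausted
oracle_matched_pairs <- function(vals, threshold = 1) {
  rn <- rownames(vals); cn <- colnames(vals)
  edges <- expand.grid(i = seq_along(rn), j = seq_along(cn))
  edges$d <- vals[cbind(edges$i, edges$j)]
  edges <- edges[edges$d <= threshold, , drop = FALSE]
  vec <- numeric(0)
  pair_rows <- character(0); pair_cols <- character(0)
  while (nrow(edges) > 0L) {
    cand <- edges[edges$d == min(edges$d), , drop = FALSE]
    cand <- cand[order(rn[cand$i], cn[cand$j]), , drop = FALSE]
    e <- cand[1L, ]
    vec <- c(vec, e$d)
    pair_rows <- c(pair_rows, rn[e$i])
    pair_cols <- c(pair_cols, cn[e$j])
    edges <- edges[edges$i != e$i & edges$j != e$j, , drop = FALSE]
  }
  list(row_id = pair_rows, col_id = pair_cols, distance_vector = vec,
       minimum = if (length(vec)) vec[1L] else NA_real_,
       median = if (length(vec)) stats::median(vec) else NA_real_)
}

# matrix with all entries distinct, drawn (without replacement) from a grid
random_distinct_matrix <- function(nr, nc, grid) {
  m <- matrix(sample(grid, nr * nc), nr, nc,
              dimnames = list(paste0("r", seq_len(nr)),
                              paste0("c", seq_len(nc))))
  m
}

make_spectrum <- function(s, k, id = "seq", circular = FALSE) {
  count_kmers(genome_record(id, s), k, circular = circular)
}
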