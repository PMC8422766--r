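#' Simulate a cohort of diverged strain pairs
#'
#' Generates `n_pairs` independent ancestor/descendant pairs along a graded
#' divergence ladder: pair i receives substitution rate
#' `substitution_rates[i]` and `n_inversions[i]` segmental inversions, so
#' later pairs carry a heavier mutation load — the way longer separation
#' times accumulate both substitutions and rearrangements. For each pair
#' the D1 and D2 distances at the chosen `k` are computed between ancestor
#' and descendant, and the synteny proximities are computed from the
#' generator's ground-truth blocks filtered at the identity threshold
#' (blocks whose local substitution density pushes identity at or below the
#' threshold drop out, exactly as alignment-derived blocks would).
#'
#' The defaults emulate closely related bacterial strains at a reduced
#' scale: 100 kb chromosomes, substitution rates from 0.5% to 13% spanning
#' the 90%-identity cliff, and 1-10 inversions of 2-8 kb.
#'
#' @param n_pairs number of strain pairs.
#' @param ancestor_length chromosome length per pair.
#' @param substitution_rates per-pair substitution rates (length `n_pairs`).
#' @param n_inversions per-pair inversion counts (length `n_pairs`).
#' @param inversion_length_range (min, max) inversion length.
#' @param k word length for the distances.
#' @param identity_threshold strict identity cutoff for block retention.
#' @param seed master seed; per-pair seeds are derived from it.
#' @return data frame with one row per pair: `pair`, `substitution_rate`,
#'   `n_inversions`, `d1`, `d2`, `p_dsyn`, `p_syn`; the `k` used is stored
#'   in attribute `"k"`.
#' @export
simulate_strain_cohort <- function(n_pairs = 20L,
                                   ancestor_length = 100000L,
                                   substitution_rates = seq(0.005, 0.13,
                                                            length.out = n_pairs),
                                   n_inversions = round(seq(1, 10,
                                                            length.out = n_pairs)),
                                   inversion_length_range = c(2000L, 8000L),
                                   k = 7L,
                                   identity_threshold = 90,
                                   seed = 1L) {
  stopifnot(n_pairs >= 1L, length(substitution_rates) == n_pairs,
            length(n_inversions) == n_pairs)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max, 2L * n_pairs))
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    anc <- random_genome(ancestor_length, seed = seeds[i],
                         id = sprintf("pair%02d", i))
    sc <- evolution_scenario(
      ancestor_length,
      substitution_rate = substitution_rates[i],
      n_inversions = n_inversions[i],
      inversion_length_range = inversion_length_range,
      seed = seeds[n_pairs + i])
    ev <- evolve_strain(anc, sc)
    s1 <- count_kmers(anc, k)
    s2 <- count_kmers(ev$descendant, k)
    blocks <- true_blocks(ev$truth, ancestor_length)
    kept <- blocks[blocks$identity_pct > identity_threshold, , drop = FALSE]
    px <- proximities(kept, ancestor_length, ancestor_length,
                      id_1 = anc$id, id_2 = ev$descendant$id)
    rows[[i]] <- data.frame(
      pair = i, substitution_rate = substitution_rates[i],
      n_inversions = n_inversions[i],
      d1 = d1(s1, s2)$value, d2 = d2(s1, s2)$value,
      p_dsyn = px$p_dsyn, p_syn = px$p_syn)
  }
  out <- do.call(rbind, rows)
  attr(out, "k") <- as.integer(k)
  out
}

#' Simulate a cohort of masked/unmasked genome pairs for KDR
#'
#' Each replicate builds two strains of a multi-chromosome genome that
#' share an ancestor and diverge in two ways: a small background
#' substitution load everywhere, and complete turnover of low-complexity
#' tracts — the tract positions are shared between the strains (so masking
#' removes the same windows from both) but the repeat content is redrawn
#' independently per strain, concentrating divergence in the maskable
#' fraction. For each strain pair the minimal matched-pair D2 distance is
#' computed on the unmasked and on the masked versions, and their ratio
#' (KDR). Because the masked run strips out precisely the fast-diverging
#' tracts, unmasked minima exceed masked minima and KDR > 1.
#'
#' Defaults: 20 replicates of 2 chromosomes x 60 kb, 30% tract coverage,
#' 1% background substitutions, k = 8.
#'
#' @param n_replicates number of independent replicates.
#' @param n_chromosomes chromosomes per genome.
#' @param chromosome_length length of each chromosome.
#' @param tract_fraction approximate fraction of each chromosome covered by
#'   low-complexity tracts.
#' @param tract_length_range (min, max) tract length.
#' @param background_substitution_rate per-site substitution rate applied
#'   to each strain outside and inside tracts (tract content is redrawn
#'   anyway).
#' @param k word length for D2.
#' @param threshold matched-pair edge threshold.
#' @param seed master seed.
#' @return data frame with one row per replicate: `replicate`,
#'   `unmasked_min`, `masked_min`, `kdr`.
#' @export
simulate_kdr_cohort <- function(n_replicates = 20L,
                                n_chromosomes = 2L,
                                chromosome_length = 60000L,
                                tract_fraction = 0.3,
                                tract_length_range = c(500L, 2000L),
                                background_substitution_rate = 0.01,
                                k = 8L,
                                threshold = 1,
                                seed = 1L) {
  stopifnot(n_replicates >= 1L, n_chromosomes >= 1L,
            tract_fraction >= 0, tract_fraction < 0.5)
  n_tracts <- max(1L, round(tract_fraction * chromosome_length /
                              mean(tract_length_range)))
  seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max,
                     n_replicates * n_chromosomes * 4L))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    strain_a <- vector("list", n_chromosomes)
    strain_b <- vector("list", n_chromosomes)
    for (c in seq_len(n_chromosomes)) {
      anc <- random_genome(chromosome_length, seed = nxt(),
                           id = sprintf("rep%02d_chr%d", r, c))
      base_sc <- evolution_scenario(
        chromosome_length,
        substitution_rate = background_substitution_rate,
        n_low_complexity_tracts = n_tracts,
        tract_length_range = tract_length_range,
        seed = nxt())
      tracts <- withr::with_seed(
        base_sc$seed,
        .sample_nonoverlapping(chromosome_length, n_tracts,
                               tract_length_range))
      for (strain in c("a", "b")) {
        sc <- evolution_scenario(
          chromosome_length,
          substitution_rate = background_substitution_rate,
          seed = nxt())
        ev <- evolve_strain(anc, sc)
        planted <- plant_low_complexity(ev$descendant, sc, tracts = tracts)
        g <- planted$genome
        g$id <- sprintf("%s_%s", anc$id, strain)
        if (strain == "a") strain_a[[c]] <- g else strain_b[[c]] <- g
      }
    }
    spectra <- function(recs, mode) {
      lapply(recs, function(g) count_kmers(apply_masking(g, mode), k))
    }
    m_unmasked <- matched_pairs(
      distance_matrix(spectra(strain_a, "unmasked"),
                      spectra(strain_b, "unmasked"), "D2"),
      threshold = threshold)
    m_masked <- matched_pairs(
      distance_matrix(spectra(strain_a, "masked"),
                      spectra(strain_b, "masked"), "D2"),
      threshold = threshold)
    kk <- kdr(m_unmasked, m_masked)
    rows[[r]] <- data.frame(replicate = r,
                            unmasked_min = kk$unmasked_min,
                            masked_min = kk$masked_min,
                            kdr = kk$kdr)
  }
  do.call(rbind, rows)
}
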