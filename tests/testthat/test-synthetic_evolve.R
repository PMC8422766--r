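test_that("random_genome honours composition, length and seed", {
  g <- random_genome(1000, seed = 4)
  expect_equal(g$length, 1000L)
  counts <- table(strsplit(g$sequence, "")[[1]])
  # binomial bound: each base frequency within 5 sd of 0.25
  sd5 <- 5 * sqrt(0.25 * 0.75 / 1000)
  expect_true(all(abs(counts / 1000 - 0.25) < sd5))

  allA <- random_genome(50, base_composition = c(1, 0, 0, 0), seed = 1)
  expect_equal(allA$sequence, strrep("A", 50))

  expect_identical(random_genome(200, seed = 9)$sequence,
                   random_genome(200, seed = 9)$sequence)
  expect_false(random_genome(200, seed = 10)$sequence ==
                 random_genome(200, seed = 9)$sequence)
  expect_error(random_genome(100, base_composition = c(0.5, 0.5, 0.5, 0.5)))
})

test_that("evolution_scenario validates its parameters", {
  expect_error(evolution_scenario(0))
  expect_error(evolution_scenario(100, substitution_rate = 1))
  expect_error(evolution_scenario(100, base_composition = c(1, 1, 0, 0)))
  expect_error(evolution_scenario(100, inversion_length_range = c(10, 5)))
  sc <- evolution_scenario(100, seed = 3)
  expect_s3_class(sc, "evolution_scenario")
})

test_that("evolve_strain with no events is the identity", {
  anc <- random_genome(2000, seed = 2)
  ev <- evolve_strain(anc, evolution_scenario(2000, seed = 5))
  expect_identical(ev$descendant$sequence, anc$sequence)
  expect_equal(nrow(ev$truth$inverted_intervals), 0L)
  expect_length(ev$truth$substituted_positions, 0L)
})

test_that("a whole-sequence inversion yields the reverse complement", {
  anc <- random_genome(3000, seed = 6)
  sc <- evolution_scenario(3000, n_inversions = 1,
                           inversion_length_range = c(3000, 3000), seed = 7)
  ev <- evolve_strain(anc, sc)
  expect_identical(ev$descendant$sequence, reverse_complement(anc$sequence))
  a <- count_kmers(anc, 4); b <- count_kmers(ev$descendant, 4)
  expect_identical(d2(a, b)$value, 0)
})

test_that("substitution load matches the binomial expectation", {
  anc <- random_genome(100000, seed = 8)
  sc <- evolution_scenario(100000, substitution_rate = 0.01, seed = 9)
  ev <- evolve_strain(anc, sc)
  n_sub <- length(ev$truth$substituted_positions)
  sd5 <- 5 * sqrt(100000 * 0.01 * 0.99)
  expect_lt(abs(n_sub - 1000), sd5)
  # every recorded position differs, every other position matches
  a <- strsplit(anc$sequence, "")[[1]]
  d <- strsplit(ev$descendant$sequence, "")[[1]]
  expect_true(all(a[ev$truth$substituted_positions] !=
                    d[ev$truth$substituted_positions]))
  expect_identical(which(a != d), ev$truth$substituted_positions)
  s1 <- count_kmers(anc, 7); s2 <- count_kmers(ev$descendant, 7)
  expect_gt(d1(s1, s2)$value, 0)
})

test_that("evolve_strain is deterministic and reports placement failure", {
  anc <- random_genome(5000, seed = 11)
  sc <- evolution_scenario(5000, substitution_rate = 0.02, n_inversions = 2,
                           inversion_length_range = c(500, 1000), seed = 12)
  e1 <- evolve_strain(anc, sc)
  e2 <- evolve_strain(anc, sc)
  expect_identical(e1$descendant$sequence, e2$descendant$sequence)
  expect_identical(e1$truth$inverted_intervals, e2$truth$inverted_intervals)

  crowded <- evolution_scenario(1000, n_inversions = 10,
                                inversion_length_range = c(200, 200),
                                seed = 13)
  expect_error(evolve_strain(anc <- random_genome(1000, seed = 1), crowded),
               "could not place")
})

test_that("inversions do not overlap and stay in bounds", {
  anc <- random_genome(20000, seed = 14)
  sc <- evolution_scenario(20000, n_inversions = 6,
                           inversion_length_range = c(500, 2000), seed = 15)
  inv <- evolve_strain(anc, sc)$truth$inverted_intervals
  expect_equal(nrow(inv), 6L)
  expect_true(all(inv$start >= 1 & inv$end <= 20000))
  expect_true(all(inv$start[-1] > inv$end[-nrow(inv)]))  # sorted, disjoint
})

test_that("true_blocks tiles the sequence from the event record", {
  no_events <- evolve_strain(random_genome(1000, seed = 16),
                             evolution_scenario(1000, seed = 17))
  b0 <- true_blocks(no_events$truth, 1000)
  expect_equal(nrow(b0), 1L)
  expect_equal(b0$start, 1L)
  expect_equal(b0$end, 1000L)
  expect_equal(b0$identity_pct, 100)
  expect_equal(b0$orientation, "direct")
  expect_equal(proximities(b0, 1000, 1000)$p_syn, 1)

  truth <- structure(
    list(inverted_intervals = data.frame(start = 301L, end = 600L),
         substituted_positions = c(10L, 350L, 360L, 990L),
         masked_intervals = data.frame(start = integer(0), end = integer(0))),
    class = "ground_truth")
  b <- true_blocks(truth, 1000)
  expect_equal(b$start, c(1L, 301L, 601L))
  expect_equal(b$end, c(300L, 600L, 1000L))
  expect_equal(b$orientation, c("direct", "inverse", "direct"))
  expect_equal(b$identity_pct,
               100 * (1 - c(1 / 300, 2 / 300, 1 / 400)))
  expect_equal(nrow(true_blocks(truth, 1000, min_block = 350)), 1L)
})

test_that("ground-truth blocks reproduce programmed coverage exactly", {
  anc <- random_genome(50000, seed = 18)
  sc <- evolution_scenario(50000, n_inversions = 4,
                           inversion_length_range = c(1000, 5000), seed = 19)
  ev <- evolve_strain(anc, sc)
  blocks <- true_blocks(ev$truth, 50000)
  px <- proximities(blocks, 50000, 50000)
  inv_cov <- sum(ev$truth$inverted_intervals$end -
                   ev$truth$inverted_intervals$start + 1L)
  expect_identical(px$l_isb, inv_cov)
  expect_identical(px$l_dsb, 50000L - inv_cov)
  expect_equal(px$p_syn, 1)
})

test_that("plant_low_complexity soft-masks tracts that masking removes", {
  g <- random_genome(10000, seed = 20, id = "g")
  none <- plant_low_complexity(g, evolution_scenario(10000, seed = 21))
  expect_identical(none$genome$sequence, g$sequence)
  expect_equal(nrow(none$truth$masked_intervals), 0L)

  sc <- evolution_scenario(10000, n_low_complexity_tracts = 5,
                           tract_length_range = c(200, 600), seed = 22)
  planted <- plant_low_complexity(g, sc)
  tr <- planted$truth$masked_intervals
  expect_equal(nrow(tr), 5L)
  chars <- strsplit(planted$genome$sequence, "")[[1]]
  in_tract <- rep(FALSE, 10000)
  for (i in seq_len(nrow(tr))) in_tract[tr$start[i]:tr$end[i]] <- TRUE
  expect_true(all(grepl("[a-z]", chars[in_tract])))
  expect_true(all(grepl("[A-Z]", chars[!in_tract])))

  # masked-mode window bookkeeping: valid windows = windows that do not
  # intersect any tract, computed independently by interval arithmetic
  k <- 6L
  spec <- count_kmers(apply_masking(planted$genome, "masked"), k)
  blocked <- rep(FALSE, 10000 - k + 1)
  for (i in seq_len(nrow(tr))) {
    lo <- max(1L, tr$start[i] - k + 1L)
    hi <- min(tr$end[i], 10000L - k + 1L)
    blocked[lo:hi] <- TRUE
  }
  expect_equal(spec$total_valid, sum(!blocked))
  expect_equal(spec$skipped_windows, sum(blocked))
})

test_that("divergence graded by dose raises D1 and never raises P_SYN", {
  rates <- c(0, 0.005, 0.01, 0.02, 0.05)
  med_d1 <- numeric(length(rates))
  psyn <- numeric(length(rates))
  # paired design: each replicate keeps its ancestor and inversion draw
  # fixed across the ladder, so only the substitution dose varies
  seeds <- withr::with_seed(100, sample.int(1e6, 3))
  ancestors <- lapply(seeds, function(s) random_genome(30000, seed = s))
  for (j in seq_along(rates)) {
    vals <- numeric(3); ps <- numeric(3)
    for (r in 1:3) {
      anc <- ancestors[[r]]
      sc <- evolution_scenario(30000, substitution_rate = rates[j],
                               n_inversions = 2,
                               inversion_length_range = c(1000, 3000),
                               seed = seeds[r] + 1L)
      ev <- evolve_strain(anc, sc)
      vals[r] <- d1(count_kmers(anc, 7), count_kmers(ev$descendant, 7))$value
      blocks <- true_blocks(ev$truth, 30000)
      kept <- blocks[blocks$identity_pct > 90, , drop = FALSE]
      ps[r] <- proximities(kept, 30000, 30000)$p_syn
    }
    med_d1[j] <- median(vals)
    psyn[j] <- median(ps)
  }
  expect_true(all(diff(med_d1) > 0))
  expect_true(all(diff(psyn) <= 0))
})

test_that("ground truth serializes to JSON", {
  ev <- evolve_strain(random_genome(2000, seed = 23),
                      evolution_scenario(2000, substitution_rate = 0.01,
                                         n_inversions = 1,
                                         inversion_length_range = c(100, 300),
                                         seed = 24))
  js <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(ev$truth, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$inverted_intervals$start,
               ev$truth$inverted_intervals$start)
  expect_equal(back$substituted_positions, ev$truth$substituted_positions)
})
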