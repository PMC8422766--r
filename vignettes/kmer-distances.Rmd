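---
title: "Methods: k-mer distances, synteny proximities, and the KDR statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer distances, synteny proximities, and the KDR statistic}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kmerdist)
```

## The model

A chromosome strand $S$ of length $L$, read 5′→3′, contains
$N = L - k + 1$ sliding windows of length $k$. The empirical frequency of a
k-mer $m$ is $f_m = n(m)/N$, with $n(m)$ its window count. `kmerdist`
compares chromosomes through two L1 distances over the full $4^k$-dimensional
frequency vector:

* **D1** (single strand):
  $D_1^k(S_1, S_2) = \sum_{i=1}^{4^k} \lvert f_{m_i}(S_1) - f_{m_i}(S_2)\rvert$.
* **D2** (both strands): writing $M_i$ for the reverse complement of $m_i$,
  $D_2^k(S_1, S_2) = \tfrac12 \sum_i \lvert f_{m_i}(S_1) + f_{M_i}(S_1) -
  f_{m_i}(S_2) - f_{M_i}(S_2)\rvert$. The factor $\tfrac12$ compensates for
  the doubled effective count when both strands are read.

Both are genuine metrics up to equivalence (non-negative, symmetric,
triangle inequality) with values in $[0, 2]$, $D_2 \le D_1$ always, and both
are non-decreasing in $k$ while every k-mer is realized on both sequences.
D2 is invariant under the arbitrary strand choice made for each chromosome
in an assembly, which is why it is the default for comparisons between
species; D1 is meaningful between closely related bacterial strains where a
positive strand is well defined.

**Inversion symmetry.** The count of a k-mer on one strand approximately
equals the count of its reverse complement on the same strand (the
generalized second parity rule). Two consequences shape the package:

* $D_1(S, \mathrm{rc}(S))$ *equals the inversion-symmetry deviation of $S$
  itself*. It is exactly zero only for a sequence with exact inversion
  symmetry, and small-but-positive for real chromosomes and for random
  sequences. The test suite checks the exact-zero statement on sequences
  that have exact symmetry by construction — a circular window scan of
  $x \,\Vert\, \mathrm{rc}(x)$ is invariant under reverse complementation —
  and checks that on ordinary random sequences $D_1(S, \mathrm{rc}(S))$
  coincides with the independently computed symmetry deviation.
* $D_2(S, \mathrm{rc}(S)) = 0$ holds identically (the combined vector is
  the same object for both inputs), and the suite asserts it *exactly*, not
  within a tolerance.

**Inversion immunity of D2.** Replacing a segment by its reverse complement
conserves the combined $(f_m + f_M)$ window multiset except in windows that
straddle the two breakpoints. For $R$ non-overlapping inversions,
$D_2^k \le 4R(k-1)/N$ — a hard combinatorial bound: at most $2R(k-1)$
window positions differ between the two scans, and each differing position
moves at most $4/N$ of combined L1 mass ($2/N$ removed, $2/N$ added), of
which the $\tfrac12$ factor keeps half. The bound is attained when every
breakpoint window changes k-mer class, so tests compare against it with a
$10^{-12}$ allowance for floating-point summation.

## Tunable parameters

* `k` (1–12, dimensionless): the word length. The count table has $4^k$
  entries, so 12 is a memory guard rail, not a statistical limit. Defaults
  follow field practice: 7 for bacterial strain comparisons, 8 for
  inter-species D2 runs. `kl_limit()` implements the advisory heuristic
  $K_L = \lfloor 0.7 \ln \min(L_1, L_2) \rfloor$, the empirical growth law
  of the largest $k$ at which inversion symmetry holds within 10%. The
  formula gives ≈10 for a 4.6 Mbp chromosome while bacterial analyses
  conventionally use 7–8; we implement the formula as printed and treat it
  as an upper bound, surfacing the discrepancy in the documentation rather
  than resolving it.
* `masking_mode`: `unmasked` uppercases everything; `masked` converts
  soft-masked lowercase to `N`, unifying soft and hard masking into one
  window-skipping rule. Frequencies divide by the count of *valid* windows
  (those free of non-ACGT characters), not by $L-k+1$; this keeps frequency
  vectors summing to 1 under masking and hence distances within $[0,2]$.
  For a pure-ACGT sequence the two denominators coincide.
* `identity_threshold` (percent, default 90, strict `>`): synteny blocks
  must exceed this local identity. The value demands near-identity and is a
  convention; it is exposed rather than hard-coded.
* `merge_overlaps` (default `TRUE`): overlapping alignment segments are
  unioned within each orientation class before coverage is summed, so
  repeated local alignments cannot be double-counted; the raw-sum reading
  is kept behind the flag because the underlying definition ("overall
  sequence length") admits both.
* `threshold` (default 1): matched-pair edges above this distance are
  discarded before matching.

## Synteny proximities

From a 12-column tabular alignment of two strain chromosomes, blocks above
the identity threshold are classified **direct** (same strand: subject
interval forward) or **inverse** (opposite strands: subject interval
reversed). With $L_{DSB}$ and $L_{ISB}$ the covered lengths of the two
classes,

$$P_{DSYN} = \frac{L_{DSB}}{\min(L_1, L_2)}, \qquad
  P_{SYN} = \frac{L_{DSB} + L_{ISB}}{\min(L_1, L_2)}.$$

Design choices where the definition is silent: block lengths are measured
on the **query** chromosome, and `run_aligner()` makes the *shorter* genome
the query, so coverage and the denominator live on the same sequence;
coordinates are 1-based inclusive (covered length $b - a + 1$), converted
to half-open only in the BED writer. These proximities presuppose long
near-identical tracts and are meaningful only between very close relatives
(strains of one bacterium); they are not a cross-species measure.

## The matched-pair algorithm

Given the full distance matrix between the chromosomes of two species:
discard edges above the threshold; repeatedly select the globally minimal
remaining edge and remove **both endpoint chromosomes**; report the
selected distances (non-decreasing by construction), their minimum, and
their median. We read the step "remove this edge" as removing the endpoint
vertices — i.e. a greedy matching — because the procedure is summarised per
genome pair over matched chromosome pairs; the literal edge-only reading
(which simply sorts all sub-threshold edges) is available via
`remove = "edges"`. Ties on the minimal value are broken lexicographically
on (row id, column id) for determinism. The median of an even-length vector
is the mean of the two middle values. An all-above-threshold matrix yields
an explicit empty result with a status string, not an error, since that is
a legitimate biological outcome (no sufficiently similar chromosome pairs).

## KDR

For one genome pair, run the matched-pair algorithm twice at the same `k`
on the same chromosome sets — once on unmasked sequences, once masked — and
form $\mathrm{KDR} = \min D_2^{\text{unmasked}} / \min D_2^{\text{masked}}$.
Low-complexity DNA is weakly constrained by selection and turns over
rapidly, so masking removes the fastest-diverging fraction and the ratio
measures the aggregated differential mutation load; KDR $>1$ is the
expected direction whenever divergence concentrates in maskable sequence.
The ratio is undefined when the masked minimum is zero (identical masked
genomes), which is reported as an error rather than infinity.

## What the simulator emulates — and what it does not

`evolve_strain()` produces a descendant by (1) segmental inversions —
non-overlapping segments replaced in place by their reverse complements —
then (2) i.i.d. point substitutions on descendant coordinates, each hit
site redrawn uniformly among the three other bases. Ground truth (inversion
intervals, substituted positions, tract intervals) is exact, and
`true_blocks()` converts it into the synteny blocks an aligner would
report, with block identity $100(1 - \text{substitutions}/\text{length})$.
`plant_low_complexity()` overwrites sampled tracts with tandem repeats of
random 1–3-mer motifs and emits them soft-masked.

Deliberate simplifications: no transition/transversion bias, no indels, no
nested or overlapping inversions (non-overlapping sampling keeps
ground-truth blocks well defined), no horizontal transfer, no gene
structure, uniform base composition by default. Consequently, green tests
demonstrate that the *algorithms* behave as specified under the stated
generative model — inversion immunity, pipeline closure, anticorrelation,
KDR direction — not that real genomes satisfy the model. Real chromosomes
have skewed composition, repeat families, and alignment noise that the
ground-truth route bypasses; the `run_aligner()` path exists precisely so
real tabular alignments can replace `true_blocks()` without any other code
change.

### Study conditions

Chosen once, as conditions a desk-scale strain comparison would use, and
used unchanged by tests and the acceptance script:

* **Strain cohort** (`simulate_strain_cohort()`): 20 pairs, 100 kb
  ancestors, substitution rates graded 0.005–0.13 so the ladder crosses the
  90%-identity cliff (blocks drop out of the proximity sums exactly as
  alignment-derived blocks would), 1–10 inversions of 2–8 kb, distances at
  $k=7$. Heavier doses get both more substitutions and more inversions,
  mirroring how separation time accumulates both.
* **KDR cohort** (`simulate_kdr_cohort()`): 20 replicates of 2 × 60 kb
  chromosomes, ≈30% tract coverage, tract positions shared between the two
  strains but tract content redrawn independently per strain, 1% background
  substitutions, $k=8$. Sharing positions makes masking remove the same
  windows from both strains, concentrating the surviving divergence outside
  tracts.
* Property suites use 0.5–10 kb random sequences at $k \le 5$, where the
  brute-force substring-map oracle is affordable.

These sizes are scaled-down analogues of multi-megabase chromosomes; the
qualitative claims they support (signs, bounds, orderings) are
scale-invariant, the printed magnitudes are not.

## Numerical choices

* k-mers are ranked lexicographically in base 4 ($A{=}0, C{=}1, G{=}2,
  T{=}3$); the reverse-complement rank is computed arithmetically (digit
  reversal and complement), giving an $O(1)$, bit-exact pairing for the D2
  sum, cached per `k`.
* Counting runs through `Biostrings::oligonucleotideFrequency`, whose
  window rule (windows containing any non-ACGT symbol are simply not
  counted) is exactly the skip rule the frequency denominator needs.
* `kl_limit()` adds $10^{-9}$ inside `floor()` so that arguments landing
  exactly on an integer (e.g. $0.7 \ln e^{10}$) are not pushed down by
  representation error.
* Exact-zero claims (D2 against a reverse complement, self-distance) are
  asserted with `identical()`, not a tolerance: the implementation computes
  bitwise-identical combined vectors in those cases. Inequalities that sum
  $4^k$ floating-point terms carry a $10^{-12}$ allowance.
* Degenerate inputs: a spectrum with zero valid windows refuses to yield
  frequencies ("no valid k-mer windows"); `k` larger than the sequence is
  an error; an empty FASTA file is an empty list plus a warning, not an
  error; IUPAC ambiguity codes are mapped to `N` with a logged count.
* Every stochastic routine is a pure function of its seed
  (`withr::with_seed`), and cohort functions derive per-replicate seeds
  from one master seed, so whole cohorts are reproducible bit for bit.

## Limitations

* The proximity measures saturate ($P \to 0$) once local identity falls
  below the threshold, so the distance–proximity anticorrelation is only
  informative within the near-identity regime the measures were designed
  for.
* `k = 12` is a hard cap; disk-backed counting for larger `k` is out of
  scope, as are sketching approximations — the distances here are exact by
  construction.
* The matched-pair minimum is sensitive to a single outlying chromosome
  pair; the median is reported alongside it for that reason.
* The KL heuristic is advisory and its constant is empirical; choosing `k`
  remains the analyst's decision.
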