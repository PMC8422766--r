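Package: kmerdist
Title: Alignment-Free k-mer Distances and Synteny Proximities Between Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Alignment-free comparison of chromosomal sequences through k-mer
    frequency spectra. Implements the single-strand (D1) and double-strand (D2)
    L1 k-mer distances, synteny proximities between closely related bacterial
    strains derived from tabular alignment output (direct and inverse synteny
    blocks), a greedy matched-pair algorithm summarising inter-genome distance
    matrices, and the k-mer distance ratio (KDR) contrasting unmasked with
    masked genome versions. Ships a synthetic genome-evolution generator
    (point substitutions, segmental inversions, low-complexity tracts) with
    exact ground-truth annotations for end-to-end testing without genome
    downloads, and a command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    seqinr,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
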