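Package: spacedpairs
Title: Discovery of Spaced Motif Pairs with Conserved Spacer Length in
    Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised genome-wide discovery of pairs of short sequence
    motifs (pentamers by default) that occur at one specific spacer distance
    significantly more often than expected under a uniform distance
    distribution.  Significance of the maximum per-distance count is assessed
    against the exact distribution of the maximum cell count of a uniform
    multinomial (balls-in-urns occupancy model) with an asymptotic percentile
    approximation for large totals, after Bonferroni correction over all
    ordered motif pairs.  Near-duplicate spacers are collapsed by greedy
    Needleman-Wunsch alignment to discount segmental duplications, candidate
    pairs must be corroborated by their reverse complement at the same
    distance, overlapping pentamer pairs are merged into consensus patterns,
    and hits are classified against gene annotations (gene / intergenic /
    overlap, flanking-gene orientation).  Includes a synthetic-genome
    generator with planted motif pairs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    readr,
    withr,
    Biostrings,
    IRanges,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
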