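Package: plastedit
Title: Quantification and Differential Analysis of Chloroplast C-to-U RNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies C-to-U RNA editing at catalogued plastid sites from
    aligned RNA-seq reads (strand-aware pileup base counting) and from Sanger
    chromatograms (T/C peak-area integration), and tests sites for differential
    editing between conditions by pooling biological replicates and applying
    Fisher's exact test with Bonferroni correction. Also provides the
    expression-side arithmetic used alongside such analyses: counts-per-million
    normalization, expressed-gene filters, a simple exact-test caller for
    significantly differentially expressed genes, set-overlap percentages,
    Fisher set enrichment, 2^-ddCt qPCR quantification and row Z-scores.
    Includes seeded simulators for aligned reads, chromatogram traces and
    negative-binomial count matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
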