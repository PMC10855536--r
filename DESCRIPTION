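Package: retroamp
Title: Locus-Specific Quantification of Endogenous Retrovirus Amplicon Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for copy-specific expression analysis of multi-copy
    endogenous retrovirus (ERV) families from degenerate-primer amplicon
    sequencing. Implements in-silico PCR over a genome with IUPAC-degenerate
    primers, primer trimming and length filtering of reads, end-to-end
    (no soft clipping) glocal read alignment with seeded random tie-breaking
    among equal best hits, per-locus read counting and relative-frequency
    matrices, median-based fold-change and symmetric relative-fold-change
    statistics, a simplified negative-binomial Wald test with
    Benjamini-Hochberg FDR control, 2^-ddCt qPCR relative-expression
    arithmetic, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
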