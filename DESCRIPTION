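Package: isomirage
Title: IsomiR Calling, Seed-Match Target Prediction and Age-Related
    Anti-Correlation Screening for Small RNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns small-RNA reads to mature microRNA loci on their
    precursor hairpins and classifies them into sequence variants
    (isomiRs): 5'/3' trimming variants, non-templated 3' additions and
    single-nucleotide substitutions. Quantifies variants by their 7-nt
    seed region (miRNA positions 2-8) with counts-per-million-miRNA
    normalization, predicts canonical 8mer/7mer-m8/7mer-A1 seed-match
    sites in 3'UTR sequences, detects age-related genes by nonlinear
    trend regression against a constant model, and screens predicted
    (miRNA variant, target gene) pairs for expression anti-correlation
    across an age series. Includes a synthetic-data generator with
    planted ground truth for end-to-end validation, modelled on the
    seed dichotomy of human miR-101 and its abundant 5'-shifted isomiR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
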