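Package: trioseq
Title: Three-Library Transcriptome Comparison for Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the transcriptome of an allopolyploid hybrid against its
    paternal and maternal parents from per-gene read counts of three RNA-Seq
    libraries. Provides RPKM normalization, expressed-gene calling and
    three-set Venn partitioning, gene-length and read-coverage binning,
    read-subsampling saturation analysis, the Audic-Claverie exact test for
    digital expression counts with Benjamini-Hochberg adjustment,
    midparent-value construction and additive/nonadditive classification,
    sign-rule expression-pattern grouping with hierarchical clustering,
    a normalized parental-bias statistic, functional-category contrasts
    between additive and nonadditive genes, and a negative-binomial
    synthetic-data generator with ground-truth labels for calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
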