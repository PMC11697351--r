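Package: panffpe
Title: Pan-Cancer FFPE Proteomics: TIC Normalization, Protein FDR, and
    Cohort Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational procedures for large pan-cancer proteome profiling of
    formalin-fixed paraffin-embedded (FFPE) tissue: peptide-loading normalization
    from summed MS1 total ion chromatograms against an external dilution-series
    calibration; protein-level false discovery rate control from search-engine
    protein probabilities via cumulative-mean q-values; data-driven completeness
    and fold-change cutoffs; one-vs-rest Wilcoxon differential expression with
    Benjamini-Hochberg correction; cohort fingerprint classification (exclusive,
    enriched, enhanced) with tissue-of-origin attribution and chi-squared
    overrepresentation tests; retention-time drift and longitudinal QC monitoring.
    Includes a synthetic-data generator that emulates the statistical structure of
    such cohorts with planted ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
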