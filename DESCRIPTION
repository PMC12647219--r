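Package: gbamine
Title: Guilt-by-Association Correlation Mining of Proteome Abundance Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for guilt-by-association analysis of wide protein-abundance
    matrices such as pan-cancer proteome resources. Computes all-vs-all
    Spearman correlation matrices after zero-imputation of missing values,
    produces descending-ranked association lists for query proteins, validates
    the approach with per-GO-term median-of-correlation statistics and
    synthetic-lethal pair-set enrichment against the background correlation
    distribution, profiles protein panels (sub-matrix, correlation and
    abundance ranges, missingness), and performs two-condition replicate
    differential abundance analysis with group-level fold-change aggregation.
    A synthetic-cohort generator with planted correlated modules,
    detection-limit missingness, annotation terms, pair sets and depletion
    experiments makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
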