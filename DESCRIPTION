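Package: clonediv
Title: Clonal Diversity Indices for Vector Insertion-Site Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Richness and evenness statistics for clonal tracking of
    gene-modified cells by vector insertion sites (IS): Shannon entropy,
    Pielou evenness, Simpson diversity, Gini inequality via Brown's formula,
    Chao1 richness estimation, the UC50 clone count, and a coverage-based
    (Horvitz-Thompson) entropy correction. Includes an in-silico simulator of
    progressive clonal dominance with multinomial subsampling at several
    sampling efforts, a richness-by-dominance surface study, a longitudinal
    re-analysis pipeline that normalises published Shannon summaries across
    log bases, derives Pielou evenness from (Shannon, richness) pairs and
    flags samples below a 0.5 evenness alert threshold, and synthetic-data
    generators that emulate published trial summaries and spiked-clone
    abundance series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
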