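Package: mavekit
Title: Parse, Validate, and Summarize Multiplexed Assay of Variant Effect Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with multiplexed assay of variant effect (MAVE)
    datasets offline: a strict parser and formatter for the MAVE-HGVS variant
    nomenclature subset, validation of variants against a target sequence or a
    pluggable accession lookup, schema validation for per-variant score and
    count tables, the hierarchical record model (experiment sets, experiments,
    score sets, and meta-analysis score sets) with URN accessions, a bulk
    archive reader/writer (JSON metadata plus CSV tables), automatic score
    histograms and variant effect heatmaps, and a deterministic synthetic
    fixture generator with controlled defect seeding for testing validators
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
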