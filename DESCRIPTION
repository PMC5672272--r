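Package: karyometry
Title: Karyotype Measurement, Asymmetry and 5S rDNA Repeat Analysis for
    Plant Molecular Cytogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative plant karyotype analysis from
    per-metaphase chromosome arm measurements: aggregation into haploid
    karyotype tables (relative lengths, arm ratios, centromeric indices,
    total complement length), Levan centromere-position classification and
    karyotype formula strings, the six-index karyotype asymmetry profile
    (mean CI, A1, A2, As K%, AI, Stebbins category), positional and size
    statistics for chromosomal markers (5S/45S rDNA FISH sites,
    fluorochrome bands, self-GISH blocks), deterministic SVG idiograms,
    dissection and comparison of 5S rDNA repeat units (gene/NTS segments,
    promoter motifs, GC content, variable sites, global alignment), and a
    synthetic-data generator providing ground truth for parameter-recovery
    tests. Ships the published chromosome measurement table for the two
    cultivated Canavalia species as a worked reference dataset.
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
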