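Package: homeoscan
Title: Homoeolog-Level Analysis of Nascent Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing gene regulation and genome dynamics in
    nascent allopolyploids from homoeolog-resolved count data. Computes
    homoeolog expression bias (log2 R/C ratios), decomposes expression
    divergence into cis- and trans-regulatory components against an in
    silico hybrid reference, calls 5-methylcytosine sites from bisulfite
    cytosine counts and classifies differentially methylated and
    methylation-regulated genes, detects unequal homoeologous
    recombination as runs of shifted read-depth copy ratios, and tests
    the association between transposable elements and structural
    variants. Includes a synthetic-data generator with planted ground
    truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
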