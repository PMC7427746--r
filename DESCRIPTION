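Package: msclineage
Title: Reliability Classification of MSC Lineage Gene Signatures Across
    Expansion and Licensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess whether candidate mesenchymal stromal cell
    (MSC) lineage signature genes remain reliably expressed through serial
    culture expansion and cytokine licensing. Given normalized log2
    expression matrices, sample annotations and candidate gene lists, the
    package collapses probes to genes, calls detection above the array
    background floor, computes empirical-Bayes moderated two-group
    contrasts with Benjamini-Hochberg adjustment, classifies each gene as
    reliable, sporadic, never detected or condition-silenced, and derives
    a refined consensus identity panel from prior-evidence tables. A
    synthetic-data generator emulates floor-censored expansion and
    licensing designs with known per-gene truth so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
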