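Package: rieqtl
Title: Expression QTL Mapping and Co-Expression Signatures for Recombinant Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for systems-genetics analysis of transcriptomes
    measured across recombinant inbred (RI) mouse panels such as the BXD family.
    Implements the GeneNetwork-style normalization chain (offset, log2, quantile
    normalization, rescaled Z scores), array-identity quality control (sex-marker
    and Mendelian bimodal transcript checks), one-way ANOVA heritability,
    Haley-Knott regression interval mapping on an RI-scale pseudomarker grid with
    permutation-based genome-wide significance, transcriptome-wide cis/trans eQTL
    cataloguing, candidate-gene interval queries, and correlation-network /
    principal-component cell-type signature extraction. Ships a synthetic BXD-like
    panel generator with planted ground truth so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
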