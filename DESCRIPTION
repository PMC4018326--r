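Package: tendomics
Title: Label-Free Quantitative Proteomics of Ligament and Tendon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for label-free quantitative proteomics of dense
    connective tissue (anterior cruciate ligament and patellar tendon).
    Takes peptide-level intensity tables through decoy-based FDR filtering,
    fraction merging, protein roll-up, error-weighted ANOVA with
    Benjamini-Hochberg correction and Cohen's d effect-size curation, and
    top-3 ("Hi3") absolute quantification against a spiked surrogate
    standard, reporting protein amounts as percent of tissue dry weight,
    cross-tissue comparisons, collagen chain and type ratios, and
    albumin-relative enrichment of blood proteins. Includes a synthetic
    peptide-level data generator with a ground-truth ledger so every stage
    is testable without raw mass-spectrometry data, plus matrisome
    annotation and quality-control summaries (surrogate-standard RSD,
    fraction uniqueness, PCA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
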