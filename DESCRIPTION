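Package: metabotyper
Title: Metabolic Profiling, Metabotype Detection and Gut-Microbiome
    Correlation Analysis for Inbred Fly Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how genome variation, diet and the gut
    microbiome shape Drosophila metabolic phenotypes across panels of
    inbred lines such as the DGRP. Converts raw plate-reader assays into
    per-animal metabolite amounts (including citrate-synthase activity),
    normalises metabolite panels, detects metabotypes by k-means
    clustering and sex-atypical ("virago") lines by principal-component
    classification, quantifies diet-shift responses, computes Spearman
    rank correlation matrices with AS89 p-values, derives pairwise
    shared-allele distributions and group-unique alleles from biallelic
    genotype matrices, post-processes genome-wide association output
    (significance filtering, gene classification, condition overlap,
    Manhattan-plot preparation), and processes 16S taxon abundance
    tables (top-95 percent taxon filtering, genus rollup, Bray-Curtis
    clustering, metabolite-microbe correlation). A synthetic-data module
    generates all pipeline inputs with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    biomformat
Config/testthat/edition: 3
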