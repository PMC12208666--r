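Package: songmod
Title: Co-Expression Module Analysis of Songbird Vocal-Circuit Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted gene co-expression network analysis of bulk RNA-seq from
    songbird vocal-control nuclei and their motor surrounds. Builds unsigned
    adjacency and topological-overlap networks, detects modules by static tree
    cut with iterative gene reassignment, computes module eigengenes and
    continuous membership (kME), tests module and single-gene association to
    binarized design contrasts (song nucleus vs surround, sex, estradiol
    treatment), performs bootstrap chromosome-module enrichment with
    Benjamini-Hochberg FDR, quantifies sex-chromosome dosage via male
    expression fractions against copy-number predictions, and selects core
    genes via a four-contrast intersection with hypergeometric Z-chromosome
    enrichment. Includes a synthetic-data generator that emulates a
    2 sexes x 2 treatments x 3 birds x 8 regions study design with planted
    modules, sex-chromosome dosage classes, outlier samples, and bird-specific
    modules for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
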