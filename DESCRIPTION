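Package: anthersmallrna
Title: Comparative Small RNA and Degradome Analysis of Plant Anther Libraries
Version: 0.1.0
Authors@R:
    person("Anther", "smallRNA Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparative small RNA profiling
    of paired plant anther libraries (wild type versus a genetic-male-sterile
    mutant across three developmental stages): adapter cleaning and 18-30 nt
    tag collapsing, structural non-coding RNA annotation, conserved miRNA
    family assignment with a two-tier (species then all-plant) reference rule,
    novel miRNA discovery by transcript mapping and hairpin evaluation under a
    base-pair stacking energy proxy, chi-square differential expression of
    count libraries, and degradome (PARE) based cleavage-site identification
    with TP10M normalization, peak categories and t-plot tables. A synthetic
    data generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
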