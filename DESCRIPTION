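Package: adaptscan
Title: Multiscale Detection of Selection from SNP, Gene and Pathway Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting signatures of local adaptation in
    population resequencing panels of nonmodel species. Implements the
    standard sequence diversity and neutrality statistics (nucleotide
    diversity by site class, Tajima's D, Fu and Li's D* and F*,
    inbreeding and pairwise relatedness), SNP-level genotype-environment
    association scans by rank correlation against multi-period climate
    tables, a gene-level binomial outlier test for genes carrying an
    excess of climate-associated SNPs, and polygenic gene-set enrichment
    by the SUMSTAT score with iterative pruning of overlapping sets and
    an empirical false discovery rate obtained by whole-pipeline
    randomization. A seed-reproducible synthetic-data generator
    (coalescent gene alignments, population panels with planted climate
    clines, pathway universes with planted shifts) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
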