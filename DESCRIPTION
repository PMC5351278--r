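Package: subcloneCN
Title: Subclonal Copy-Number and LOH Inference from Single-Sample Tumor
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("subcloneCN", "Developers", email = "subclonecn@example.org",
           role = c("aut", "cre"))
Description: Joint segmentation of window read counts and B-allele read
    depths at known SNP positions from a single tumor whole-genome
    sequencing sample, without a matched normal. A factorial hidden
    Markov model over aberration genotypes (total and major copy number
    up to a configurable ceiling) and clonal clusters is fitted by
    expectation-maximization with Newton-Raphson parameter updates;
    the number of clonal populations is selected by an incremental
    Bayesian information criterion. The package reports clonal and
    subclonal copy-number-alteration and loss-of-heterozygosity
    segments, the cellularity of each clonal cluster and the tumor
    purity, and ships a tumor-mixture simulator plus an evaluation
    harness for benchmarking against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
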