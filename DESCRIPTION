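Package: ylineage
Title: Y-Chromosome SNP Phylogenies and Rho-Statistic Dating of Haplogroup Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing haploid Y-chromosome SNP data along the
    pipeline used in haplogroup phylogeography: reading multi-sample haploid
    VCFs against a callable-region mask, a site/genotype quality filter
    cascade (depth, missingness, indels, monomorphic sites), outgroup
    polarization, perfect-phylogeny tree construction with parsimony
    (Fitch) branch assignment and recurrent-mutation flagging, rho-statistic
    TMRCA dating with confidence bounds propagated from a mutation-rate
    interval, and clade-level variant partitioning (defining, equivalent,
    private and catalog-novel SNPs).  A clock-tree simulator with Poisson
    mutation placement over a region mask provides datasets with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
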