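Package: phyloplace
Title: Branch Assignment of SNPs and Phylogenetic Placement of
    Low-Coverage Ancient Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns biallelic SNPs from a reference genotype panel to
    branches of a fixed phylogeny under a genotype-error likelihood model,
    then places low-coverage, damage-affected query samples (typically
    ancient DNA) onto that tree.  Query base calls are collected from BAM
    pileups or pre-called VCFs at the informative sites, filtered with
    deamination-aware rules (singleton transition removal, transversions-only
    mode, consensus thresholding), and placed either by a best-path
    support/conflict traversal or by a per-edge likelihood with Bayesian
    posterior probabilities and a conservative 99% placement clade.
    Placements can be refined to a named haplogroup using a curated
    ISOGG-style marker table.  A bundled simulator generates reference
    trees, genotype panels, marker tables and damaged query pileups with
    known truth, so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vcfR,
    Rsamtools,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
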