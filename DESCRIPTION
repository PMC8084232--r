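Package: sweepscan
Title: Selection-Signature Scanning with Windowed F_ST and Nucleotide Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selective sweeps in multi-population SNP data by
    contrasting one target population against the pool of all remaining
    populations. Implements cohort-wide minor-allele-frequency and missingness
    filtering of VCF genotypes, sliding-window Nei's nucleotide diversity and
    Weir-Cockerham F_ST, joint top-quantile outlier intersection, merging of
    outlier windows into candidate regions, extraction of overlapping genes
    from a GFF3 annotation, and hypergeometric term enrichment with
    Benjamini-Hochberg false-discovery-rate control. Ships a Balding-Nichols
    multi-population genotype simulator with embedded sweeps and ground truth
    so the whole pipeline can be exercised and power-checked offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
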