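#!/usr/bin/env Rscript
# Step 2: cohort-wide variant filtering.
#
# Applies the post-calling filter — minor allele frequency > 0.05 and
# missing-genotype fraction < 25%, both strict — across all 47 samples at
# once, and writes the filtered VCF for the scan step.

suppressMessages(library(sweepscan))

g <- read_vcf("scratch/fixture/genotypes.vcf")
st <- allele_stats(g)
gf <- filter_variants(g, filter_config())
write_vcf(gf, "scratch/filtered.vcf")

dir.create("results", showWarnings = FALSE)
tab <- data.frame(
  quantity = c("variants_in", "variants_retained", "dropped_maf",
               "dropped_missing_only"),
  value = c(nrow(g$variants), nrow(gf$variants),
            sum(st$maf <= 0.05),
            sum(st$maf > 0.05 & st$missing_fraction >= 0.25)))
write.table(tab, "results/02_filter_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Retained %d of %d SNPs (%.1f%%); filtered VCF in scratch/filtered.vcf\n",
            nrow(gf$variants), nrow(g$variants),
            100 * nrow(gf$variants) / nrow(g$variants)))
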