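#!/usr/bin/env Rscript
# Step 4: candidate genes and term enrichment.
#
# Reads each contrast's candidate regions (BED, 0-based half-open), extracts
# the genes whose bodies overlap them from the GFF3 annotation, and tests
# term over-representation with the upper-tail hypergeometric test under
# BH FDR <= 0.05 — per target and for the pooled union of all targets'
# selected genes.

suppressMessages(library(sweepscan))

genes <- read_gff_genes("scratch/fixture/genes.gff3")
terms <- read_term_map("scratch/fixture/terms.tsv")
targets <- list.dirs("scratch/scan", recursive = FALSE, full.names = FALSE)
targets <- setdiff(targets, "pooled")

per_target_genes <- list()
for (tg in targets) {
  bed <- file.path("scratch/scan", tg, "candidates.bed")
  b <- tryCatch(read.table(bed, sep = "\t",
                           col.names = c("chrom", "start", "end", "name")),
                error = function(e) NULL)   # empty BED -> no candidates
  per_target_genes[[tg]] <-
    if (is.null(b)) character() else genes_in_regions(b, genes)
}

dir.create("results", showWarnings = FALSE)
gene_counts <- data.frame(target = names(per_target_genes),
                          n_genes = lengths(per_target_genes))
write.table(gene_counts, "results/04_gene_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

pooled <- sort(unique(unlist(per_target_genes)))
enr <- hypergeom_enrich(pooled, terms, genes$gene_id, alpha = 0.05)
write.table(enr, "results/04_enrichment_pooled.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Candidate genes per target:\n")
print(gene_counts, row.names = FALSE)
cat(sprintf("\nPooled: %d genes; %d of %d terms significant at FDR <= 0.05\n",
            length(pooled), sum(enr$significant), nrow(enr)))
print(head(enr[, c("term_id", "k", "K", "n", "N", "p_value", "fdr",
                   "significant")], 3), row.names = FALSE)
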