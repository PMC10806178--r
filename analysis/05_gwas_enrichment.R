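#!/usr/bin/env Rscript
# Stage 5: SNP-density enrichment of the temporal clusters.
#
# SNPs are split at the genome-wide threshold (p < 5e-8) and linked to genes
# by symmetric TSS windows from 50 kb to 2.5 Mb; each cluster's ratio of
# significant to nonsignificant linked SNPs is contrasted against the rest
# of the genome by Pearson's chi-square. The planted cluster (late_up) is
# expected to dominate.

library(osteotempo)

snps <- classify_snps(read.delim("results/data/gwas_snps.tsv"), alpha = 5e-8)
ann <- read.delim("results/data/annotation.tsv")
clusters <- read.delim("results/clusters.tsv")

queries <- split(clusters$gene, clusters$archetype)
res <- cluster_snp_enrichment(snps, ann, queries,
                              windows = c(50, 100, 250, 500, 1000, 2500) * 1e3)
write_tsv(res, "results/snp_enrichment.tsv")

# cluster x window matrix of -log10 p for a quick look
m <- reshape(res[, c("cluster", "window", "pvalue")], idvar = "cluster",
             timevar = "window", direction = "wide")
m[-1] <- round(-log10(as.matrix(m[-1])), 1)
names(m) <- sub("pvalue.", "w", names(m))
write_tsv(m, "results/snp_enrichment_neglog10p.tsv")

message(sprintf("significant SNPs: %d of %d", sum(snps$significant), nrow(snps)))
top <- res[which.max(res$chi2), ]
message(sprintf("strongest enrichment: %s at %g kb window (chi2 = %.1f, p = %.3g)",
                top$cluster, top$window / 1e3, top$chi2, top$pvalue))
print(m, row.names = FALSE)
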