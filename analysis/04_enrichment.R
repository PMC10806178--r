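#!/usr/bin/env Rscript
# Stage 4: hypergeometric enrichment of the temporal clusters against the
# planted archetype gene sets (the synthetic analogue of testing clusters
# against external bone-biology collections), and a GSEA sanity run.

library(osteotempo)

de <- read.delim("results/de_timepoint.tsv")
clusters <- read.delim("results/clusters.tsv")
collection <- read_gmt("results/data/planted_sets.gmt")

universe <- de$gene[de$status == "tested"]
queries <- split(clusters$gene, paste0("cluster_", clusters$cluster))
res <- enrich_matrix(queries, collection, universe, adjust = TRUE)
write_tsv(res, "results/enrichment_clusters.tsv")

best <- do.call(rbind, lapply(split(res, res$query), function(d)
  d[which.min(d$pvalue), c("query", "set", "k", "pvalue", "fdr")]))
message("top enriched set per cluster:")
for (i in seq_len(nrow(best)))
  message(sprintf("  %-10s -> %-14s k=%3d  p=%.3g", best$query[i],
                  best$set[i], best$k[i], best$pvalue[i]))

# GSEA: rank genes by LRT statistic; the late_up planted set should lead
ranked <- de$gene[order(-de$stat)]
g <- gsea(ranked, intersect(collection$late_up, ranked), n_perm = 999, seed = 6)
message(sprintf("GSEA of planted late_up on the DE ranking: ES = %.3f, p = %.4f",
                g$es, g$pvalue))
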