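#!/usr/bin/env Rscript
# Stage 1: simulate the study world.
#
# Eight donors, four timepoints (days 0, 2, 5, 9), 2 000 genes; half the
# genes flat, the rest planted on the eight temporal archetypes with peak
# amplitude 2 log2 units and NB dispersion 0.05; 15% of genes are
# donor-discordant. Also simulates the GWAS SNP map around the planted
# late_up genes and a TF-target regulatory world for the network stages.

library(osteotempo)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 2000, n_donors = 8, effect_log2fc = 2,
                  nb_dispersion = 0.05, frac_null = 0.5,
                  frac_discordant = 0.15, seed = 1)
world <- generate_timecourse(cfg)
write_counts(world$counts, "results/data/counts.tsv")
write_tsv(world$design, "results/data/design.tsv")
write_tsv(world$truth, "results/data/truth.tsv")

ann <- generate_annotation(rownames(world$counts), seed = 2)
write_tsv(ann, "results/data/annotation.tsv")

late_up <- world$truth$gene_id[world$truth$archetype == "late_up" &
                                 world$truth$donor_consistent]
snps <- generate_gwas(ann, late_up, n_snps = 50000, window_bp = 250e3,
                      sig_rate_near = 0.2, sig_rate_bg = 0.02, seed = 3)
write_tsv(snps, "results/data/gwas_snps.tsv")

reg <- generate_regulatory_truth(n_tfs = 40, n_genes = 500,
                                 targets_per_tf = 10, n_clusters = 12,
                                 coupling = 0.8, seed = 4)
write_tsv(reg$truth, "results/data/regulatory_truth.tsv")
write_tsv(data.frame(gene = rownames(reg$motif_counts), reg$motif_counts,
                     check.names = FALSE), "results/data/motif_counts.tsv")
write_tsv(data.frame(gene = rownames(reg$cluster_expr), reg$cluster_expr,
                     check.names = FALSE), "results/data/cluster_expression.tsv")

planted <- split(world$truth$gene_id[world$truth$archetype != "null"],
                 world$truth$archetype[world$truth$archetype != "null"])
write_gmt(planted, "results/data/planted_sets.gmt")

message("simulated: ", nrow(world$counts), " genes x ", ncol(world$counts),
        " samples; ", nrow(snps), " SNPs; ",
        nrow(reg$truth), " true regulatory edges")
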