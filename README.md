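# osteotempo

Temporal transcriptomic analysis of human osteoclast differentiation.

Osteoclasts — the bone-resorbing cells implicated in osteoporosis — are
differentiated in vitro from CD14+ monocytes under M-CSF and RANKL, and bulk
RNA-seq is collected from several donors at a few timepoints (days 0, 2, 5, 9
in the default design). `osteotempo` implements the downstream analysis chain
for such time courses, for computational biologists who want each step as a
tested, scriptable function:

* **Differential expression**: median-of-ratios size factors; grouped
  method-of-moments dispersion with trend shrinkage; per-gene NB GLM
  likelihood-ratio tests of `~ donor + timepoint` vs `~ donor` (χ², df =
  #timepoints − 1, BH at FDR < 10⁻⁴); Wald association of counts with a
  continuous donor phenotype such as resorptive activity (moderated-t,
  BH at FDR < 10⁻²); plain log2 fold changes between days.
* **Temporal patterns**: a cross-donor reproducibility filter (gene kept when
  ≥ 6 of 8 donors have Pearson r > 0.8 to the mean profile) and k-means
  clustering (k = 8) of z-scored temporal profiles, with automatic labelling
  of cluster centroids as early/mid/late/transient, up/down archetypes.
* **Enrichment**: exact hypergeometric overlap tests in an explicit universe,
  and unweighted KS GSEA with permutation p-values.
* **GWAS**: SNP-density enrichment near transcription start sites — SNPs split
  at p < 5×10⁻⁸, linked to genes by symmetric TSS windows (50 kb – 2.5 Mb
  sweep), cluster-vs-genome 2×2 Pearson chi-square.
* **Regulatory networks**: a motif-activity response model (ridge regression
  of row-centered expression on promoter motif counts, `E ≈ N·A`, penalty by
  cross-validation), χ² differential-activity calls (p < 10⁻³),
  signal-to-noise–scored TF→target edges (edge at score > 2), NEAT-type
  directed network enrichment (`n_AB ~ Hypergeometric(W, i_B, o_A)`), per-TF
  regulator enrichment with BH, and TF–target Spearman coexpression on
  pseudo-bulk cluster expression.
* **Synthetic data**: generators for donor × timepoint NB counts with eight
  planted temporal archetypes and donor-discordant genes, GWAS SNP maps with
  planted TSS-proximal signal, TF–target regulatory worlds with tunable
  coexpression coupling, and count-coupled donor phenotypes — all with ground
  truth for recovery testing.

The methods vignette (`vignettes/osteotempo-methods.Rmd`) documents the
models, parameter defaults and numerical choices in detail.

## Worked example

The numbered scripts under `analysis/` run the whole chain on a simulated
study (2 000 genes, 8 donors, 4 timepoints, planted archetypes at 2 log2
units amplitude, NB dispersion 0.05):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_temporal_patterns.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_gwas_enrichment.R
Rscript analysis/06_regulatory_network.R
```

which prints, stage by stage:

```
simulated: 2000 genes x 32 samples; 50000 SNPs; 400 true regulatory edges
differentially expressed: 706 of 2000 genes (FDR < 1e-4)
recall on donor-consistent planted signal: 1.000; false calls on null: 0
reproducible: 706 genes; clustered: 700 genes; ARI vs truth: 0.990
cluster archetypes: early_down, early_up, late_down, late_up, mid_down, mid_up, transient_down, transient_up
GSEA of planted late_up on the DE ranking: ES = 0.458, p = 0.0010
significant SNPs: 2575 of 50000
strongest enrichment: late_up at 250 kb window (chi2 = 4611.1, p = 0)
lambda = 0.001; activity recovery r = 0.9998
edges: 400 (precision 1.000, recall 1.000); differential motifs: 40 of 40
TF-target coexpression (coupling 0.8): median rho = 0.759 over 40 TFs
```

Reading the numbers: of 1 000 genes carrying a planted temporal profile, the
LRT recovers every donor-consistent one at FDR < 10⁻⁴ with zero false calls
on flat genes; the reproducibility filter then removes donor-discordant
genes, and k-means on the surviving profiles reconstructs the eight planted
archetypes essentially perfectly (adjusted Rand index 0.99, one cluster per
archetype). The cluster whose genes carry the planted excess of genome-wide
significant SNPs near their TSSs dominates the chi-square sweep at every
window, and the regulatory stage re-estimates the planted motif activities
(r ≈ 1) and recovers the TF→target network exactly at the score > 2 edge
rule. Each stage writes its tables under `results/`.

The same chain is available programmatically via `run_all(pipeline_config(...))`,
which writes every stage output plus a checksummed manifest and the resolved
configuration, and halts naming the failing stage if an input is missing.

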