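Package: osteotempo
Title: Temporal Transcriptomic Analysis of Osteoclast Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for time-course RNA-seq of human osteoclast
    differentiation. Provides negative-binomial GLM differential expression
    with donor blocking and continuous-phenotype association, cross-donor
    reproducibility filtering, k-means discovery of temporal expression
    archetypes, hypergeometric and KS-type gene-set enrichment, SNP-density
    enrichment of GWAS summary statistics in windows around transcription
    start sites, motif-activity response modelling by ridge regression with
    scored transcription-factor target edges, directed network enrichment
    (NEAT-type) between gene groups, and TF-target coexpression ranking on
    pseudo-bulk cluster expression. A synthetic-data module generates donor
    by timepoint count matrices with planted temporal archetypes, GWAS SNP
    maps with planted TSS-proximal signal, regulatory networks with tunable
    TF-target coupling, and count-coupled donor phenotypes, with ground-truth
    labels for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
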