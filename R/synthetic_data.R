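#' Simulation configuration for the time-course generator
#'
#' Bundles and validates the parameters of [generate_timecourse()]. Defaults
#' emulate the study design the analysis assumes: eight donors sampled on
#' days 0, 2, 5 and 9, negative-binomial counts with dispersion 0.05, a peak
#' planted amplitude of 2 log2 units, half of the genes flat, and a modest
#' fraction of genes whose temporal profile is not shared between donors.
#'
#' @param n_genes Number of genes.
#' @param n_donors Number of donors (>= 2).
#' @param timepoints_days Strictly increasing vector of sampling days
#'   (>= 3 timepoints).
#' @param nb_dispersion Negative-binomial dispersion alpha (>= 0; 0 gives
#'   Poisson counts).
#' @param effect_log2fc Peak amplitude of the planted archetype profiles,
#'   in log2 units.
#' @param frac_null Fraction of genes with a flat (null) profile.
#' @param frac_discordant Fraction of genes whose per-donor profiles are
#'   drawn independently (donor-discordant genes).
#' @param donor_lsf_sd Standard deviation of the log-normal per-donor
#'   library-size factors.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   per-gene baseline expected count.
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_donors = 8,
                       timepoints_days = c(0, 2, 5, 9),
                       nb_dispersion = 0.05, effect_log2fc = 2,
                       frac_null = 0.5, frac_discordant = 0.15,
                       donor_lsf_sd = 0.3,
                       base_mean_meanlog = log(200), base_mean_sdlog = 1,
                       seed = 1) {
  if (n_donors < 2) stop("n_donors must be >= 2: downstream models are unidentifiable")
  if (length(timepoints_days) < 3) stop("need at least 3 timepoints")
  if (is.unsorted(timepoints_days, strictly = TRUE))
    stop("timepoints_days must be strictly increasing")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  .assert_prob(frac_null, "frac_null")
  .assert_prob(frac_discordant, "frac_discordant")
  if (frac_null + frac_discordant > 1)
    stop("frac_null + frac_discordant must not exceed 1")
  structure(list(
    n_genes = as.integer(n_genes), n_donors = as.integer(n_donors),
    timepoints_days = timepoints_days, nb_dispersion = nb_dispersion,
    effect_log2fc = effect_log2fc, frac_null = frac_null,
    frac_discordant = frac_discordant, donor_lsf_sd = donor_lsf_sd,
    base_mean_meanlog = base_mean_meanlog, base_mean_sdlog = base_mean_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a donor-by-timepoint RNA-seq count matrix with planted archetypes
#'
#' Counts are drawn from a negative binomial with mean
#' `library_factor(donor) * base_mean(gene) * 2^profile(gene, day)`, where the
#' profile is the gene's archetype evaluated at the study days
#' (see [archetype_profile()]). Donor-consistent genes share one profile
#' across donors; donor-discordant genes get an independently drawn archetype
#' per donor. Per-donor library-size factors are log-normal so that size
#' factor estimation is non-trivial. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (integer matrix genes x samples), `design`
#'   (data.frame sample / donor / day), and `truth` (data.frame gene_id /
#'   archetype / base_mean / donor_consistent).
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  D <- config$n_donors
  tp <- config$timepoints_days
  TT <- length(tp)

  gene_id <- sprintf("g%05d", seq_len(G))
  donors <- sprintf("D%d", seq_len(D))
  design <- data.frame(
    sample = paste0(rep(donors, each = TT), "_d", rep(tp, D)),
    donor = rep(donors, each = TT),
    day = rep(tp, D),
    stringsAsFactors = FALSE
  )

  base_mean <- stats::rlnorm(G, config$base_mean_meanlog, config$base_mean_sdlog)
  lib_factor <- exp(stats::rnorm(D, 0, config$donor_lsf_sd))

  n_null <- round(config$frac_null * G)
  n_disc <- round(config$frac_discordant * G)
  archetype <- c(rep("null", n_null),
                 rep_len(ARCHETYPES, G - n_null))
  donor_consistent <- rep(TRUE, G)
  signal_idx <- which(archetype != "null")
  disc_idx <- if (n_disc > 0) sample(signal_idx, min(n_disc, length(signal_idx))) else integer(0)
  donor_consistent[disc_idx] <- FALSE

  # log2 profiles per archetype at the study days
  prof <- vapply(c("null", ARCHETYPES), archetype_profile,
                 numeric(TT), timepoints = tp, amplitude = config$effect_log2fc)
  # G x T profile matrix for the consistent world
  P <- t(prof[, archetype, drop = FALSE])

  # expand to G x S (samples ordered donor-major as in `design`)
  log2fc <- P[, rep(seq_len(TT), D), drop = FALSE]
  # discordant genes: independent archetype per donor
  if (length(disc_idx) > 0) {
    disc_arch <- matrix(sample(ARCHETYPES, length(disc_idx) * D, replace = TRUE),
                        nrow = length(disc_idx))
    for (d in seq_len(D)) {
      cols <- (d - 1) * TT + seq_len(TT)
      log2fc[disc_idx, cols] <- t(prof[, disc_arch[, d], drop = FALSE])
    }
  }

  mu <- base_mean * 2^log2fc
  mu <- sweep(mu, 2, rep(lib_factor, each = TT), `*`)
  n <- length(mu)
  counts <- if (config$nb_dispersion > 0) {
    stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  } else {
    stats::rpois(n, mu)
  }
  counts <- matrix(as.integer(counts), nrow = G,
                   dimnames = list(gene_id, design$sample))

  truth <- data.frame(gene_id = gene_id, archetype = archetype,
                      base_mean = base_mean,
                      donor_consistent = donor_consistent,
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth)
}

#' Place gene TSSs uniformly on a synthetic genome
#'
#' One linear chromosome; window logic downstream is position arithmetic
#' only, so a single chromosome suffices.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param genome_size Chromosome length in bp (default 250 Mb).
#' @param seed Integer RNG seed.
#' @return Data.frame with gene_id, chrom, tss (0-based bp), strand.
#' @export
generate_annotation <- function(gene_ids, genome_size = 250e6, seed = 1) {
  set.seed(seed)
  data.frame(
    gene_id = gene_ids,
    chrom = "chr1",
    tss = floor(stats::runif(length(gene_ids), 0, genome_size)),
    strand = sample(c("+", "-"), length(gene_ids), replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate GWAS summary statistics with planted TSS-proximal signal
#'
#' SNPs are placed uniformly on the synthetic genome. A SNP lying within
#' `window_bp` of the TSS of any target gene is genome-wide significant
#' (p drawn below 5e-8) with probability `sig_rate_near`, any other SNP with
#' probability `sig_rate_bg`. Setting the two rates equal gives a null world
#' in which downstream window enrichment should be calibrated.
#'
#' @param annotation Gene annotation as from [generate_annotation()].
#' @param target_genes Character vector of genes carrying the planted excess.
#' @param n_snps Number of SNPs.
#' @param window_bp Window half-width in bp (> 0).
#' @param sig_rate_near,sig_rate_bg Significance probabilities in [0, 1].
#' @param seed Integer RNG seed.
#' @param alpha Genome-wide significance level used to draw p-values.
#' @param genome_size Chromosome length; defaults to just past the last TSS.
#' @return Data.frame with snp, chrom, pos (0-based), pval.
#' @export
generate_gwas <- function(annotation, target_genes, n_snps, window_bp,
                          sig_rate_near, sig_rate_bg, seed = 1,
                          alpha = 5e-8, genome_size = NULL) {
  if (nrow(annotation) == 0) stop("annotation must be non-empty")
  if (window_bp <= 0) stop("window_bp must be > 0")
  .assert_prob(sig_rate_near, "sig_rate_near")
  .assert_prob(sig_rate_bg, "sig_rate_bg")
  set.seed(seed)
  genome_size <- genome_size %||% (max(annotation$tss) + 1e6)
  if (n_snps == 0) {
    return(data.frame(snp = character(0), chrom = character(0),
                      pos = integer(0), pval = numeric(0)))
  }
  pos <- floor(stats::runif(n_snps, 0, genome_size))
  chrom <- rep(annotation$chrom[1], n_snps)
  tss <- annotation$tss[annotation$gene_id %in% target_genes]
  near <- if (length(tss) > 0) {
    .min_dist(pos, sort(tss)) <= window_bp
  } else rep(FALSE, n_snps)
  rate <- ifelse(near, sig_rate_near, sig_rate_bg)
  sig <- stats::runif(n_snps) < rate
  pval <- ifelse(sig, stats::runif(n_snps) * alpha,
                 alpha + stats::runif(n_snps) * (1 - alpha))
  data.frame(snp = sprintf("rs%07d", seq_len(n_snps)), chrom = chrom,
             pos = pos, pval = pval, stringsAsFactors = FALSE)
}

# minimal distance from each position to a sorted vector of anchors
.min_dist <- function(pos, anchors) {
  idx <- findInterval(pos, anchors)
  left <- ifelse(idx >= 1, pos - anchors[pmax(idx, 1)], Inf)
  right <- ifelse(idx < length(anchors), anchors[pmin(idx + 1, length(anchors))] - pos, Inf)
  pmin(abs(left), abs(right))
}

#' Simulate a TF-target regulatory world with tunable coexpression coupling
#'
#' Builds a ground-truth directed network (each TF regulating
#' `targets_per_tf` genes, disjoint across TFs while the gene pool lasts), a
#' promoter motif-count matrix whose entries are nonzero exactly on true
#' TF-target pairs, and pseudo-bulk cluster expression in which the summed
#' expression of a TF's targets tracks the TF's own expression across
#' clusters with expected Pearson correlation `coupling`.
#'
#' @param n_tfs,n_genes Number of TFs and of (non-TF) target-pool genes.
#' @param targets_per_tf Targets per TF (<= n_genes).
#' @param n_clusters Number of pseudo-bulk clusters.
#' @param coupling Expected TF vs target-sum correlation in [0, 1].
#' @param seed Integer RNG seed.
#' @return List with `truth` (data.frame tf / target), `motif_counts`
#'   (genes x motifs matrix), `cluster_expr` (matrix, rows = TFs then genes,
#'   columns = clusters), and `tf_ids`.
#' @export
generate_regulatory_truth <- function(n_tfs, n_genes, targets_per_tf,
                                      n_clusters, coupling, seed = 1) {
  if (targets_per_tf > n_genes) stop("targets_per_tf must be <= n_genes")
  .assert_prob(coupling, "coupling")
  set.seed(seed)
  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  gene_ids <- sprintf("t%05d", seq_len(n_genes))

  pool <- sample(gene_ids)                    # randomized disjoint allocation
  edges <- vector("list", n_tfs)
  used <- 0
  for (i in seq_len(n_tfs)) {
    if (targets_per_tf == 0) { edges[[i]] <- character(0); next }
    if (used + targets_per_tf <= n_genes) {
      tg <- pool[used + seq_len(targets_per_tf)]
      used <- used + targets_per_tf
    } else {
      tg <- sample(gene_ids, targets_per_tf)  # pool exhausted: allow overlap
    }
    edges[[i]] <- tg
  }
  truth <- data.frame(
    tf = rep(tf_ids, lengths(edges)),
    target = unlist(edges),
    stringsAsFactors = FALSE
  )

  motif_counts <- matrix(0L, n_genes, n_tfs, dimnames = list(gene_ids, tf_ids))
  if (nrow(truth) > 0) {
    ij <- cbind(match(truth$target, gene_ids), match(truth$tf, tf_ids))
    motif_counts[ij] <- stats::rpois(nrow(ij), 1) + 1L
  }

  # cluster-level expression: TF rows drive their targets' shared component
  tf_expr <- matrix(stats::rnorm(n_tfs * n_clusters), n_tfs,
                    dimnames = list(tf_ids, sprintf("C%d", seq_len(n_clusters))))
  gene_expr <- matrix(stats::rnorm(n_genes * n_clusters), n_genes,
                      dimnames = list(gene_ids, colnames(tf_expr)))
  for (i in seq_len(n_tfs)) {
    tg <- edges[[i]]
    if (length(tg) == 0) next
    z <- as.numeric(scale(tf_expr[i, ]))
    k <- length(tg)
    if (coupling >= 1) {
      gene_expr[tg, ] <- matrix(rep(z / k, k), nrow = k, byrow = TRUE)
    } else if (coupling > 0) {
      b <- coupling / sqrt(k * (1 - coupling^2))
      gene_expr[tg, ] <- b * matrix(rep(z, k), nrow = k, byrow = TRUE) +
        matrix(stats::rnorm(k * n_clusters), k)
    } # coupling == 0: keep independent noise
  }
  cluster_expr <- rbind(tf_expr, gene_expr)
  list(truth = truth, motif_counts = motif_counts,
       cluster_expr = cluster_expr, tf_ids = tf_ids)
}

#' Simulate expression from planted motif activities
#'
#' `E = N A + noise`, the generative model inverted by
#' [fit_motif_activity()]. The planted activity matrix is row-centered so
#' activities are deviations across samples.
#'
#' @param motif_counts Genes x motifs site-count matrix.
#' @param activity Motifs x samples planted activity matrix.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer RNG seed.
#' @return Genes x samples expression matrix (log-scale units).
#' @export
simulate_motif_expression <- function(motif_counts, activity, noise_sd = 0.1,
                                      seed = 1) {
  stopifnot(ncol(motif_counts) == nrow(activity))
  set.seed(seed)
  activity <- activity - rowMeans(activity)
  E <- motif_counts %*% activity +
    matrix(stats::rnorm(nrow(motif_counts) * ncol(activity), 0, noise_sd),
           nrow(motif_counts))
  dimnames(E) <- list(rownames(motif_counts), colnames(activity))
  E
}

#' Couple a donor phenotype to a gene signature in simulated counts
#'
#' Draws a per-donor phenotype uniform on [0, 1] (e.g. percent eroded bone
#' surface rescaled) and multiplies the counts of signature genes in every
#' sample of a donor by `2^(slope * phenotype)`, rounding back to integers.
#' Non-signature genes are untouched; with `slope = 0` the matrix is returned
#' bit-identical.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param design Sample design data.frame with `sample` and `donor`.
#' @param signature Character vector of signature genes (non-empty subset of
#'   `rownames(counts)`).
#' @param slope_log2_per_unit Log2 fold change per phenotype unit.
#' @param seed Integer RNG seed.
#' @return List with modified `counts` and `phenotype` (named per-donor
#'   vector).
#' @export
generate_phenotype <- function(counts, design, signature,
                               slope_log2_per_unit, seed = 1) {
  if (length(signature) == 0) stop("signature must be non-empty")
  if (!all(signature %in% rownames(counts)))
    stop("signature genes must all be present in counts")
  set.seed(seed)
  donors <- unique(design$donor)
  phenotype <- stats::runif(length(donors))
  names(phenotype) <- donors
  fac <- 2^(slope_log2_per_unit * phenotype[design$donor])
  counts[signature, ] <- matrix(
    as.integer(round(sweep(counts[signature, , drop = FALSE], 2, fac, `*`))),
    nrow = length(signature))
  list(counts = counts, phenotype = phenotype)
}
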