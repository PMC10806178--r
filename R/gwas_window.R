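#' Classify GWAS SNPs by genome-wide significance
#'
#' Strict threshold: a SNP is significant iff `pvalue < alpha`
#' (default 5e-8); a p-value exactly at the threshold is nonsignificant.
#'
#' @param snps Data.frame with at least `pval` (plus snp/chrom/pos).
#' @param alpha Significance level.
#' @return The input with a logical `significant` column.
#' @export
classify_snps <- function(snps, alpha = 5e-8) {
  if (nrow(snps) > 0) .assert_prob(snps$pval, "pval")
  snps$significant <- snps$pval < alpha
  snps
}

# per-SNP logical: within `window` bp of any TSS in `ann` (same chromosome,
# closed interval at the boundary)
.snps_linked <- function(snps, ann, window) {
  linked <- rep(FALSE, nrow(snps))
  for (ch in unique(ann$chrom)) {
    tss <- sort(ann$tss[ann$chrom == ch])
    idx <- which(snps$chrom == ch)
    if (length(idx) == 0 || length(tss) == 0) next
    linked[idx] <- .min_dist(snps$pos[idx], tss) <= window
  }
  linked
}

#' Link SNPs to genes by a symmetric TSS window
#'
#' A SNP is linked to a gene when both lie on the same chromosome and
#' `|pos - tss| <= window` (closed interval; strand ignored). A SNP may link
#' to several genes. SNPs on chromosomes absent from the annotation are
#' counted and left unlinked.
#'
#' @param snps Classified SNP table (see [classify_snps()]).
#' @param ann Gene annotation (gene_id, chrom, tss).
#' @param window Window half-width in bp (> 0).
#' @return List with `gene_counts` (data.frame gene, n_sig, n_nonsig) and
#'   `snp_genes` (list of linked gene-id vectors, one per SNP).
#' @export
assign_snps_to_genes <- function(snps, ann, window) {
  if (window <= 0) stop("window must be > 0")
  stopifnot(!is.null(snps$significant))
  n_sig <- n_nonsig <- integer(nrow(ann))
  snp_genes <- vector("list", nrow(snps))
  unmatched <- !snps$chrom %in% ann$chrom
  if (any(unmatched))
    message(sum(unmatched), " SNP(s) on chromosomes absent from annotation; unlinked")
  for (ch in unique(ann$chrom)) {
    gi <- which(ann$chrom == ch)
    si <- which(snps$chrom == ch)
    if (length(si) == 0) next
    ord <- si[order(snps$pos[si])]
    pos <- snps$pos[ord]
    sig <- snps$significant[ord]
    csig <- c(0, cumsum(sig))
    for (g in gi) {
      lo <- .bisect_left(pos, ann$tss[g] - window)
      hi <- .bisect_right(pos, ann$tss[g] + window)
      if (hi < lo) next
      n_sig[g] <- csig[hi + 1] - csig[lo]
      n_nonsig[g] <- (hi - lo + 1) - n_sig[g]
      for (j in ord[lo:hi]) {
        snp_genes[[j]] <- c(snp_genes[[j]], ann$gene_id[g])
      }
    }
  }
  list(gene_counts = data.frame(gene = ann$gene_id, n_sig = n_sig,
                                n_nonsig = n_nonsig, stringsAsFactors = FALSE),
       snp_genes = snp_genes)
}

# first index with x[i] >= v and last index with x[i] <= v, on sorted x
.bisect_left <- function(x, v) findInterval(v - 0.5, x) + 1L
.bisect_right <- function(x, v) findInterval(v + 0.5, x)

# Pearson chi-square on a 2x2 table, closed form, no continuity correction
.chi2_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' SNP-density enrichment of gene clusters over TSS windows
#'
#' For every cluster and window, SNPs are partitioned into those linked to at
#' least one cluster gene versus the remainder of the genome, and into
#' genome-wide significant versus nonsignificant, giving a 2x2 table tested
#' by Pearson's chi-square (df = 1, no continuity correction). A SNP near
#' genes of several clusters counts in each cluster's test independently.
#' The default background is exclusive (SNPs not linked to the cluster);
#' `background = "inclusive"` contrasts the cluster-linked ratio against all
#' SNPs instead.
#'
#' @param snps Classified SNP table.
#' @param ann Gene annotation.
#' @param clusters Named list of gene sets or a `cluster_assignment`.
#' @param windows Numeric vector of window half-widths in bp (default sweep
#'   50 kb to 2.5 Mb).
#' @return Data.frame per (cluster, window): cells a, b, c, d (cluster-sig,
#'   cluster-nonsig, other-sig, other-nonsig), ratio_cluster, ratio_genome,
#'   chi2, df, pvalue, degenerate.
#' @export
cluster_snp_enrichment <- function(snps, ann, clusters,
                                   windows = c(50, 100, 250, 500, 1000, 2500) * 1e3,
                                   background = c("exclusive", "inclusive")) {
  background <- match.arg(background)
  if (length(windows) == 0) stop("windows must be non-empty")
  if (inherits(clusters, "cluster_assignment")) clusters <- cluster_sets(clusters)
  stopifnot(!is.null(snps$significant))
  sig <- snps$significant
  out <- list()
  for (cl in names(clusters)) {
    ann_cl <- ann[ann$gene_id %in% clusters[[cl]], , drop = FALSE]
    for (w in windows) {
      linked <- if (nrow(ann_cl) > 0) .snps_linked(snps, ann_cl, w) else rep(FALSE, nrow(snps))
      a <- sum(linked & sig)
      b <- sum(linked & !sig)
      if (background == "exclusive") {
        c_ <- sum(!linked & sig)
        d <- sum(!linked & !sig)
      } else {
        c_ <- sum(sig)
        d <- sum(!sig)
      }
      degen <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
      chi2 <- if (degen) NA_real_ else .chi2_2x2(a, b, c_, d)
      out[[length(out) + 1]] <- data.frame(
        cluster = cl, window = w, a = a, b = b, c = c_, d = d,
        ratio_cluster = if (a + b > 0) a / (a + b) else NA_real_,
        ratio_genome = if (c_ + d > 0) c_ / (c_ + d) else NA_real_,
        chi2 = chi2, df = 1,
        pvalue = if (degen) NA_real_ else stats::pchisq(chi2, 1, lower.tail = FALSE),
        degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
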