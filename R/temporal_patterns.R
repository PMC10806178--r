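#' Per-donor log2 expression profiles over the time course
#'
#' `log2(normalized count + 1)` for every gene, donor and timepoint, plus the
#' cross-donor mean profile. Requires a complete design: every donor observed
#' exactly once at every timepoint.
#'
#' @param counts Genes x samples count matrix.
#' @param sf Size factors.
#' @param design Sample design with `sample`, `donor`, `day`.
#' @return List with `profiles` (array gene x donor x timepoint),
#'   `mean_profile` (matrix gene x timepoint), `donors`, `timepoints`.
#' @export
donor_profiles <- function(counts, sf, design) {
  counts <- as.matrix(counts)
  donors <- unique(design$donor)
  tps <- sort(unique(design$day))
  tab <- table(design$donor, design$day)
  if (any(tab != 1))
    stop("design must contain exactly one sample per (donor, timepoint) cell")
  q <- sweep(counts, 2, sf, `/`)
  lp <- log2(q + 1)
  profiles <- array(NA_real_, dim = c(nrow(counts), length(donors), length(tps)),
                    dimnames = list(rownames(counts), donors, paste0("d", tps)))
  for (d in seq_along(donors)) {
    for (t in seq_along(tps)) {
      j <- which(design$donor == donors[d] & design$day == tps[t])
      profiles[, d, t] <- lp[, j]
    }
  }
  mean_profile <- apply(profiles, c(1, 3), mean)
  list(profiles = profiles, mean_profile = mean_profile,
       donors = donors, timepoints = tps)
}

#' Cross-donor reproducibility filter
#'
#' For each gene and donor, the Pearson correlation between the donor's
#' timepoint profile and the cross-donor mean profile. A gene is kept when at
#' least `min_donors` donors exceed `r_threshold` (defaults 6 of 8 donors at
#' r > 0.8). Correlations are NA when either profile has zero variance, and
#' NA never counts as a pass, so flat genes are excluded by construction.
#'
#' @param profiles Output of [donor_profiles()].
#' @param r_threshold Pearson correlation threshold (strict >).
#' @param min_donors Minimum number of passing donors.
#' @return List with `kept` (character vector of gene ids) and `records`
#'   (data.frame: gene, r_<donor> columns, n_pass, kept).
#' @export
reproducibility_filter <- function(profiles, r_threshold = 0.8, min_donors = 6) {
  if (length(profiles$timepoints) < 3)
    stop("need >= 3 timepoints for a meaningful profile correlation")
  arr <- profiles$profiles
  mp <- profiles$mean_profile
  r <- vapply(seq_along(profiles$donors), function(d) {
    .row_cor(arr[, d, , drop = TRUE], mp)
  }, numeric(nrow(mp)))
  colnames(r) <- paste0("r_", profiles$donors)
  n_pass <- rowSums(r > r_threshold, na.rm = TRUE)
  kept <- n_pass >= min_donors
  records <- data.frame(gene = rownames(mp), r, n_pass = n_pass, kept = kept,
                        stringsAsFactors = FALSE, check.names = FALSE)
  rownames(records) <- NULL
  list(kept = rownames(mp)[kept], records = records)
}

#' K-means clustering of temporal profiles
#'
#' Donor-averaged log2 profiles are z-scored across timepoints and clustered
#' by Euclidean k-means, keeping the best of `n_init` restarts by
#' within-cluster sum of squares. Genes with zero profile variance cannot be
#' z-scored and are excluded with a warning (the reproducibility filter
#' normally removes them first). Deterministic given `seed`.
#'
#' @param mean_profile Gene x timepoint matrix (e.g.
#'   `donor_profiles()$mean_profile` restricted to kept genes).
#' @param k Number of clusters (default 8).
#' @param n_init Number of random restarts.
#' @param seed Integer RNG seed.
#' @param timepoints Numeric vector of days (defaults to column index).
#' @return Object of class `cluster_assignment`: list with `assignment`
#'   (data.frame gene / cluster), `centroids` (k x timepoints, z-scored),
#'   `k`, `timepoints`, `tot_withinss`.
#' @export
kmeans_cluster <- function(mean_profile, k = 8, n_init = 50, seed = 1,
                           timepoints = NULL) {
  stopifnot(is.matrix(mean_profile))
  if (nrow(mean_profile) < k) stop("need at least k genes to form k clusters")
  z <- .row_zscore(mean_profile)
  bad <- rowSums(is.na(z)) > 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero profile variance excluded from clustering")
    z <- z[!bad, , drop = FALSE]
    if (nrow(z) < k) stop("too few genes with profile variance left to cluster")
  }
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100)
  centroids <- .row_zscore(km$centers)
  rownames(centroids) <- seq_len(k)
  structure(list(
    assignment = data.frame(gene = rownames(z), cluster = unname(km$cluster),
                            stringsAsFactors = FALSE),
    centroids = centroids,
    k = k,
    timepoints = timepoints %||% seq_len(ncol(mean_profile)),
    tot_withinss = km$tot.withinss
  ), class = "cluster_assignment")
}

#' Split a cluster assignment into named gene sets
#'
#' @param ca A `cluster_assignment`.
#' @return Named list of character vectors, one per cluster.
#' @export
cluster_sets <- function(ca) {
  stopifnot(inherits(ca, "cluster_assignment"))
  split(ca$assignment$gene, paste0("cluster_", ca$assignment$cluster))
}
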