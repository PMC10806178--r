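#' Motif activity by ridge regression of expression on promoter motif counts
#'
#' Fits, per sample, the linear activity model `E[g, s] = sum_m N[g, m]
#' A[m, s]` by ridge regression: `A` minimizes
#' `sum_gs (E_gs - (N A)_gs)^2 + lambda * sum_ms A_ms^2`, with the closed
#' form `A = (N'N + lambda I)^{-1} N' E`. Expression rows are centered across
#' samples first, so activities are deviations and each activity row sums to
#' zero. `lambda = "auto"` picks the penalty from a log-spaced grid by
#' 5-fold cross-validated prediction error over genes. Standard errors come
#' from the ridge covariance `sigma_s^2 (N'N + lambda I)^{-1} N'N
#' (N'N + lambda I)^{-1}` with per-sample residual variance on effective
#' degrees of freedom.
#'
#' @param E Expression matrix, genes x samples (log scale).
#' @param N Motif count matrix, genes x motifs (non-negative).
#' @param lambda Ridge penalty (>= 0) or `"auto"`.
#' @param n_folds Folds for cross-validation.
#' @param seed Seed for the fold split.
#' @return Object of class `mara_fit`: activity (motifs x samples), stderr,
#'   lambda, sigma_g (per-gene residual sd), residuals, motif_counts, genes,
#'   motifs.
#' @export
fit_motif_activity <- function(E, N, lambda = "auto", n_folds = 5, seed = 1) {
  stopifnot(is.matrix(E), is.matrix(N))
  if (any(N < 0)) stop("motif counts must be non-negative")
  genes <- intersect(rownames(E), rownames(N))
  if (length(genes) > 0) {
    E <- E[genes, , drop = FALSE]
    N <- N[genes, , drop = FALSE]
  } else if (nrow(E) == nrow(N)) {
    genes <- rownames(E) %||% as.character(seq_len(nrow(E)))
  } else {
    stop("E and N share no genes")
  }
  if (nrow(E) < 2) stop("need at least 2 genes")
  if (ncol(E) < 2) stop("need at least 2 samples")
  E <- E - rowMeans(E)

  if (identical(lambda, "auto")) {
    lambda <- .ridge_cv_lambda(E, N, n_folds, seed)
  }
  stopifnot(is.numeric(lambda), lambda >= 0)

  M <- ncol(N)
  NtN <- crossprod(N)
  Minv <- solve(NtN + diag(lambda, M))
  A <- Minv %*% crossprod(N, E)
  fitted <- N %*% A
  res <- E - fitted

  H_trace <- sum(diag(NtN %*% Minv))               # effective df per sample
  df_res <- max(nrow(E) - H_trace, 1)
  sigma2_s <- colSums(res^2) / df_res
  V <- diag(Minv %*% NtN %*% Minv)
  stderr <- sqrt(outer(pmax(V, 0), sigma2_s))
  dimnames(stderr) <- dimnames(A) <- list(colnames(N), colnames(E))

  sigma_g <- pmax(sqrt(.row_vars(res)), 1e-6)
  names(sigma_g) <- genes
  structure(list(activity = A, stderr = stderr, lambda = lambda,
                 sigma_g = sigma_g, residuals = res, motif_counts = N,
                 genes = genes, motifs = colnames(N)),
            class = "mara_fit")
}

# 5-fold CV over genes on a log-spaced lambda grid
.ridge_cv_lambda <- function(E, N, n_folds, seed) {
  set.seed(seed)
  G <- nrow(E)
  folds <- sample(rep_len(seq_len(n_folds), G))
  grid <- 10^seq(-3, 5, by = 1)
  M <- ncol(N)
  err <- vapply(grid, function(lam) {
    sse <- 0
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      Ntr <- N[tr, , drop = FALSE]
      A <- tryCatch(
        solve(crossprod(Ntr) + diag(lam, M), crossprod(Ntr, E[tr, , drop = FALSE])),
        error = function(e) NULL)
      if (is.null(A)) return(Inf)
      pred <- N[!tr, , drop = FALSE] %*% A
      sse <- sse + sum((E[!tr, , drop = FALSE] - pred)^2)
    }
    sse
  }, numeric(1))
  grid[which.min(err)]
}

#' Chi-square test for non-constant motif activity across samples
#'
#' Per motif, `sum_s (A_ms / se_ms)^2` referred to chi-square with
#' `#samples - 1` degrees of freedom (activities are centered). Motifs are
#' called differentially active at `p_threshold` (default 1e-3). Motifs with
#' a zero standard error are flagged degenerate.
#'
#' @param fit A `mara_fit`.
#' @param p_threshold Call threshold.
#' @return Data.frame: motif, stat, df, pvalue, differential, degenerate.
#' @export
activity_significance <- function(fit, p_threshold = 1e-3) {
  stopifnot(inherits(fit, "mara_fit"))
  A <- fit$activity
  se <- fit$stderr
  degen <- apply(se == 0, 1, any)
  stat <- rowSums((A / ifelse(se == 0, NA, se))^2)
  stat[degen] <- NA_real_
  df <- ncol(A) - 1
  pvalue <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  data.frame(motif = rownames(A), stat = stat, df = df, pvalue = pvalue,
             differential = !is.na(pvalue) & pvalue < p_threshold,
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Signal-to-noise target scores for TF-target edges
#'
#' `score(g, m) = N[g, m] * sd_s(A[m, ]) / sigma_g`, where `sigma_g` is the
#' gene's residual standard deviation under the fitted activity model
#' (floored at 1e-6). The score is zero wherever the promoter carries no
#' motif site, scales linearly in the site count, and a pair becomes a
#' network edge when the score exceeds the threshold (strict, default 2 --
#' roughly two residual standard deviations of leverage).
#'
#' @param fit A `mara_fit`.
#' @param as_matrix Return the full genes x motifs score matrix instead of
#'   the long form.
#' @return Long data.frame (tf, target, score) over pairs with a nonzero
#'   motif count, or the full score matrix.
#' @export
score_targets <- function(fit, as_matrix = FALSE) {
  stopifnot(inherits(fit, "mara_fit"))
  sd_a <- apply(fit$activity, 1, stats::sd)
  S <- sweep(sweep(fit$motif_counts, 2, sd_a, `*`), 1, fit$sigma_g, `/`)
  if (as_matrix) return(S)
  idx <- which(fit$motif_counts > 0, arr.ind = TRUE)
  data.frame(tf = colnames(S)[idx[, 2]], target = rownames(S)[idx[, 1]],
             score = S[idx], stringsAsFactors = FALSE)
}
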