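#' Hypergeometric overlap enrichment
#'
#' Exact tail probability of the observed overlap between a query and a
#' target gene set inside an explicit universe: `P(X >= k)` for
#' over-enrichment, `P(X <= k)` for under-enrichment, with
#' `X ~ Hypergeometric(N, K, n)` (universe size N, target size K, query size
#' n). Genes outside the universe are dropped with a message.
#'
#' @param query,target Character vectors of gene identifiers.
#' @param universe Character vector defining the universe (non-empty).
#' @param direction `"over"` or `"under"`.
#' @param query_name,set_name Labels carried into the result.
#' @return One-row data.frame: query, set, k (overlap), n (query size),
#'   K (set size), N (universe size), pvalue, direction.
#' @examples
#' u <- letters[1:10]
#' hypergeom_overlap(letters[1:5], letters[1:5], u)$pvalue  # 1/252
#' @export
hypergeom_overlap <- function(query, target, universe,
                              direction = c("over", "under"),
                              query_name = "query", set_name = "set") {
  direction <- match.arg(direction)
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe must be non-empty")
  q <- unique(query)
  t <- unique(target)
  dropped <- sum(!q %in% universe) + sum(!t %in% universe)
  if (dropped > 0)
    message(dropped, " gene(s) outside the universe dropped")
  q <- intersect(q, universe)
  t <- intersect(t, universe)
  N <- length(universe)
  K <- length(t)
  n <- length(q)
  k <- length(intersect(q, t))
  pvalue <- if (direction == "over") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n)
  }
  data.frame(query = query_name, set = set_name, k = k, n = n, K = K, N = N,
             pvalue = pvalue, direction = direction, stringsAsFactors = FALSE)
}

#' Enrichment of several queries against a gene-set collection
#'
#' One hypergeometric test per (query, set) pair in a shared universe, with
#' optional BH adjustment across the whole matrix of tests.
#'
#' @param queries Named list of gene sets (e.g. [cluster_sets()] output) or a
#'   `cluster_assignment`.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector; typically all genes tested for
#'   differential expression.
#' @param adjust Apply BH across all tests.
#' @param direction `"over"` or `"under"`.
#' @return Long data.frame of [hypergeom_overlap()] rows (plus `fdr` when
#'   `adjust = TRUE`).
#' @export
enrich_matrix <- function(queries, collection, universe, adjust = FALSE,
                          direction = "over") {
  if (inherits(queries, "cluster_assignment")) queries <- cluster_sets(queries)
  stopifnot(is.list(queries), is.list(collection))
  rows <- list()
  for (qn in names(queries)) {
    q <- intersect(queries[[qn]], universe)
    if (length(q) == 0) {
      warning("query '", qn, "' absent from universe; skipped")
      next
    }
    for (sn in names(collection)) {
      rows[[length(rows) + 1]] <- suppressMessages(
        hypergeom_overlap(q, collection[[sn]], universe, direction,
                          query_name = qn, set_name = sn))
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$fdr <- bh_adjust(out$pvalue)
  out
}

# unweighted KS enrichment score from sorted hit positions
.gsea_es <- function(pos, N) {
  S <- length(pos)
  pos <- sort(pos)
  i <- seq_len(S)
  after <- i / S - (pos - i) / (N - S)   # running sum just after each hit
  before <- after - 1 / S                # just before each hit
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Unweighted KS gene-set enrichment on a ranked list
#'
#' Classic (unweighted) GSEA: walking down the ranking, the running sum gains
#' `1/|S|` at set members and loses `1/(N-|S|)` elsewhere; the enrichment
#' score is the extremum by absolute value. Significance by random set
#' permutations with the plus-one estimator
#' `p = (1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)`.
#'
#' @param ranked Items in descending score order (character vector), or a
#'   named numeric score vector which is sorted decreasingly first.
#' @param set Item set (non-empty proper subset of the ranked items).
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed.
#' @return List of class `gsea_result`: es, pvalue, n_perm, seed, set_size, n.
#' @export
gsea <- function(ranked, set, n_perm = 999, seed = 1) {
  if (is.numeric(ranked)) {
    stopifnot(!is.null(names(ranked)))
    ranked <- names(sort(ranked, decreasing = TRUE))
  }
  N <- length(ranked)
  set <- unique(set)
  if (!all(set %in% ranked)) stop("set must be a subset of the ranked items")
  S <- length(set)
  if (S == 0) stop("set is empty")
  if (S == N) stop("set equal to all ranked items; enrichment is undefined")
  es <- .gsea_es(match(set, ranked), N)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    .gsea_es(sample.int(N, S), N)
  }, numeric(1))
  pvalue <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
  structure(list(es = es, pvalue = pvalue, n_perm = n_perm, seed = seed,
                 set_size = S, n = N), class = "gsea_result")
}

#' Read a gene-set collection in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
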