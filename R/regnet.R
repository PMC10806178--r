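#' Assemble a directed regulatory network from scored TF-target pairs
#'
#' Keeps pairs with `score > threshold` (strict; default 2), deduplicates
#' edges, and records out- and in-degrees. The total edge count `W` equals
#' both degree sums.
#'
#' @param edges Data.frame with tf, target, score.
#' @param threshold Score threshold (strict >).
#' @return Object of class `regulatory_network`: edges, W, out_degree,
#'   in_degree.
#' @export
build_network <- function(edges, threshold = 2) {
  stopifnot(all(c("tf", "target", "score") %in% names(edges)))
  if (any(edges$score < 0)) stop("scores must be non-negative")
  keep <- edges[edges$score > threshold, , drop = FALSE]
  keep <- keep[!duplicated(keep[c("tf", "target")]), , drop = FALSE]
  if (nrow(keep) == 0)
    warning("network is empty after thresholding; downstream tests will refuse it")
  out_degree <- table(factor(keep$tf))
  in_degree <- table(factor(keep$target))
  structure(list(edges = keep, W = nrow(keep),
                 out_degree = c(out_degree), in_degree = c(in_degree)),
            class = "regulatory_network")
}

#' Targets of one TF in a network
#' @param net A `regulatory_network`.
#' @param tf TF identifier.
#' @return Character vector of target genes.
#' @export
network_targets <- function(net, tf) {
  net$edges$target[net$edges$tf == tf]
}

#' NEAT-type directed network enrichment between two gene sets
#'
#' Tests whether the number of edges from source set A to target set B
#' exceeds the degree-conditioned expectation: under the null the observed
#' count follows `Hypergeometric(W, i_B, o_A)` where `o_A` is the total
#' out-degree of A, `i_B` the total in-degree of B and `W` the network's
#' edge count; the p-value is the exact upper tail `P(X >= n_AB)` and the
#' expectation `o_A * i_B / W`.
#'
#' @param net A `regulatory_network`.
#' @param A Source gene set (must have out-degree > 0).
#' @param B Target gene set (must have in-degree > 0).
#' @param name_a,name_b Labels carried into the result.
#' @return One-row data.frame: source, target_set, o_A, i_B, n_AB, W,
#'   expected, pvalue.
#' @export
neat_test <- function(net, A, B, name_a = "A", name_b = "B") {
  stopifnot(inherits(net, "regulatory_network"))
  if (net$W == 0) stop("network has no edges")
  e <- net$edges
  o_A <- sum(e$tf %in% A)
  i_B <- sum(e$target %in% B)
  if (o_A == 0) stop("source set has zero out-degree; NEAT test is undefined")
  if (i_B == 0) stop("target set has zero in-degree; NEAT test is undefined")
  n_AB <- sum(e$tf %in% A & e$target %in% B)
  data.frame(source = name_a, target_set = name_b, o_A = o_A, i_B = i_B,
             n_AB = n_AB, W = net$W, expected = o_A * i_B / net$W,
             pvalue = stats::phyper(n_AB - 1, i_B, net$W - i_B, o_A,
                                    lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Per-TF regulator enrichment for a gene group
#'
#' For every TF with at least one target, a hypergeometric test of the
#' overlap between its target set and the group of interest inside the given
#' universe, followed by BH adjustment across TFs.
#'
#' @param net A `regulatory_network`.
#' @param group Gene set of interest.
#' @param universe Universe gene set.
#' @return Data.frame of per-TF [hypergeom_overlap()] rows with an `fdr`
#'   column.
#' @export
regulator_enrichment <- function(net, group, universe) {
  stopifnot(inherits(net, "regulatory_network"))
  tfs <- unique(net$edges$tf)
  rows <- lapply(tfs, function(tf) {
    tg <- network_targets(net, tf)
    if (length(tg) == 0) return(NULL)
    suppressMessages(hypergeom_overlap(tg, group, universe,
                                       query_name = tf, set_name = "group"))
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out
}

#' Summed expression of a gene set per cluster or cell
#'
#' Adds the expression values of the genes of interest within each column
#' (pseudo-bulk cluster or cell) of an expression matrix. Set members absent
#' from the matrix are reported via message.
#'
#' @param expr Expression matrix, genes x clusters/cells.
#' @param set Gene set with non-empty intersection with `rownames(expr)`.
#' @return Named numeric vector of per-column sums.
#' @export
signature_sum <- function(expr, set) {
  found <- intersect(unique(set), rownames(expr))
  if (length(found) == 0) stop("no signature gene measured in the expression matrix")
  missing <- length(unique(set)) - length(found)
  if (missing > 0) message(missing, " signature gene(s) not measured; ignored")
  colSums(expr[found, , drop = FALSE])
}

#' Rank TFs by coexpression with their predicted targets
#'
#' For each TF measured in the expression matrix, the Spearman correlation
#' (average ranks on ties) across clusters between the TF's own expression
#' and the summed expression of its predicted targets. TFs with constant
#' expression get `rho = NA` and are placed last in the descending ranking.
#'
#' @param expr Cluster-level expression matrix, genes x clusters (>= 3
#'   clusters).
#' @param net A `regulatory_network`.
#' @return Data.frame sorted by decreasing rho: tf, n_targets, rho.
#' @export
tf_target_coexpression <- function(expr, net) {
  stopifnot(inherits(net, "regulatory_network"))
  if (ncol(expr) < 3) stop("need >= 3 clusters for a rank correlation")
  tfs <- intersect(unique(net$edges$tf), rownames(expr))
  if (length(tfs) == 0) stop("no network TF measured in the expression matrix")
  rows <- lapply(tfs, function(tf) {
    tg <- network_targets(net, tf)
    s <- tryCatch(suppressMessages(signature_sum(expr, tg)),
                  error = function(e) NULL)
    rho <- if (is.null(s) || stats::sd(expr[tf, ]) == 0 || stats::sd(s) == 0) {
      NA_real_
    } else {
      stats::cor(expr[tf, ], s, method = "spearman")
    }
    data.frame(tf = tf, n_targets = length(tg), rho = rho,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$rho, na.last = TRUE), , drop = FALSE]
}
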