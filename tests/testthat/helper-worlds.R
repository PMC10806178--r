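# shared synthetic worlds, built once per test run

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 400, n_donors = 8, effect_log2fc = 2,
                        nb_dispersion = 0.05, frac_null = 0.5,
                        frac_discordant = 0.15, seed = 101)
      w <- generate_timecourse(cfg)
      w$sf <- size_factors(w$counts)
      cache <<- w
    }
    cache
  }
})

# tiny deterministic count matrix: 2 donors x 3 days, 5 genes
toy_counts <- function() {
  counts <- matrix(c(
    10, 12, 30, 11, 13, 29,
    100, 95, 102, 99, 101, 98,
    5, 50, 5, 6, 48, 6,
    0, 0, 0, 0, 0, 0,
    40, 41, 39, 80, 82, 78
  ), nrow = 5, byrow = TRUE)
  design <- data.frame(
    sample = c("D1_d0", "D1_d2", "D1_d5", "D2_d0", "D2_d2", "D2_d5"),
    donor = rep(c("D1", "D2"), each = 3),
    day = rep(c(0, 2, 5), 2))
  rownames(counts) <- paste0("g", 1:5)
  colnames(counts) <- design$sample
  list(counts = counts, design = design)
}

# brute-force hypergeometric over-enrichment tail by enumerating all draws
brute_hyper_over <- function(N, K, n, k) {
  if (n > N) stop("n > N")
  universe <- seq_len(N)
  target <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# brute-force NEAT upper tail: enumerate which o_A of the W edge slots are
# A-sourced; i_B slots are marked as landing in B
brute_neat_over <- function(W, i_B, o_A, n_AB) {
  draws <- utils::combn(W, o_A)
  mean(colSums(draws <= i_B) >= n_AB)
}

# brute-force unweighted KS enrichment score via the explicit running sum
brute_es <- function(positions, N) {
  S <- length(positions)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (i %in% positions) 1 / S else -1 / (N - S)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
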