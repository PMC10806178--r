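test_that("size factors follow the median-of-ratios closed form", {
  # doubled sample: ratios are 1/sqrt(2) and sqrt(2)
  k <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  expect_equal(unname(size_factors(k)), c(sqrt(0.5), sqrt(2)), tolerance = 1e-10)
  # identical samples
  k2 <- cbind(a = c(5, 9), b = c(5, 9), c = c(5, 9))
  expect_equal(unname(size_factors(k2)), c(1, 1, 1))
  # single sample is its own reference
  expect_equal(unname(size_factors(matrix(c(3, 8, 1), ncol = 1))), 1)
  # gene permutation invariance
  w <- small_world()
  perm <- sample(nrow(w$counts))
  expect_equal(size_factors(w$counts), size_factors(w$counts[perm, ]))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("scaling a sample rescales its size factor and leaves tests invariant", {
  w <- small_world()
  counts2 <- w$counts
  counts2[, 3] <- counts2[, 3] * 2L
  sf1 <- size_factors(w$counts)
  sf2 <- size_factors(counts2)
  # relative factor of the scaled sample doubles
  expect_equal((sf2[3] / sf2[1]) / (sf1[3] / sf1[1]), 2, tolerance = 1e-10,
               ignore_attr = TRUE)
  # normalized-mean quantities are invariant up to the pseudocount
  d2 <- sort(unique(w$design$day))[2]
  d9 <- max(w$design$day)
  expect_equal(log2fc(w$counts, sf1 / exp(mean(log(sf1))), w$design, d2, d9),
               log2fc(counts2, sf2 / exp(mean(log(sf2))), w$design, d2, d9),
               tolerance = 1e-3)
  # count-level GLM statistics change only marginally (the raw counts differ)
  idx <- 1:40
  disp <- estimate_dispersion(w$counts[idx, ], sf1, factor(w$design$day))
  de1 <- lrt_timepoint(w$counts[idx, ], sf1, w$design, dispersion = disp)
  de2 <- lrt_timepoint(counts2[idx, ], sf2, w$design, dispersion = disp)
  ok <- de1$status == "tested" & de2$status == "tested"
  expect_gt(sum(ok), 30)
  expect_equal(de1$stat[ok], de2$stat[ok], tolerance = 0.1)
  expect_gt(cor(de1$stat[ok], de2$stat[ok]), 0.999)
})

test_that("dispersion estimation recovers the Poisson and NB regimes", {
  # Poisson world: median estimate near zero
  cfgP <- sim_config(n_genes = 1000, n_donors = 8, effect_log2fc = 0,
                     frac_null = 1, frac_discordant = 0, nb_dispersion = 0,
                     seed = 21)
  wP <- generate_timecourse(cfgP)
  dP <- estimate_dispersion(wP$counts, size_factors(wP$counts),
                            factor(wP$design$day))
  expect_lt(median(dP$alpha[dP$status == "tested"]), 0.02)

  # NB world at alpha = 0.1, 8 replicates per group
  cfgN <- sim_config(n_genes = 2000, n_donors = 8, effect_log2fc = 0,
                     frac_null = 1, frac_discordant = 0, nb_dispersion = 0.1,
                     seed = 22)
  wN <- generate_timecourse(cfgN)
  dN <- estimate_dispersion(wN$counts, size_factors(wN$counts),
                            factor(wN$design$day))
  med <- median(dN$alpha[dN$status == "tested"])
  expect_gt(med, 0.05)
  expect_lt(med, 0.2)
})

test_that("degenerate dispersion inputs hit the floor / low_count paths", {
  counts <- rbind(g1 = rep(20L, 8), g2 = rep(0L, 8), g3 = rep(c(1L, 0L), 4))
  colnames(counts) <- paste0("s", 1:8)
  d <- estimate_dispersion(counts, rep(1, 8), factor(rep(1:2, each = 4)))
  expect_equal(d$alpha[1], 1e-8)           # constant counts -> floor
  expect_equal(d$status[2], "low_count")   # all-zero gene
  expect_equal(d$status[3], "low_count")   # total count below threshold
})

test_that("timepoint LRT recovers planted signal and ignores donor-only structure", {
  w <- small_world()
  de <- lrt_timepoint(w$counts, w$sf, w$design)
  truth <- w$truth
  early <- truth$archetype == "early_up" & truth$donor_consistent
  expect_gte(mean(de$de[early]), 0.95)
  expect_equal(sum(de$de[truth$archetype == "null"]), 0)
  expect_true(all(de$fdr >= de$pvalue, na.rm = TRUE))

  # donor-only signal: donor effects are absorbed, LRT ~ 0
  set.seed(31)
  donor_mu <- rep(c(50, 400), length.out = 8)
  counts1 <- matrix(rpois(32, rep(donor_mu, each = 4)), nrow = 1,
                    dimnames = list("g1", w$design$sample))
  counts <- rbind(counts1, w$counts[1:30, ])  # companions for the trend fit
  de1 <- lrt_timepoint(counts, w$sf, w$design)
  expect_lt(de1$stat[1], 3)
  expect_gt(de1$pvalue[1], 0.3)
})

test_that("Poisson LRT matches a brute-force maximized likelihood ratio", {
  # tiny toy: 2 donors x 3 timepoints, alpha forced to 0
  toy <- toy_counts()
  sf <- rep(1, 6)
  day <- factor(toy$design$day)
  donor <- factor(toy$design$donor)
  X_full <- model.matrix(~ donor + day)
  X_red <- model.matrix(~ donor)
  for (g in c(1, 3, 5)) {
    y <- toy$counts[g, ]
    fit <- osteotempo:::.fit_nb_glm(y, X_full, log(sf), 0)
    fit_r <- osteotempo:::.fit_nb_glm(y, X_red, log(sf), 0)
    lrt <- 2 * (fit$loglik - fit_r$loglik)
    nll <- function(beta, X) -sum(dpois(y, exp(pmin(drop(X %*% beta), 30)), log = TRUE))
    brute <- function(X) {
      best <- Inf
      for (rep in 1:20) {
        o <- optim(rnorm(ncol(X), 0, 2), nll, X = X, method = "BFGS",
                   control = list(maxit = 500))
        best <- min(best, o$value)
      }
      -best
    }
    set.seed(g)
    lrt_brute <- 2 * (brute(X_full) - brute(X_red))
    expect_equal(lrt, lrt_brute, tolerance = 1e-4)
  }
})

test_that("null LRT p-values are close to uniform", {
  cfg <- sim_config(n_genes = 1500, n_donors = 8, effect_log2fc = 0,
                    frac_null = 1, frac_discordant = 0, nb_dispersion = 0.05,
                    seed = 33)
  w <- generate_timecourse(cfg)
  de <- lrt_timepoint(w$counts, size_factors(w$counts), w$design)
  p <- de$pvalue[de$status == "tested"]
  ks <- suppressWarnings(ks.test(p, "punif"))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("phenotype association recovers a planted resorption signature", {
  w <- small_world()
  sig <- w$truth$gene_id[w$truth$archetype == "null"][1:50]
  ph <- generate_phenotype(w$counts, w$design, sig, slope_log2_per_unit = 3,
                           seed = 41)
  d0 <- w$design$day == 0
  res <- phenotype_association(ph$counts[, d0], size_factors(ph$counts[, d0]),
                               w$design[d0, ], ph$phenotype)
  expect_gte(mean(res$associated[res$gene %in% sig]), 0.8)
  expect_lt(mean(res$associated[!res$gene %in% sig]), 0.05)
})

test_that("phenotype association refuses degenerate phenotypes", {
  w <- small_world()
  d0 <- w$design$day == 0
  counts0 <- w$counts[, d0]
  sf0 <- size_factors(counts0)
  const <- setNames(rep(0.5, 8), unique(w$design$donor))
  expect_error(phenotype_association(counts0, sf0, w$design[d0, ], const),
               "constant")
  short <- setNames(runif(7), unique(w$design$donor)[1:7])
  expect_error(phenotype_association(counts0, sf0, w$design[d0, ], short),
               "missing donors")
  expect_error(phenotype_association(w$counts, w$sf, w$design,
                                     setNames(runif(8), unique(w$design$donor))),
               "one sample per donor")
})

test_that("null phenotype worlds keep raw p calibrated and BH quiet", {
  counts_fp <- 0
  bh_calls <- 0
  m_tot <- 0
  donors <- paste0("D", 1:8)
  design <- data.frame(sample = donors, donor = donors, day = 0)
  for (s in 1:10) {
    set.seed(500 + s)
    counts <- matrix(rnbinom(200 * 8, mu = 100, size = 1 / 0.05), 200,
                     dimnames = list(sprintf("g%03d", 1:200), donors))
    ph <- setNames(runif(8), donors)
    res <- phenotype_association(counts, size_factors(counts), design, ph)
    counts_fp <- counts_fp + sum(res$pvalue < 0.01, na.rm = TRUE)
    bh_calls <- bh_calls + sum(res$associated)
    m_tot <- m_tot + sum(res$status == "tested")
  }
  # raw p-values roughly calibrated at the 1% level; Wald on n=8 is
  # permissive, so allow a generous band
  expect_lt(counts_fp / m_tot, 0.05)
  # BH at 1% under the global null yields (almost) no calls
  expect_lt(bh_calls, 3)
})

test_that("log2 fold changes use normalized means with a pseudocount", {
  toy <- toy_counts()
  sf <- rep(1, 6)
  flat <- matrix(rep(c(10, 10, 10), 4)[1:6], nrow = 1,
                 dimnames = list("g", toy$design$sample))
  expect_equal(unname(log2fc(flat, sf, toy$design, 0, 5)), 0)
  # mean 10 -> 40 with pseudocount 1
  ramp <- matrix(c(10, 0, 40, 10, 0, 40), nrow = 1,
                 dimnames = list("g", toy$design$sample))
  expect_equal(unname(log2fc(ramp, sf, toy$design, 0, 5)), log2(41 / 11),
               tolerance = 1e-12)
  zero <- matrix(0L, 1, 6, dimnames = list("g", toy$design$sample))
  expect_equal(unname(log2fc(zero, sf, toy$design, 0, 5)), 0)
  expect_error(log2fc(flat, sf, toy$design, 0, 99), "not present")
})

test_that("BH adjustment is step-up, order preserving and NA aware", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(NA, 0.05)), c(NA, 0.05))
  p <- c(0.002, 0.8, 0.04, NA, 0.0001)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p, na.rm = TRUE))
  expect_true(all(adj <= 1, na.rm = TRUE))
  ord <- order(p[!is.na(p)])
  expect_true(!is.unsorted(adj[!is.na(p)][ord]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
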