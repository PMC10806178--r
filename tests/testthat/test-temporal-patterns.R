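test_that("donor profiles normalize counts and collapse to the mean correctly", {
  toy <- toy_counts()
  sf <- setNames(rep(1, 6), toy$design$sample)
  prof <- donor_profiles(toy$counts, sf, toy$design)
  expect_equal(dim(prof$profiles), c(5, 2, 3))
  # zero counts -> flat zero profile
  expect_equal(unname(prof$profiles[4, , ]), matrix(0, 2, 3))
  # identical donors -> each donor profile equals the mean profile
  expect_equal(unname(prof$profiles[2, 1, ]), unname(prof$mean_profile[2, ]),
               tolerance = 0.1)
  # missing cell rejected
  expect_error(donor_profiles(toy$counts[, -1], sf[-1], toy$design[-1, ]),
               "exactly one sample")
})

test_that("doubling a sample's raw counts leaves its profile unchanged", {
  w <- small_world()
  counts2 <- w$counts
  counts2[, 5] <- counts2[, 5] * 2L
  p1 <- donor_profiles(w$counts, size_factors(w$counts), w$design)
  p2 <- donor_profiles(counts2, size_factors(counts2), w$design)
  # size factors cancel the scaling up to the common renormalization of all
  # samples; profiles agree after removing that shared shift
  d1 <- p1$profiles[, 2, ] - p1$profiles[, 1, ]
  d2 <- p2$profiles[, 2, ] - p2$profiles[, 1, ]
  expect_equal(d1[rowSums(w$counts) > 200, ], d2[rowSums(w$counts) > 200, ],
               tolerance = 0.02)
})

test_that("reproducibility filter keeps concordant and drops flat/discordant genes", {
  tp <- c(0, 2, 5, 9)
  donors <- paste0("D", 1:8)
  ramp <- matrix(rep(c(1, 2, 3, 4), 8), nrow = 1)
  arr <- array(NA_real_, c(3, 8, 4), dimnames = list(paste0("g", 1:3), donors, paste0("d", tp)))
  for (d in 1:8) arr[1, d, ] <- c(1, 2, 3, 4)          # perfect ramp everywhere
  for (d in 1:8) arr[2, d, ] <- if (d <= 5) c(1, 2, 3, 4) else c(4, 1, 4, 1)  # 5 of 8
  arr[3, , ] <- 2                                       # flat
  prof <- list(profiles = arr,
               mean_profile = apply(arr, c(1, 3), mean),
               donors = donors, timepoints = tp)
  filt <- reproducibility_filter(prof, 0.8, 6)
  expect_true("g1" %in% filt$kept)
  expect_false("g2" %in% filt$kept)   # 5 < 6 passing donors
  expect_false("g3" %in% filt$kept)   # all r NA
  expect_equal(filt$records$n_pass[1], 8)
  expect_true(all(is.na(filt$records[3, paste0("r_", donors)])))
})

test_that("filter is donor-permutation invariant and monotone in its thresholds", {
  w <- small_world()
  prof <- donor_profiles(w$counts, w$sf, w$design)
  base <- reproducibility_filter(prof, 0.8, 6)

  # permute donors
  perm <- sample(length(prof$donors))
  prof_p <- prof
  prof_p$profiles <- prof$profiles[, perm, , drop = FALSE]
  prof_p$donors <- prof$donors[perm]
  expect_setequal(reproducibility_filter(prof_p, 0.8, 6)$kept, base$kept)

  # tightening either threshold never enlarges the kept set
  for (thr in c(0.9, 0.95)) {
    expect_true(all(reproducibility_filter(prof, thr, 6)$kept %in% base$kept))
  }
  for (md in c(7, 8)) {
    expect_true(all(reproducibility_filter(prof, 0.8, md)$kept %in% base$kept))
  }
})

test_that("filter separates donor-consistent from donor-discordant planted genes", {
  w <- small_world()
  prof <- donor_profiles(w$counts, w$sf, w$design)
  filt <- reproducibility_filter(prof, 0.8, 6)
  cons <- w$truth$gene_id[w$truth$donor_consistent & w$truth$archetype != "null"]
  disc <- w$truth$gene_id[!w$truth$donor_consistent]
  expect_gte(mean(cons %in% filt$kept), 0.97)
  expect_lte(mean(disc %in% filt$kept), 0.05)
})

test_that("k-means separates noiseless archetypes perfectly", {
  tp <- c(0, 2, 5, 9)
  profs <- t(vapply(ARCHETYPES, archetype_profile, numeric(4),
                    timepoints = tp, amplitude = 2))
  mp <- profs[rep(1:8, each = 10), ] + 5
  rownames(mp) <- sprintf("g%03d", 1:80)
  truth <- rep(ARCHETYPES, each = 10)
  ca <- kmeans_cluster(mp, k = 8, seed = 1, timepoints = tp)
  # one-to-one mapping between clusters and archetypes
  expect_equal(length(unique(paste(ca$assignment$cluster, truth))), 8)
  # duplicate profiles share a cluster id
  expect_equal(ca$assignment$cluster[1], ca$assignment$cluster[2])
  # centroids are z-scored
  expect_equal(unname(rowMeans(ca$centroids)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(ca$centroids, 1, sd)), rep(1, 8), tolerance = 1e-12)
  # archetype labels match the planted shapes exactly
  ca <- label_archetypes(ca)
  lab_by_truth <- tapply(ca$assignment$archetype, truth, unique)
  expect_equal(as.vector(lab_by_truth[ARCHETYPES]), ARCHETYPES)
})

test_that("k-means is reproducible given a seed and refuses degenerate input", {
  w <- small_world()
  prof <- donor_profiles(w$counts, w$sf, w$design)
  kept <- reproducibility_filter(prof)$kept
  mp <- prof$mean_profile[kept, , drop = FALSE]
  ca1 <- kmeans_cluster(mp, k = 8, seed = 5, timepoints = prof$timepoints)
  ca2 <- kmeans_cluster(mp, k = 8, seed = 5, timepoints = prof$timepoints)
  expect_identical(ca1$assignment, ca2$assignment)
  expect_error(kmeans_cluster(mp[1:4, ], k = 8), "at least k genes")
  flatrow <- rbind(mp, flat = rep(3, ncol(mp)))
  expect_warning(kmeans_cluster(flatrow, k = 8, seed = 5), "zero profile variance")
})

test_that("archetype labelling follows the extremum/endpoint rule table", {
  tp <- c(0, 2, 5, 9)
  # interior peak returning below the half-way point -> transient
  expect_equal(osteotempo:::.label_profile(c(-1.2, 1.3, 0.2, -0.3), tp),
               "transient_up")
  # monotone ramps
  expect_equal(osteotempo:::.label_profile(c(-1.3, -0.4, 0.5, 1.2), tp), "late_up")
  expect_equal(osteotempo:::.label_profile(c(1.3, 0.4, -0.5, -1.2), tp), "late_down")
  # labelling is mirror symmetric over all orderings of four distinct values
  perms <- rbind(
    c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4), c(1, 3, 4, 2), c(1, 4, 2, 3),
    c(1, 4, 3, 2), c(2, 1, 3, 4), c(2, 1, 4, 3), c(2, 3, 1, 4), c(2, 3, 4, 1),
    c(2, 4, 1, 3), c(2, 4, 3, 1), c(3, 1, 2, 4), c(3, 1, 4, 2), c(3, 2, 1, 4),
    c(3, 2, 4, 1), c(3, 4, 1, 2), c(3, 4, 2, 1), c(4, 1, 2, 3), c(4, 1, 3, 2),
    c(4, 2, 1, 3), c(4, 2, 3, 1), c(4, 3, 1, 2), c(4, 3, 2, 1))
  mirror <- function(lab) chartr("ud", "du", lab)  # up <-> down
  swap <- c(early_up = "early_down", mid_up = "mid_down", late_up = "late_down",
            transient_up = "transient_down", early_down = "early_up",
            mid_down = "mid_up", late_down = "late_up",
            transient_down = "transient_up")
  for (i in seq_len(nrow(perms))) {
    z <- as.numeric(scale(perms[i, ]))
    lab <- osteotempo:::.label_profile(z, tp)
    expect_true(lab %in% ARCHETYPES)
    expect_equal(osteotempo:::.label_profile(-z, tp), unname(swap[lab]))
    # peak position consistency
    if (grepl("up$", lab)) {
      p <- which.max(z)
      if (lab == "late_up") expect_equal(p, 4) else expect_lt(p, 4)
    }
  }
})
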