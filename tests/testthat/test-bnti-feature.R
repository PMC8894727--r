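test_that("nearest-taxon distances honour presence and conspecific settings", {
  D <- cherry_dist()
  ct <- as_community_table(
    data.frame(sample = c("S1", "S2", "S3"),
               A = c(1, 0, 1), B = c(0, 0, 0), C = c(0, 1, 1), D = c(0, 1, 0)),
    mode = "counts"
  )
  # j = {C, D}: nearest of A is either cherry partner at distance 4
  expect_equal(nearest_taxon_distance("A", "S2", ct, D), 4)
  # j = {A, C}: conspecific distance is zero when allowed ...
  expect_equal(nearest_taxon_distance("A", "S3", ct, D, allow_conspecifics = TRUE), 0)
  # ... and the minimum over the remaining tips when excluded
  expect_equal(nearest_taxon_distance("A", "S3", ct, D, allow_conspecifics = FALSE), 4)
  # sample reduced to {A} alone under exclusion: undefined
  expect_true(is.na(nearest_taxon_distance("A", "S1", ct, D,
                                           allow_conspecifics = FALSE)))
})

test_that("feature-level beta-MNTD matches hand-evaluated values", {
  D <- cherry_dist()
  # pairwise: f_A = 0.5 in S1 = {A, B}, partner S2 = {C, D} -> 0.5 * 4
  expect_equal(feature_bmntd("A", cherry_block_table(), D,
                             focal = "S1", partner = "S2"), 2.0)
  # dataset scope over {S1, S2}, conspecifics allowed:
  # w = 0.5, ntd(A, S1) = 0, ntd(A, S2) = 4 -> 0.5 * 2 = 1
  expect_equal(feature_bmntd("A", cherry_block_table(), D), 1.0)
  # absent from every scope sample -> NA
  expect_true(is.na(feature_bmntd("C", cherry_pair_table(), D,
                                  samples = c("S1", "S2"))))
})

test_that("exhaustive null enumerates all tip permutations and matches the brute-force oracle", {
  D <- cherry_dist()
  ct <- cherry_pair_table()
  cfg <- bnti_config(exhaustive = TRUE)
  nulls <- null_distribution("A", ct, D, focal = "S1", partner = "S2", cfg = cfg)
  # 24 permutations; within-cherry pairs (distance 2) arise in 8 of them
  expect_length(nulls, 24)
  expect_equal(unname(table(nulls)), c(8L, 16L), ignore_attr = TRUE)
  expect_equal(sort(unique(nulls)), c(2, 4))

  oracle <- oracle_exhaustive_null(D, "A", partner_feats = "B", f_a = 1)
  expect_equal(sort(nulls), sort(oracle))

  # z-score under the sample-SD convention, against the oracle's moments
  obs <- feature_bmntd("A", ct, D, focal = "S1", partner = "S2")
  z_oracle <- (obs - mean(oracle)) / sd(oracle)
  fit <- bnti_feat(ct, D, mode = "pairwise", focal = "S1", cfg = cfg)
  rec <- dplyr::filter(tidy(fit), feature == "A")
  expect_equal(rec$bnti, z_oracle, tolerance = 1e-12)
  expect_equal(z_oracle, -4 / 3 / sqrt(8 / 9 * 24 / 23), tolerance = 1e-12)
  # the population-SD form of the same enumeration is -sqrt(2)
  n <- length(oracle)
  z_pop <- (obs - mean(oracle)) / (sd(oracle) * sqrt((n - 1) / n))
  expect_equal(z_pop, -sqrt(2), tolerance = 1e-12)

  # exhaustive enumeration refuses large trees
  big <- random_tree(12, seed = 1)
  ctb <- neutral_communities(big, 4, occupancy = 0.6, seed = 2)
  expect_error(
    bnti_feat(ctb, cophenetic_matrix(big), cfg = cfg),
    "exceeds the cap"
  )
})

test_that("sampled nulls converge to the exhaustive enumeration", {
  D <- cherry_dist()
  ct <- cherry_pair_table()
  oracle <- oracle_exhaustive_null(D, "A", partner_feats = "B", f_a = 1)
  cfg <- bnti_config(n_null = 999, seed = 42)
  nulls <- null_distribution("A", ct, D, focal = "S1", partner = "S2", cfg = cfg)
  expect_length(nulls, 999)
  # sampled mean within 3 standard errors of the enumerated mean
  se <- sd(oracle) / sqrt(999)
  expect_lt(abs(mean(nulls) - mean(oracle)), 3 * se)
  # determinism: identical list for an identical seed
  expect_identical(nulls,
                   null_distribution("A", ct, D, focal = "S1", partner = "S2",
                                     cfg = cfg))
  # zero-noise limit: values are pure shuffled beta-MNTD_feat
  cfg0 <- bnti_config(n_null = 99, seed = 5, noise_low = 0, noise_high = 0)
  n0 <- null_distribution("A", ct, D, focal = "S1", partner = "S2", cfg = cfg0)
  expect_true(all(n0 %in% c(0, 2, 4)))
})

test_that("contribution classification applies the documented thresholds", {
  expect_equal(classify_contribution(2.5), "SigDivergence")
  expect_equal(classify_contribution(-1.5), "Convergence")
  expect_equal(classify_contribution(0.99), "Insignificant")
  expect_equal(classify_contribution(-0.99), "Insignificant")
  expect_equal(classify_contribution(NA_real_), "Undefined")
  # boundaries go to the higher-magnitude category
  expect_equal(classify_contribution(c(1, -1, 2, -2)),
               c("Divergence", "Convergence", "SigDivergence", "SigConvergence"))
})

test_that("run cardinalities follow the scope contracts", {
  tr <- random_tree(12, seed = 9)
  D <- cophenetic_matrix(tr)
  ct <- neutral_communities(tr, 6, occupancy = 0.6, seed = 10)
  cfg <- bnti_config(n_null = 49, seed = 1)

  fit_d <- suppressWarnings(bnti_feat(ct, D, mode = "dataset", cfg = cfg))
  expect_equal(nrow(tidy(fit_d)), 12)

  groups <- data.frame(sample = ct_samples(ct),
                       group = rep(c("g1", "g2"), each = 3))
  fit_g <- suppressWarnings(bnti_feat(ct, D, mode = "group", groups = groups,
                                      cfg = cfg))
  expect_equal(nrow(tidy(fit_g)), 24)
  expect_setequal(unique(tidy(fit_g)$scope_label), c("g1", "g2"))

  fit_p <- suppressWarnings(bnti_feat(ct, D, mode = "pairwise",
                                      focal = "S1", cfg = cfg))
  expect_equal(nrow(tidy(fit_p)), 12 * 5)
  expect_false("S1" %in% tidy(fit_p)$partner)

  expect_error(bnti_feat(ct, D, mode = "pairwise", focal = "nope", cfg = cfg),
               "focal sample not found")
  expect_error(bnti_feat(ct, D, mode = "group",
                         groups = groups[-1, ], cfg = cfg),
               "without a group")
})

test_that("z-scores are invariant to the abundance mode of the input table", {
  tr <- random_tree(25, seed = 21)
  D <- cophenetic_matrix(tr)
  counts <- neutral_communities(tr, 8, occupancy = 0.45, seed = 22)
  relab <- to_relative(counts)
  pres <- as_community_table(t((ct_matrix(counts) > 0) * 1), mode = "presence")
  cfg <- bnti_config(n_null = 199, seed = 23)

  for (mode in c("dataset", "pairwise")) {
    focal <- if (mode == "pairwise") "S1" else NULL
    z <- lapply(list(counts, relab, pres), function(tab) {
      suppressWarnings(tidy(bnti_feat(tab, D, mode = mode, focal = focal,
                                      cfg = cfg)))$bnti
    })
    expect_equal(z[[1]], z[[2]], tolerance = 1e-9)
    expect_equal(z[[1]], z[[3]], tolerance = 1e-9)
  }
})

test_that("directed pairwise feature values aggregate to the community metric", {
  for (seed in 1:5) {
    tr <- random_tree(30, seed = seed)
    D <- cophenetic_matrix(tr)
    ct <- neutral_communities(tr, 10, occupancy = 0.4, seed = seed + 50)
    bm <- community_bmntd(ct, D)
    samples <- ct_samples(ct)
    for (pair in list(c(1, 2), c(3, 7))) {
      i <- samples[pair[1]]; j <- samples[pair[2]]
      directed <- function(from, to) {
        sum(vapply(ct_features(ct), function(a) {
          v <- feature_bmntd(a, ct, D, focal = from, partner = to)
          if (is.na(v)) 0 else v
        }, numeric(1)))
      }
      expect_equal(directed(i, j) + directed(j, i), 2 * bm[i, j],
                   tolerance = 1e-10)
    }
  }
})

test_that("conspecific-everywhere features get the noise-driven z with a warning", {
  D <- cherry_dist()
  ct <- as_community_table(
    data.frame(sample = c("S1", "S2", "S3"),
               A = c(1, 1, 1), B = c(1, 0, 0), C = c(0, 1, 0), D = c(0, 0, 1)),
    mode = "counts"
  )
  expect_warning(
    fit <- bnti_feat(ct, D, cfg = bnti_config(n_null = 999, seed = 3)),
    "conspecific in every scope sample"
  )
  recA <- dplyr::filter(tidy(fit), feature == "A")
  # uniform(1e-20, 5e-20) noise: mean 3e-20, sd 4e-20/sqrt(12) -> z ~ -2.6
  expect_equal(recA$bmntd_obs, 0)
  expect_gt(recA$bnti, -2.8)
  expect_lt(recA$bnti, -2.4)
  expect_equal(recA$category, "SigConvergence")

  # with noise disabled the same feature is Undefined, never dropped
  fit0 <- bnti_feat(ct, D, cfg = bnti_config(n_null = 99, seed = 3,
                                             noise_low = 0, noise_high = 0))
  expect_equal(dplyr::filter(tidy(fit0), feature == "A")$category, "Undefined")
  expect_equal(nrow(tidy(fit0)), 4)
})

test_that("null calibration on neutral communities is well-behaved", {
  z_all <- unlist(lapply(1:2, function(seed) {
    tr <- random_tree(60, seed = seed)
    ct <- neutral_communities(tr, 12, occupancy = 0.5, seed = seed + 10)
    fit <- suppressWarnings(
      bnti_feat(ct, cophenetic_matrix(tr),
                cfg = bnti_config(n_null = 299, seed = seed + 20))
    )
    tidy(fit)$bnti
  }))
  expect_gt(mean(z_all, na.rm = TRUE), -0.3)
  expect_lt(mean(z_all, na.rm = TRUE), 0.3)
  expect_lte(mean(abs(z_all) > 2, na.rm = TRUE), 0.10)
})
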