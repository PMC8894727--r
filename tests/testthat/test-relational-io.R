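test_that("newick reading validates tips, labels and branch lengths", {
  p <- withr::local_tempfile(fileext = ".nwk")

  writeLines("((A:1,B:1):1,(C:1,D:1):1);", p)
  tree <- read_newick(p)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("A", "B", "C", "D"))
  expect_true(all(tree$edge.length[tree$edge[, 2] <= 4] == 1))

  writeLines("(A:1);", p)
  expect_error(read_newick(p), "at least 2 tips")

  writeLines("((A:1,A:2):1,B:1);", p)
  expect_error(read_newick(p), "duplicate tip label")

  writeLines("((A:1,B:-1):1,C:1);", p)
  expect_error(read_newick(p), "negative branch lengths")

  writeLines("((A:1,B:1:1,C);", p)
  expect_error(read_newick(p), "malformed|parse")
})

test_that("cophenetic distances are path-length sums", {
  D <- cherry_dist()
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["C", "D"], 2)
  expect_equal(unname(diag(D)), rep(0, 4))

  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  Ds <- cophenetic_matrix(star)
  expect_true(all(Ds[upper.tri(Ds)] == 2))
})

test_that("cophenetic matrices are symmetric with zero diagonal on random trees", {
  for (seed in 1:10) {
    tree <- random_tree(sample(5:40, 1), seed = seed)
    D <- cophenetic_matrix(tree)
    expect_identical(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
  }
})

test_that("label shuffling conserves the off-diagonal multiset and is seed-deterministic", {
  D <- cophenetic_matrix(random_tree(12, seed = 3))
  for (seed in 1:5) {
    Ds <- shuffle_labels(D, seed = seed)
    expect_identical(dimnames(Ds), dimnames(D))
    expect_equal(sort(Ds[upper.tri(Ds)]), sort(D[upper.tri(D)]))
    expect_true(all(diag(Ds) == 0))
    expect_identical(Ds, shuffle_labels(D, seed = seed))
  }
  # 2-label matrix: the single distance is invariant under either permutation
  D2 <- D[1:2, 1:2]
  expect_equal(shuffle_labels(D2, seed = 1)[1, 2], D2[1, 2])
})

test_that("community table mode is inferred and validated", {
  expect_message(
    ct <- as_community_table(data.frame(sample = c("S1", "S2"),
                                        A = c(5, 3), B = c(0, 7))),
    "counts"
  )
  expect_equal(ct_mode(ct), "counts")

  expect_message(
    ctr <- as_community_table(data.frame(sample = c("S1", "S2"),
                                         A = c(0.4, 1), B = c(0.6, 0))),
    "relative"
  )
  expect_equal(ct_mode(ctr), "relative")

  expect_message(
    ctp <- as_community_table(data.frame(sample = c("S1", "S2"),
                                         A = c(1, 0), B = c(0, 1))),
    "presence"
  )
  expect_equal(ct_mode(ctp), "presence")

  expect_error(
    as_community_table(data.frame(sample = "S1", A = -3), mode = "counts"),
    "negative abundance.*'S1'.*'A'"
  )
})

test_that("community tables round-trip through delimited text in both orientations", {
  ct <- cherry_block_table()
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(ct), p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_community_table(p, mode = "counts")
  expect_equal(ct_matrix(back), ct_matrix(ct))

  pt <- withr::local_tempfile(fileext = ".tsv")
  m <- t(as.matrix(as.data.frame(ct)[-1]))
  colnames(m) <- ct_samples(ct)
  write.table(data.frame(feature = rownames(m), m, check.names = FALSE),
              pt, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- read_community_table(pt, mode = "counts", samples_as = "cols")
  expect_equal(ct_matrix(back_t), ct_matrix(ct))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tA\tB", "S1\t1\toops"), bad)
  expect_error(read_community_table(bad), "non-numeric")
})

test_that("harmonize intersects feature sets, is idempotent, and rejects empty overlap", {
  D <- cherry_dist()
  ct <- as_community_table(
    data.frame(sample = c("S1", "S2"), A = c(1, 0), B = c(1, 1),
               C = c(0, 1), X = c(2, 0)),
    mode = "counts"
  )
  expect_error(harmonize(ct, D), "prune")
  expect_message(h <- harmonize(ct, D, prune = TRUE), "dropped 1 feature")
  expect_setequal(ct_features(h$table), c("A", "B", "C"))
  expect_setequal(rownames(h$dist), c("A", "B", "C"))

  h2 <- harmonize(h$table, h$dist, prune = TRUE)
  expect_equal(ct_matrix(h2$table), ct_matrix(h$table))
  expect_equal(h2$dist, h$dist)

  ct2 <- as_community_table(data.frame(sample = "S1", X = 1, Y = 2),
                            mode = "counts")
  expect_error(harmonize(ct2, D, prune = TRUE), "no features shared")

  # a sample holding only the dropped feature is removed with a warning
  ct3 <- as_community_table(
    data.frame(sample = c("S1", "S2"), A = c(1, 0), X = c(0, 5)),
    mode = "counts"
  )
  expect_warning(
    expect_message(h3 <- harmonize(ct3, D, prune = TRUE), "dropped"),
    "left empty"
  )
  expect_equal(ct_samples(h3$table), "S1")
})

test_that("to_relative normalises every mode and rejects empty samples", {
  ct <- as_community_table(data.frame(sample = "S1", A = 2, B = 2, C = 4),
                           mode = "counts")
  expect_equal(unname(ct_matrix(to_relative(ct))[, 1]), c(0.25, 0.25, 0.5))

  ctp <- as_community_table(data.frame(sample = "S1", A = 1, B = 0, C = 1),
                            mode = "presence")
  expect_equal(unname(ct_matrix(to_relative(ctp))[, 1]), c(0.5, 0, 0.5))

  ct0 <- as_community_table(
    data.frame(sample = c("S1", "S2"), A = c(1, 0), B = c(1, 0)),
    mode = "counts"
  )
  expect_error(to_relative(ct0), "all-zero sample.*S2")

  # property: rows sum to 1 for random tables
  for (seed in 1:5) {
    tr <- random_tree(15, seed = seed)
    ct <- neutral_communities(tr, 6, occupancy = 0.5, seed = seed)
    sums <- colSums(ct_matrix(to_relative(ct)))
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})
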