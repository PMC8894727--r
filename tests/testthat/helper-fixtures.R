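# shared fixtures: the 4-tip "two cherries" tree and small tables built in code

cherry_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

cherry_dist <- function() cophenetic_matrix(cherry_tree())

# S1 = {A}, S2 = {B}: the pairwise oracle configuration
cherry_pair_table <- function() {
  as_community_table(
    data.frame(sample = c("S1", "S2"),
               A = c(1, 0), B = c(0, 1), C = c(0, 0), D = c(0, 0)),
    mode = "counts"
  )
}

# S1 = {A, B} equal, S2 = {C, D} equal
cherry_block_table <- function() {
  as_community_table(
    data.frame(sample = c("S1", "S2"),
               A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1)),
    mode = "counts"
  )
}

# independent brute-force oracle: beta-MNTD_feat for feature `a` in focal
# sample against partner, recomputed from first principles on a plainly
# relabelled distance matrix (no package internals)
oracle_pair_bmntd <- function(D, relabel, a, partner_feats, f_a) {
  Dp <- D
  dimnames(Dp) <- list(relabel, relabel)
  Dp <- Dp[rownames(D), colnames(D)]
  f_a * min(Dp[a, partner_feats])
}

# enumerate the full exhaustive null with the oracle
oracle_exhaustive_null <- function(D, a, partner_feats, f_a) {
  perms <- e1071::permutations(nrow(D))
  apply(perms, 1, function(p) {
    oracle_pair_bmntd(D, rownames(D)[p], a, partner_feats, f_a)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
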