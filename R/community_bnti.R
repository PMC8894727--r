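#' Community-level beta mean nearest taxon distance
#'
#' The conventional between-sample betaMNTD: for samples i and j,
#' \deqn{\tfrac{1}{2}\big[\sum_{a \in i} f_{ai}\,\mathrm{ntd}(a, j) +
#'       \sum_{b \in j} f_{bj}\,\mathrm{ntd}(b, i)\big]}
#' with relative abundances. The feature-level metric aggregates back to it:
#' the sum of directed pairwise feature-level betaMNTD values over both
#' directions equals twice this quantity.
#'
#' @param table A `community_tbl`.
#' @param D Cophenetic distance matrix matching the table's features.
#' @param allow_conspecifics See [bnti_config()].
#' @return A symmetric sample-by-sample matrix of betaMNTD values.
#' @export
community_bmntd <- function(table, D, allow_conspecifics = TRUE) {
  rel <- to_relative(table)
  D <- align_dist(rel, D)
  X <- ct_matrix(rel)
  bmntd_from_matrix(X, D, allow_conspecifics)
}

bmntd_from_matrix <- function(X, D, allow_conspecifics, perm = NULL) {
  perm <- perm %||% seq_len(nrow(X))
  ntd <- ntd_matrix_cpp(D, X > 0, as.integer(perm), allow_conspecifics)
  S <- ncol(X)
  out <- matrix(0, S, S, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i < j) {
        directed_ij <- sum(X[, i] * ntd[, j])
        directed_ji <- sum(X[, j] * ntd[, i])
        out[i, j] <- out[j, i] <- (directed_ij + directed_ji) / 2
      }
    }
  }
  out
}

#' Community-level beta nearest taxon index
#'
#' z-score of the observed pairwise betaMNTD against the tip-shuffling null,
#' using one shared permutation per replicate across all sample pairs and no
#' noise injection. Pairs with zero null standard deviation come out `NA`.
#'
#' @inheritParams community_bmntd
#' @param cfg A [bnti_config()] (`noise_*` is ignored here).
#' @return A list with matrices `bnti` (z-scores), `bmntd_obs`, and the
#'   `null_mean` / `null_sd` matrices.
#' @export
community_bnti <- function(table, D, cfg = bnti_config()) {
  rel <- to_relative(table)
  D <- align_dist(rel, D)
  X <- ct_matrix(rel)
  obs <- bmntd_from_matrix(X, D, cfg$allow_conspecifics)
  draws <- null_draws(cfg, nrow(X))
  nulls <- array(NA_real_, c(nrow(draws$perms), ncol(X), ncol(X)))
  for (r in seq_len(nrow(draws$perms))) {
    nulls[r, , ] <- bmntd_from_matrix(X, D, cfg$allow_conspecifics,
                                      perm = draws$perms[r, ])
  }
  nm <- apply(nulls, c(2, 3), mean)
  ns <- apply(nulls, c(2, 3), sd)
  z <- ifelse(ns > 0, (obs - nm) / ns, NA_real_)
  diag(z) <- NA_real_
  dimnames(nm) <- dimnames(ns) <- dimnames(z) <- dimnames(obs)
  list(bnti = z, bmntd_obs = obs, null_mean = nm, null_sd = ns,
       n_null = nrow(draws$perms), seed = cfg$seed)
}

#' Taxonomic (non-relational) dissimilarity matrices
#'
#' Bray-Curtis on relative abundances or Jaccard on presence/absence, the
#' standard inputs to ordination. Computed with [vegan::vegdist()].
#'
#' @param table A `community_tbl`.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return A symmetric sample-by-sample dissimilarity matrix in `[0, 1]`.
#' @export
taxonomic_dissimilarity <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  X <- t(ct_matrix(to_relative(table)))  # samples x features, vegan layout
  if (any(rowSums(X) == 0)) abort("empty sample(s) in table")
  d <- if (metric == "bray_curtis") {
    vegan::vegdist(X, method = "bray")
  } else {
    vegan::vegdist(X > 0, method = "jaccard", binary = TRUE)
  }
  as.matrix(d)
}

#' Write a labelled square matrix as TSV
#'
#' Plain labelled-TSV output any ordination library consumes.
#' @param m A labelled square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
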