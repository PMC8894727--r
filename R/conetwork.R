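#' Correlate feature-level profiles across assemblages
#'
#' Pearson correlation between per-sample z-score profiles (rows of
#' [temporal_profile()] matrices) for every feature pair, within and across
#' feature types -- e.g. relating putatively active ASVs to molecular
#' formulas. Both profiles must cover the same partner samples in the same
#' order; features with any missing entry are excluded (imputation is
#' refused: a missing z-value is information, not noise), as are
#' zero-variance profiles.
#'
#' @param p1 A `bnti_profile` (or plain features x partners matrix).
#' @param p2 Optional second profile over the identical partner set; its
#'   features are labelled as a second type.
#' @param types Length-2 character giving the feature-type labels (default
#'   `c("taxon", "formula")`).
#' @return A list: `cor` (feature x feature Pearson matrix), `type` (named
#'   vector of feature types), `n_excluded`.
#' @export
correlate_profiles <- function(p1, p2 = NULL, types = c("taxon", "formula")) {
  m <- unclass(p1)
  type <- stats::setNames(rep(types[1], nrow(m)), rownames(m))
  if (!is.null(p2)) {
    m2 <- unclass(p2)
    if (!identical(colnames(m), colnames(m2))) {
      abort("profiles must share an identical, identically ordered partner set")
    }
    if (any(rownames(m2) %in% rownames(m))) {
      abort("feature identifiers collide across the two profiles")
    }
    type <- c(type, stats::setNames(rep(types[2], nrow(m2)), rownames(m2)))
    m <- rbind(m, m2)
  }
  if (ncol(m) < 3) abort("need at least 3 shared partner samples to correlate")
  complete <- !apply(m, 1, anyNA)
  novar <- complete & apply(m, 1, function(v) isTRUE(sd(v) == 0))
  if (any(novar)) {
    warn(sprintf("excluding %d zero-variance profile(s)", sum(novar)))
  }
  keep <- complete & !novar
  n_excl <- sum(!keep)
  if (sum(!complete)) {
    inform(sprintf("excluding %d profile(s) with missing entries", sum(!complete)))
  }
  if (sum(keep) < 2) abort("fewer than 2 usable profiles remain")
  C <- cor(t(m[keep, , drop = FALSE]))
  list(cor = C, type = type[rownames(C)], n_excluded = n_excl)
}

#' Detect co-contribution modules
#'
#' A deliberately simplified weighted-correlation module detection: the
#' signed soft adjacency \eqn{a_{ij} = ((1 + r_{ij})/2)^{\beta}} is turned
#' into the dissimilarity \eqn{1 - a_{ij}}, average-linkage hierarchical
#' clustering is cut at a fixed height, and modules smaller than `min_size`
#' are dissolved to unassigned -- which removes doublet modules (one feature
#' related to only one other feature). No topological-overlap transform or
#' dynamic tree cut is applied.
#'
#' @param C A feature x feature correlation matrix (or the list returned by
#'   [correlate_profiles()]).
#' @param power Soft-threshold exponent (default 6).
#' @param cut_height Cut height on the dissimilarity scale, in (0, 1)
#'   (default 0.25).
#' @param min_size Smallest module kept (default 3; doublets dissolved).
#' @param signed If `FALSE`, use `|r|^power` instead of the signed adjacency.
#' @return A tibble: `feature`, `type` (when known), `module` (integer id,
#'   `NA` for unassigned), `module_label`.
#' @export
detect_modules <- function(C, power = 6, cut_height = 0.25, min_size = 3,
                           signed = TRUE) {
  type <- NULL
  if (is.list(C) && !is.matrix(C)) {
    type <- C$type
    C <- C$cor
  }
  stopifnot(is.matrix(C), nrow(C) == ncol(C), power > 0,
            cut_height > 0, cut_height < 1)
  adj <- if (signed) ((1 + C) / 2)^power else abs(C)^power
  diss <- 1 - adj
  if (all(abs(diss[upper.tri(diss)] - diss[upper.tri(diss)][1]) < 1e-12)) {
    warn("degenerate correlation structure: all features in a single module")
  }
  hc <- hclust(stats::as.dist(diss), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  module <- ifelse(raw %in% keep, match(raw, sort(keep)), NA_integer_)
  out <- tibble(
    feature = rownames(C),
    module = as.integer(module),
    module_label = ifelse(is.na(module), "unassigned",
                          paste0("M", sprintf("%02d", module)))
  )
  if (!is.null(type)) out <- dplyr::mutate(out, type = unname(type[.data$feature]),
                                           .after = "feature")
  out
}

#' Per-module ecological statistics
#'
#' For each module: size and composition; over its member taxa, Shannon's
#' diversity H on mean relative abundances, exp(H) (the effective number of
#' taxa), Pielou's evenness J = H / ln(richness) (undefined for a single
#' taxon), and the number of distinct taxonomic Orders; over its member
#' formulas, the relative abundance of elemental-composition groups.
#'
#' @param assignments Module tibble from [detect_modules()].
#' @param table Optional `community_tbl` with the taxon abundances.
#' @param taxonomy Optional taxonomy tibble (see [read_taxonomy()]).
#' @param formulas Optional formula property table (with `feature_id` and
#'   `elemental_group`).
#' @return A tibble, one row per module, with a list-column
#'   `elemental_proportions` (named numeric per module).
#' @export
module_stats <- function(assignments, table = NULL, taxonomy = NULL,
                         formulas = NULL) {
  a <- dplyr::filter(assignments, !is.na(.data$module))
  rel <- if (!is.null(table)) ct_matrix(to_relative(table)) else NULL
  purrr::list_rbind(lapply(split(a, a$module), function(mod) {
    feats <- mod$feature
    taxa <- if (!is.null(rel)) intersect(feats, rownames(rel)) else character()
    fmls <- if (!is.null(formulas)) intersect(feats, formulas$feature_id) else character()
    H <- expH <- J <- NA_real_
    n_orders <- NA_integer_
    if (length(taxa) > 0) {
      p <- rowMeans(rel[taxa, , drop = FALSE])
      p <- p / sum(p)
      H <- vegan::diversity(p, index = "shannon")
      expH <- exp(H)
      J <- if (length(taxa) > 1) H / log(length(taxa)) else NA_real_
      if (!is.null(taxonomy)) {
        ords <- taxonomy$Order[match(taxa, taxonomy$feature_id)]
        n_orders <- length(unique(ords[!is.na(ords)]))
      }
    }
    props <- if (length(fmls) > 0) {
      eg <- formulas$elemental_group[match(fmls, formulas$feature_id)]
      tab <- table(eg)
      stats::setNames(as.numeric(tab) / length(fmls), names(tab))
    } else {
      stats::setNames(numeric(0), character(0))
    }
    tibble(
      module = mod$module[1], module_label = mod$module_label[1],
      size = length(feats), n_taxa = length(taxa), n_formulas = length(fmls),
      shannon_H = H, exp_H = expH, pielou_J = J, n_orders = n_orders,
      elemental_proportions = list(props)
    )
  }))
}

#' Export a co-contribution network as edge and node tables
#'
#' Writes the thresholded correlation network in the plain tabular form graph
#' viewers import: an edge list (`source`, `target`, `weight`, `sign`) for
#' feature pairs with `|r| >= threshold`, and a node-attribute table
#' (`feature`, `type`, `module`).
#'
#' @param C Correlation matrix or [correlate_profiles()] result.
#' @param assignments Module tibble from [detect_modules()].
#' @param threshold Minimum `|r|` for an edge (default 0.7).
#' @return A list of tibbles `edges` and `nodes`.
#' @export
export_network <- function(C, assignments, threshold = 0.7) {
  if (is.list(C) && !is.matrix(C)) C <- C$cor
  feats <- rownames(C)
  idx <- which(upper.tri(C) & abs(C) >= threshold, arr.ind = TRUE)
  edges <- tibble(
    source = feats[idx[, 1]], target = feats[idx[, 2]],
    weight = C[idx], sign = ifelse(C[idx] >= 0, "positive", "negative")
  )
  nodes <- dplyr::filter(assignments, .data$feature %in% feats)
  list(edges = edges, nodes = nodes)
}
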