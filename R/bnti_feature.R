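#' Nearest-taxon distance of one feature to one sample
#'
#' The minimum relational distance from feature `a` to any feature present in
#' sample `j`. With `allow_conspecifics = TRUE` and `a` itself present in `j`
#' the result is 0; with `FALSE`, `a` is excluded from the minimum and the
#' result is `NA` when `j` holds no other feature.
#'
#' @param feature Feature identifier.
#' @param sample Sample identifier.
#' @param table A `community_tbl`.
#' @param D Cophenetic distance matrix over the table's features.
#' @param allow_conspecifics See [bnti_config()].
#' @return A single nonnegative number, or `NA` when no comparison feature
#'   exists.
#' @export
nearest_taxon_distance <- function(feature, sample, table, D,
                                   allow_conspecifics = TRUE) {
  X <- ct_matrix(table)
  stopifnot(feature %in% rownames(X), sample %in% colnames(X))
  present <- rownames(X)[X[, sample] > 0]
  if (!allow_conspecifics) present <- setdiff(present, feature)
  if (length(present) == 0) return(NA_real_)
  min(D[feature, present])
}

align_dist <- function(table, D) {
  feat <- ct_features(table)
  if (!setequal(feat, rownames(D))) {
    abort("table and distance matrix feature sets differ; run harmonize() first")
  }
  D[feat, feat, drop = FALSE]
}

#' Observed feature-level beta-MNTD
#'
#' The abundance-weighted mean nearest-taxon distance of one feature. In
#' scope (dataset/group) form this is \eqn{\bar w_a \cdot
#' \frac{1}{n}\sum_{j=1}^{n} \min d_{a b_j}} over the `samples` scope, with
#' \eqn{\bar w_a} the mean relative abundance of the feature over the scope
#' samples where it occurs. In pairwise form (`focal` and `partner` given) it
#' is \eqn{f_{a,\mathrm{focal}} \cdot \min d_{a b_\mathrm{partner}}}.
#'
#' @inheritParams nearest_taxon_distance
#' @param samples Scope samples (default: all samples in the table).
#' @param focal,partner Sample identifiers selecting the pairwise form.
#' @return A single nonnegative number; `NA` when the feature is absent from
#'   the scope or a comparison set is empty.
#' @export
feature_bmntd <- function(feature, table, D, samples = NULL,
                          focal = NULL, partner = NULL,
                          allow_conspecifics = TRUE) {
  rel <- to_relative(table)
  D <- align_dist(rel, D)
  X <- ct_matrix(rel)
  if (!is.null(focal) || !is.null(partner)) {
    stopifnot(!is.null(focal), !is.null(partner))
    f <- X[feature, focal]
    if (f == 0) return(NA_real_)
    return(f * nearest_taxon_distance(feature, partner, rel, D,
                                      allow_conspecifics))
  }
  samples <- samples %||% ct_samples(rel)
  occ <- X[feature, samples] > 0
  if (!any(occ)) return(NA_real_)
  w <- mean(X[feature, samples][occ])
  ntds <- vapply(samples, function(j) {
    nearest_taxon_distance(feature, j, rel, D, allow_conspecifics)
  }, numeric(1))
  w * mean(ntds)
}

# permutations + per-feature noise for a run; everything derives from cfg$seed
# and depends only on problem dimensions (never on abundances), which is what
# makes z-scores identical across counts / relative / presence inputs.
null_draws <- function(cfg, n_feat) {
  if (cfg$exhaustive) {
    if (n_feat > cfg$exhaustive_cap) {
      abort(sprintf(
        "exhaustive null over %d tips exceeds the cap of %d; use sampled nulls",
        n_feat, cfg$exhaustive_cap))
    }
    perms <- as.matrix(e1071::permutations(n_feat))
    storage.mode(perms) <- "integer"
    list(perms = perms, noise = matrix(0, nrow(perms), n_feat))
  } else {
    withr::with_seed(cfg$seed, {
      perms <- t(vapply(seq_len(cfg$n_null), function(r) sample.int(n_feat),
                        integer(n_feat)))
      noise <- matrix(runif(cfg$n_null * n_feat, cfg$noise_low, cfg$noise_high),
                      cfg$n_null, n_feat)
      list(perms = perms, noise = noise)
    })
  }
}

#' Null distribution of feature-level beta-MNTD
#'
#' Recomputes [feature_bmntd()] for each tip-shuffle replicate (abundances
#' untouched), adding a uniform noise term per replicate. With
#' `cfg$exhaustive = TRUE`, one value per distinct tip-label permutation and
#' no noise.
#'
#' @inheritParams feature_bmntd
#' @param cfg A [bnti_config()].
#' @return Numeric vector of null beta-MNTD values.
#' @export
null_distribution <- function(feature, table, D, samples = NULL,
                              focal = NULL, partner = NULL,
                              cfg = bnti_config()) {
  rel <- to_relative(table)
  D <- align_dist(rel, D)
  X <- ct_matrix(rel)
  feats <- rownames(X)
  a <- match(feature, feats)
  stopifnot(!is.na(a))
  draws <- null_draws(cfg, length(feats))
  pairwise <- !is.null(focal) || !is.null(partner)
  if (pairwise) {
    stopifnot(!is.null(focal), !is.null(partner))
    w <- X[feature, focal]
    presence <- matrix(X[, partner] > 0, ncol = 1)
  } else {
    samples <- samples %||% ct_samples(rel)
    occ <- X[feature, samples] > 0
    w <- if (any(occ)) mean(X[feature, samples][occ]) else NA_real_
    presence <- X[, samples, drop = FALSE] > 0
  }
  raw <- null_scope_means_cpp(D, presence, draws$perms, cfg$allow_conspecifics)
  w * raw[, a] + draws$noise[, a]
}

#' Feature-level beta-NTI for a single feature
#'
#' The z-score of the observed feature-level beta-MNTD against its
#' tip-shuffling null distribution, with the sample standard deviation
#' (denominator n - 1) in the denominator.
#'
#' @inheritParams null_distribution
#' @return A one-row tibble: `feature`, `abundance_weight`, `bmntd_obs`,
#'   `null_mean`, `null_sd`, `bnti`, `category`.
#' @export
feature_bnti <- function(feature, table, D, samples = NULL,
                         focal = NULL, partner = NULL, cfg = bnti_config()) {
  obs <- feature_bmntd(feature, table, D, samples, focal, partner,
                       cfg$allow_conspecifics)
  rel <- to_relative(table)
  X <- ct_matrix(rel)
  if (is.null(focal)) {
    sc <- samples %||% ct_samples(rel)
    occ <- X[feature, sc] > 0
    w <- if (any(occ)) mean(X[feature, sc][occ]) else NA_real_
  } else {
    w <- X[feature, focal]
  }
  if (is.na(obs) && (is.na(w) || w == 0)) {
    return(tibble(feature = feature, abundance_weight = w, bmntd_obs = NA_real_,
                  null_mean = NA_real_, null_sd = NA_real_, bnti = NA_real_,
                  category = "Absent"))
  }
  nulls <- null_distribution(feature, table, D, samples, focal, partner, cfg)
  summarise_record(feature, w, obs, nulls)
}

summarise_record <- function(feature, w, obs, nulls) {
  feature <- unname(feature); w <- unname(w); obs <- unname(obs)
  nulls <- unname(nulls)
  if (is.na(obs) || anyNA(nulls)) {
    return(tibble(feature = feature, abundance_weight = w, bmntd_obs = obs,
                  null_mean = NA_real_, null_sd = NA_real_, bnti = NA_real_,
                  category = "Undefined"))
  }
  m <- mean(nulls)
  s <- sd(nulls)  # NA for a single replicate
  z <- if (!is.na(s) && s > 0) (obs - m) / s else NA_real_
  tibble(feature = feature, abundance_weight = w, bmntd_obs = obs,
         null_mean = m, null_sd = s, bnti = z,
         category = classify_contribution(z))
}

#' Feature-level beta-NTI across a whole table
#'
#' The main driver. Computes one feature-level z-score record per feature
#' (dataset mode), per feature per group (group mode, nulls drawn within each
#' group's samples only), or per feature per non-focal partner sample
#' (pairwise mode). Within a null replicate one shared tip-label permutation
#' is applied to all features and partners, so features are comparable within
#' a replicate; all randomness derives from `cfg$seed`.
#'
#' @param table A `community_tbl` (any abundance mode; z-scores are invariant
#'   to whether counts, relative abundances, or presence/absence are supplied).
#' @param D Cophenetic distance matrix whose labels match the table's
#'   features (see [harmonize()]).
#' @param mode `"dataset"`, `"group"`, or `"pairwise"`.
#' @param groups For group mode: a data frame with columns `sample` and
#'   `group`, or a named character vector (names = samples).
#' @param focal For pairwise mode: the fixed focal sample identifier.
#' @param cfg A [bnti_config()].
#' @return An object of class `bnti_feat`; use [tidy()] for the per-record
#'   tibble, [glance()] for a one-row summary, [autoplot()] to plot.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' D <- cophenetic_matrix(tree)
#' ct <- as_community_table(
#'   data.frame(sample = c("S1", "S2"), A = c(1, 0), B = c(1, 0),
#'              C = c(0, 1), D = c(0, 1)),
#'   mode = "counts"
#' )
#' fit <- bnti_feat(ct, D, mode = "dataset", cfg = bnti_config(n_null = 99))
#' tidy(fit)
#' @export
bnti_feat <- function(table, D, mode = c("dataset", "group", "pairwise"),
                      groups = NULL, focal = NULL, cfg = bnti_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "community_tbl"))
  rel <- to_relative(table)
  D <- align_dist(rel, D)
  X <- ct_matrix(rel)
  feats <- rownames(X)
  draws <- null_draws(cfg, length(feats))

  parts <- switch(
    mode,
    dataset = list(scope_records(X, D, scope_label = "dataset",
                                 samples = colnames(X), draws = draws, cfg = cfg)),
    group = {
      g <- normalise_groups(groups, colnames(X))
      lapply(split(names(g), g), function(ss) {
        scope_records(X, D, scope_label = unique(g[ss])[1], samples = ss,
                      draws = draws, cfg = cfg)
      })
    },
    pairwise = {
      if (is.null(focal)) abort("pairwise mode needs a focal sample")
      if (!focal %in% colnames(X)) abort(paste0("focal sample not found: ", focal))
      list(pairwise_records(X, D, focal = focal, draws = draws, cfg = cfg))
    }
  )
  records <- purrr::list_rbind(lapply(parts, `[[`, "records"))
  records$n_null <- nrow(draws$perms)
  records$seed <- cfg$seed

  n_quirk <- sum(vapply(parts, `[[`, integer(1), "quirk"))
  if (n_quirk > 0) {
    warn(sprintf(paste0(
      "%d record(s) are conspecific in every scope sample: their null ",
      "distribution is pure injected noise, so bnti ~ -2.6 by construction"),
      n_quirk))
  }
  structure(list(records = records, mode = mode, focal = focal, cfg = cfg,
                 n_features = length(feats),
                 samples = colnames(X)),
            class = "bnti_feat")
}

normalise_groups <- function(groups, samples) {
  if (is.null(groups)) abort("group mode needs a `groups` mapping")
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample", "group") %in% names(groups)))
    g <- stats::setNames(as.character(groups$group), groups$sample)
  } else {
    g <- stats::setNames(as.character(groups), names(groups))
  }
  missing <- setdiff(samples, names(g))
  if (length(missing)) {
    abort(paste0("samples without a group label: ", paste(missing, collapse = ", ")))
  }
  g[samples]
}

# one record per feature over a fixed sample scope (dataset/group modes)
scope_records <- function(X, D, scope_label, samples, draws, cfg) {
  presence <- X[, samples, drop = FALSE] > 0
  feats <- rownames(X)
  occ_n <- rowSums(presence)
  w <- ifelse(occ_n > 0,
              rowSums(X[, samples, drop = FALSE]) / pmax(occ_n, 1), NA_real_)

  obs_raw <- rowMeans(ntd_matrix_cpp(D, presence, seq_along(feats),
                                     cfg$allow_conspecifics))
  null_raw <- null_scope_means_cpp(D, presence, draws$perms,
                                   cfg$allow_conspecifics)

  quirk <- 0L
  recs <- purrr::list_rbind(lapply(seq_along(feats), function(a) {
    if (occ_n[a] == 0) {
      return(tibble(feature = feats[a], abundance_weight = NA_real_,
                    bmntd_obs = NA_real_, null_mean = NA_real_,
                    null_sd = NA_real_, bnti = NA_real_, category = "Absent"))
    }
    raw <- null_raw[, a]
    if (!anyNA(raw) && !is.na(obs_raw[a]) &&
        obs_raw[a] == 0 && all(raw == 0) && max(draws$noise[, a]) > 0) {
      quirk <<- quirk + 1L
    }
    summarise_record(feats[a], w[a], w[a] * obs_raw[a],
                     w[a] * raw + draws$noise[, a])
  }))
  recs$scope_label <- scope_label
  recs$partner <- NA_character_
  list(records = recs[c("feature", "scope_label", "partner",
                        "abundance_weight", "bmntd_obs", "null_mean",
                        "null_sd", "bnti", "category")],
       quirk = quirk)
}

# one record per feature per non-focal partner (pairwise mode)
pairwise_records <- function(X, D, focal, draws, cfg) {
  feats <- rownames(X)
  partners <- setdiff(colnames(X), focal)
  presence <- X > 0
  nrep <- nrow(draws$perms)

  obs_raw <- ntd_matrix_cpp(D, presence, seq_along(feats),
                            cfg$allow_conspecifics)
  # null array: replicate x feature x sample
  null_raw <- array(NA_real_, c(nrep, length(feats), ncol(X)))
  for (r in seq_len(nrep)) {
    null_raw[r, , ] <- ntd_matrix_cpp(D, presence, draws$perms[r, ],
                                      cfg$allow_conspecifics)
  }

  f_focal <- X[, focal]
  quirk <- 0L
  recs <- purrr::list_rbind(lapply(partners, function(j) {
    jj <- match(j, colnames(X))
    purrr::list_rbind(lapply(seq_along(feats), function(a) {
      if (f_focal[a] == 0) {
        return(tibble(feature = feats[a], partner = j,
                      abundance_weight = 0, bmntd_obs = NA_real_,
                      null_mean = NA_real_, null_sd = NA_real_,
                      bnti = NA_real_, category = "Absent"))
      }
      raw <- null_raw[, a, jj]
      if (!anyNA(raw) && !is.na(obs_raw[a, jj]) &&
          obs_raw[a, jj] == 0 && all(raw == 0) && max(draws$noise[, a]) > 0) {
        quirk <<- quirk + 1L
      }
      rec <- summarise_record(feats[a], f_focal[a],
                              f_focal[a] * obs_raw[a, jj],
                              f_focal[a] * raw + draws$noise[, a])
      rec$partner <- j
      rec
    }))
  }))
  recs$scope_label <- paste0("focal:", focal)
  list(records = recs[c("feature", "scope_label", "partner",
                        "abundance_weight", "bmntd_obs", "null_mean",
                        "null_sd", "bnti", "category")],
       quirk = quirk)
}

#' @export
print.bnti_feat <- function(x, ...) {
  cat(sprintf("Feature-level beta-NTI (%s mode): %d features, %d records\n",
              x$mode, x$n_features, nrow(x$records)))
  print(table(x$records$category))
  invisible(x)
}

#' @rdname bnti_feat
#' @param x A `bnti_feat` object.
#' @param ... Unused.
#' @export
tidy.bnti_feat <- function(x, ...) x$records

#' @rdname bnti_feat
#' @export
glance.bnti_feat <- function(x, ...) {
  z <- x$records$bnti
  tibble(
    mode = x$mode, n_features = x$n_features, n_records = nrow(x$records),
    n_null = x$records$n_null[1], seed = x$cfg$seed,
    mean_bnti = mean(z, na.rm = TRUE),
    prop_significant = mean(abs(z) > 2, na.rm = TRUE),
    prop_convergent = mean(z < -1, na.rm = TRUE),
    prop_divergent = mean(z > 1, na.rm = TRUE)
  )
}

#' @rdname bnti_feat
#' @param object A `bnti_feat` object.
#' @export
autoplot.bnti_feat <- function(object, ...) {
  d <- dplyr::filter(object$records, !is.na(.data$bnti))
  d$feature <- stats::reorder(d$feature, d$bnti)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$bnti,
                                  colour = .data$category)) +
    ggplot2::geom_hline(yintercept = c(-2, -1, 1, 2), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(...) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "feature-level beta-NTI",
                  colour = "Contribution") +
    ggplot2::theme_minimal()
}

#' Write feature-level results to TSV
#'
#' @param x A `bnti_feat` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bnti <- function(x, path) {
  stopifnot(inherits(x, "bnti_feat"))
  write.table(x$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
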