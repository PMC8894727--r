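#' Read a taxonomy map
#'
#' Columns: `feature_id`, then the ranked lineage `Domain`, `Phylum`,
#' `Class`, `Order`, `Family`, `Genus` (missing ranks empty).
#'
#' @param path TSV path.
#' @return A tibble; empty strings become `NA`.
#' @export
read_taxonomy <- function(path) {
  tx <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             na.strings = c("", "NA")))
  if (!"feature_id" %in% names(tx)) abort("taxonomy map needs a feature_id column")
  if (anyDuplicated(tx$feature_id)) abort("duplicate feature_id in taxonomy map")
  tx
}

taxonomy_ranks <- c("Domain", "Phylum", "Class", "Order", "Family", "Genus")

#' Compare feature contributions across two runs
#'
#' Labels each feature by which of two runs (e.g. total vs putatively active
#' community, or dry vs inundated assemblage) shows the stronger absolute
#' contribution: `A_favored` when `|z_A| - |z_B| > tol`, `B_favored` when
#' below `-tol`, `Neither` otherwise; features seen in only one run are
#' `A_only` / `B_only`.
#'
#' @param rec_a,rec_b Record tibbles (from `tidy()` on two [bnti_feat()]
#'   fits) sharing a feature namespace; one record per feature.
#' @param tol Numerical guard around an exact tie (default 1e-6).
#' @return A tibble: `feature`, `bnti_a`, `bnti_b`, `label`.
#' @export
compare_datasets <- function(rec_a, rec_b, tol = 1e-6) {
  for (r in list(rec_a, rec_b)) {
    if (anyDuplicated(r$feature)) abort("duplicate feature within a run")
  }
  merged <- dplyr::full_join(
    dplyr::select(rec_a, "feature", bnti_a = "bnti"),
    dplyr::select(rec_b, "feature", bnti_b = "bnti"),
    by = "feature"
  )
  in_a <- merged$feature %in% rec_a$feature
  in_b <- merged$feature %in% rec_b$feature
  diff <- abs(merged$bnti_a) - abs(merged$bnti_b)
  merged$label <- dplyr::case_when(
    in_a & !in_b ~ "A_only",
    !in_a & in_b ~ "B_only",
    is.na(diff)  ~ "Neither",
    diff > tol   ~ "A_favored",
    diff < -tol  ~ "B_favored",
    TRUE         ~ "Neither"
  )
  merged
}

#' Aggregate feature contributions by taxonomic rank
#'
#' Summarises z-scores within taxonomic groups (e.g. Family): member count,
#' mean and median z, the share of members in each contribution category, and
#' flags for groups whose mean contributes (`|mean z| > 1`) or significantly
#' contributes (`|mean z| > 2`). Both mean and median are reported because
#' means of bimodal groups (convergers plus divergers) are misleading.
#'
#' @param records A record tibble from `tidy()` on a [bnti_feat()] fit.
#' @param taxonomy A taxonomy tibble (see [read_taxonomy()]).
#' @param rank One of Domain, Phylum, Class, Order, Family, Genus.
#' @return A tibble, one row per group per scope label.
#' @export
aggregate_by_rank <- function(records, taxonomy, rank = "Family") {
  if (!rank %in% taxonomy_ranks) {
    abort(paste0("unknown rank '", rank, "'; expected one of ",
                 paste(taxonomy_ranks, collapse = ", ")))
  }
  parent <- c("root", taxonomy_ranks)[match(rank, taxonomy_ranks)]
  tx <- taxonomy
  tx$group <- tx[[rank]]
  if (parent != "root" && parent %in% names(tx)) {
    fallback <- paste("Unclassified", dplyr::coalesce(tx[[parent]], "root"))
  } else {
    fallback <- "Unclassified root"
  }
  tx$group <- dplyr::coalesce(tx$group, fallback)
  d <- dplyr::left_join(records, dplyr::select(tx, feature = "feature_id", "group"),
                        by = "feature")
  d$group <- dplyr::coalesce(d$group, "Unclassified root")
  d |>
    dplyr::group_by(.data$scope_label, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_bnti = mean(.data$bnti, na.rm = TRUE),
      median_bnti = stats::median(.data$bnti, na.rm = TRUE),
      prop_sig_convergence = mean(.data$category == "SigConvergence"),
      prop_convergence = mean(.data$category == "Convergence"),
      prop_insignificant = mean(.data$category == "Insignificant"),
      prop_divergence = mean(.data$category == "Divergence"),
      prop_sig_divergence = mean(.data$category == "SigDivergence"),
      mean_contributes = !is.na(mean(.data$bnti, na.rm = TRUE)) &
        abs(mean(.data$bnti, na.rm = TRUE)) > 1,
      mean_significant = !is.na(mean(.data$bnti, na.rm = TRUE)) &
        abs(mean(.data$bnti, na.rm = TRUE)) > 2,
      .groups = "drop"
    )
}

#' Contribution-type frequencies within groupings
#'
#' For each group (an elemental-composition group, a compound class, a
#' taxonomic group, ...), the proportion of features falling in each
#' contribution category. Proportions within a group sum to 1.
#'
#' @param records A record tibble from `tidy()` on a [bnti_feat()] fit.
#' @param grouping Named character vector mapping feature id to group label,
#'   or a data frame with columns `feature` and `group`.
#' @return A tibble: `group`, `category`, `n`, `proportion`.
#' @export
contribution_frequency <- function(records, grouping) {
  if (is.data.frame(grouping)) {
    g <- stats::setNames(as.character(grouping$group), grouping$feature)
  } else {
    g <- grouping
  }
  ungrouped <- setdiff(records$feature, names(g))
  if (length(ungrouped)) {
    abort(paste0("features without a group: ", paste(utils::head(ungrouped, 5),
                                                     collapse = ", ")))
  }
  d <- records
  d$group <- unname(g[d$feature])
  out <- d |>
    dplyr::count(.data$group, .data$category, name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  empty <- setdiff(unique(unname(g)), out$group)
  if (length(empty)) {
    warn(paste0("omitting empty group(s): ", paste(empty, collapse = ", ")))
  }
  out
}

#' Temporal/spatial profile of pairwise results against a fixed focal sample
#'
#' Reshapes pairwise-mode records into a features x partners matrix of
#' z-scores. Absent/Undefined entries stay missing (`NA`): a missing z-value
#' is information, not a zero.
#'
#' @param records Pairwise-mode records from `tidy()` on a [bnti_feat()] fit.
#' @param focal The focal sample the run was anchored on.
#' @param sample_order Ordered partner samples for the columns (default: the
#'   order of first appearance in the records).
#' @return A `bnti_profile`: a numeric matrix (features x partners) with
#'   attributes `focal` and class `bnti_profile`.
#' @export
temporal_profile <- function(records, focal, sample_order = NULL) {
  if (!"partner" %in% names(records) || all(is.na(records$partner))) {
    abort("records are not from a pairwise-mode run")
  }
  if (!all(records$scope_label == paste0("focal:", focal))) {
    abort(paste0("records were not computed against focal sample '", focal, "'"))
  }
  partners <- sample_order %||% unique(records$partner)
  extra <- setdiff(unique(records$partner), partners)
  if (length(extra)) abort(paste0("sample_order omits partner(s): ",
                                  paste(extra, collapse = ", ")))
  wide <- records |>
    dplyr::select("feature", "partner", "bnti") |>
    tidyr::pivot_wider(names_from = "partner", values_from = "bnti")
  m <- as.matrix(wide[intersect(partners, names(wide))])
  rownames(m) <- wide$feature
  m <- m[, partners[partners %in% colnames(m)], drop = FALSE]
  structure(m, focal = focal, class = c("bnti_profile", class(m)))
}

#' Heatmap of a pairwise profile
#'
#' @param object A `bnti_profile` from [temporal_profile()].
#' @param ... Passed to [ggplot2::geom_tile()].
#' @return A ggplot object.
#' @export
autoplot.bnti_profile <- function(object, ...) {
  d <- as.data.frame(as.table(unclass(object)))
  names(d) <- c("feature", "partner", "bnti")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$partner, y = .data$feature,
                                  fill = .data$bnti)) +
    ggplot2::geom_tile(...) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey85") +
    ggplot2::labs(x = paste0("partner sample (focal: ", attr(object, "focal"), ")"),
                  y = NULL, fill = "beta-NTI (feature)") +
    ggplot2::theme_minimal()
}
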