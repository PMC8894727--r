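#' Random feature tree
#'
#' A Yule-process (random-splitting) topology with exponential branch lengths
#' (mean 1), tips labelled `t1 ... tn`. Deterministic per seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` object.
#' @export
random_tree <- function(n_tips, seed = 1L) {
  stopifnot(n_tips >= 2)
  tree <- withr::with_seed(seed, ape::rtree(n_tips, br = rexp))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  validate_tree(tree)
}

#' Neutral synthetic communities
#'
#' Presence/absence assembled independently of the tree: each feature occurs
#' in each sample independently with probability `occupancy`, with log-normal
#' abundances on occurrences. Samples that come up empty are resampled (and
#' reported). Because assembly ignores the tree, feature-level z-scores on
#' these tables calibrate the null model's type-I behaviour.
#'
#' @param tree A `phylo` whose tips are the features.
#' @param n_samples Number of samples.
#' @param occupancy Per-feature, per-sample presence probability in (0, 1].
#' @param seed Integer seed.
#' @return A `community_tbl` with mode `"counts"`.
#' @export
neutral_communities <- function(tree, n_samples, occupancy = 0.3, seed = 1L) {
  stopifnot(occupancy > 0, occupancy <= 1)
  feats <- tree$tip.label
  withr::with_seed(seed, {
    m <- matrix(0, n_samples, length(feats),
                dimnames = list(paste0("S", seq_len(n_samples)), feats))
    for (s in seq_len(n_samples)) {
      repeat {
        pres <- runif(length(feats)) < occupancy
        if (any(pres)) break
        inform(sprintf("resampling empty sample %d", s))
      }
      m[s, pres] <- rlnorm(sum(pres), meanlog = 0, sdlog = 1)
    }
    as_community_table(m, mode = "counts")
  })
}

#' Scenario specification for structured communities
#'
#' @param regime `"clade_filter"` (a monophyletic clade consistently
#'   co-occurs across all samples, the expected signature of convergence) or
#'   `"group_contrast"` (two disjoint clades are confined to opposite halves
#'   of the samples, the expected signature of divergence).
#' @param n_samples Number of samples.
#' @param target_clade Either a character vector of tip labels forming a
#'   monophyletic clade, or a fraction in (0, 1) -- a clade with about that
#'   share of the tips is selected from the tree.
#' @param selection_strength In `[0, 1]`; 0 reduces every regime to neutral.
#' @param occupancy Background presence probability.
#' @param seed Integer seed.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(regime = c("clade_filter", "group_contrast"),
                          n_samples = 20, target_clade = 0.2,
                          selection_strength = 0.9, occupancy = 0.3,
                          seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(selection_strength >= 0, selection_strength <= 1,
            occupancy > 0, occupancy <= 1)
  structure(list(regime = regime, n_samples = n_samples,
                 target_clade = target_clade,
                 selection_strength = selection_strength,
                 occupancy = occupancy, seed = as.integer(seed)),
            class = "scenario_spec")
}

# tips descending from each internal node
clade_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, function(idx) tree$tip.label[idx])
}

pick_clade <- function(tree, fraction, exclude = character()) {
  sets <- clade_tip_sets(tree)
  sets <- Filter(function(s) length(s) >= 2 && !any(s %in% exclude), sets)
  if (!length(sets)) abort("no disjoint clade available")
  sizes <- vapply(sets, length, integer(1))
  target <- max(2, round(fraction * length(tree$tip.label)))
  sets[[which.min(abs(sizes - target))]]
}

check_monophyletic <- function(tree, tips) {
  sets <- clade_tip_sets(tree)
  ok <- any(vapply(sets, function(s) setequal(s, tips), logical(1))) ||
    length(tips) == 1
  if (!ok) abort("target_clade is not a monophyletic tip set")
  invisible(TRUE)
}

#' Selection-structured synthetic communities with known truth
#'
#' Generates presence/abundance tables in which a known monophyletic clade is
#' under selection, so detection power and sign agreement of the feature-level
#' metric can be measured without external data. Selection acts on occupancy
#' (presence), not abundance: the feature-level z-score is abundance-invariant
#' under the tip-shuffling null, so abundance-based selection would be
#' untestable by design.
#'
#' \describe{
#'   \item{clade_filter}{target-clade tips get occupancy boosted toward 1
#'     (`occ + s (1 - occ)`) in all samples while background tips are drawn
#'     neutrally; consistent clade-restricted co-occurrence, expected
#'     negative z for targets.}
#'   \item{group_contrast}{samples split into two halves; the target clade is
#'     present only in the first half (with probability
#'     `occ + s (1 - occ)` there, 0 elsewhere) and a disjoint second clade
#'     only in the second half; expected positive z for both clades in
#'     dataset mode.}
#' }
#'
#' @param tree A `phylo` whose tips are the features.
#' @param spec A [scenario_spec()].
#' @return A list: `table` (a `community_tbl`, mode counts) and `truth`, a
#'   tibble with per-feature expected labels
#'   (`expected_convergent` / `expected_divergent` / `background`).
#' @export
structured_communities <- function(tree, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  feats <- tree$tip.label
  s <- spec$selection_strength

  if (is.character(spec$target_clade)) {
    target <- spec$target_clade
    check_monophyletic(tree, target)
  } else {
    target <- withr::with_seed(spec$seed, pick_clade(tree, spec$target_clade))
  }
  boosted <- spec$occupancy + s * (1 - spec$occupancy)

  withr::with_seed(spec$seed + 1L, {
    occ <- matrix(spec$occupancy, length(feats), spec$n_samples,
                  dimnames = list(feats, NULL))
    truth_label <- rep("background", length(feats))
    names(truth_label) <- feats

    if (spec$regime == "clade_filter") {
      occ[target, ] <- boosted
      if (s > 0) truth_label[target] <- "expected_convergent"
    } else {
      other <- pick_clade(tree, if (is.numeric(spec$target_clade))
        spec$target_clade else length(target) / length(feats),
        exclude = target)
      half1 <- seq_len(floor(spec$n_samples / 2))
      half2 <- setdiff(seq_len(spec$n_samples), half1)
      occ[target, half2] <- (1 - s) * spec$occupancy
      occ[target, half1] <- boosted
      occ[other, half1] <- (1 - s) * spec$occupancy
      occ[other, half2] <- boosted
      if (s > 0) truth_label[c(target, other)] <- "expected_divergent"
    }

    m <- matrix(0, spec$n_samples, length(feats),
                dimnames = list(paste0("S", seq_len(spec$n_samples)), feats))
    for (ss in seq_len(spec$n_samples)) {
      repeat {
        pres <- runif(length(feats)) < occ[, ss]
        if (any(pres)) break
      }
      m[ss, pres] <- rlnorm(sum(pres), meanlog = 0, sdlog = 1)
    }
    list(
      table = as_community_table(m, mode = "counts"),
      truth = tibble(feature = feats, label = unname(truth_label))
    )
  })
}

#' Random molecular-formula table
#'
#' Element counts drawn from ranges typical of FTICR-MS assignments (C 5-50,
#' H 6-80, O 1-30, N/S/P 0-3), rejecting chemically impossible combinations
#' (negative DBE, or H > 2C + 2 + N). Neutral monoisotopic masses are
#' computed from the counts.
#'
#' @param n Number of formulas (>= 2).
#' @param seed Integer seed.
#' @return A property tibble (as from [molecular_properties()]) with
#'   `feature_id` `f1 ... fn` and a `mass` column.
#' @export
random_formula_table <- function(n, seed = 1L) {
  stopifnot(n >= 2)
  masses <- c(C = 12, H = 1.0078250319, O = 15.9949146221,
              N = 14.0030740052, S = 31.97207069, P = 30.97376151)
  withr::with_seed(seed, {
    draw_one <- function() {
      repeat {
        v <- c(C = sample(5:50, 1), H = sample(6:80, 1), O = sample(1:30, 1),
               N = sample(0:3, 1), S = sample(0:3, 1), P = sample(0:3, 1))
        dbe <- 1 + (2 * v["C"] - v["H"] + v["N"] + v["P"]) / 2
        if (dbe >= 0 && v["H"] <= 2 * v["C"] + 2 + v["N"]) return(v)
      }
    }
    counts <- t(vapply(seq_len(n), function(i) draw_one(), numeric(6)))
    tbl <- as_tibble(as.data.frame(counts))
    tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::everything(), as.integer))
    tbl$feature_id <- paste0("f", seq_len(n))
    tbl$mass <- as.numeric(counts %*% masses[colnames(counts)])
    tbl <- dplyr::relocate(tbl, "feature_id")
    suppressMessages(molecular_properties(tbl))
  })
}
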