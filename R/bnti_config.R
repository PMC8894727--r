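#' Null-model configuration
#'
#' Bundles the knobs of the tip-shuffling null model. Defaults follow the
#' standard practice for nearest-taxon null models: 999 randomised communities
#' and a tiny uniform "phylogenetic noise" term (1e-20 to 5e-20) added to each
#' null value so that features present on both halves of a comparison
#' (conspecifics, whose null nearest-taxon distance is exactly zero) still
#' receive a finite z-score rather than a 0/0.
#'
#' @param n_null Number of null replicates (default 999).
#' @param noise_low,noise_high Bounds of the uniform noise injected into each
#'   null value. Set both to 0 to disable; conspecific-everywhere features
#'   then come out `Undefined`.
#' @param seed Integer seed; every source of randomness in a run derives from
#'   it.
#' @param exhaustive If `TRUE`, enumerate every distinct tip-label permutation
#'   instead of sampling (no noise is added). Only permitted up to
#'   `exhaustive_cap` tips.
#' @param allow_conspecifics If `TRUE` (default) a feature present in the
#'   comparison sample contributes a nearest distance of zero, matching the
#'   inclusion semantics of `picante::comdistnt`; if `FALSE` the feature
#'   itself is excluded from the minimum.
#' @param exhaustive_cap Largest tip count for which exhaustive enumeration is
#'   allowed (default 8, i.e. at most 40320 permutations).
#' @return A list of class `bnti_config`.
#' @export
bnti_config <- function(n_null = 999, noise_low = 1e-20, noise_high = 5e-20,
                        seed = 1L, exhaustive = FALSE,
                        allow_conspecifics = TRUE, exhaustive_cap = 8L) {
  stopifnot(n_null >= 1, noise_low >= 0, noise_low <= noise_high,
            is.numeric(seed), length(seed) == 1)
  structure(
    list(n_null = as.integer(n_null), noise_low = noise_low,
         noise_high = noise_high, seed = as.integer(seed),
         exhaustive = isTRUE(exhaustive),
         allow_conspecifics = isTRUE(allow_conspecifics),
         exhaustive_cap = as.integer(exhaustive_cap)),
    class = "bnti_config"
  )
}

#' Contribution categories
#'
#' The ordered set of per-feature contribution labels.
#' @export
contribution_levels <- c("SigConvergence", "Convergence", "Insignificant",
                         "Divergence", "SigDivergence", "Undefined", "Absent")

#' Classify a feature-level z-score
#'
#' `|z| < 1` is an insignificant contribution to ecological variation;
#' `1 <= |z| < 2` somewhat contributes (Convergence when negative, Divergence
#' when positive); `|z| >= 2` significantly contributes (SigConvergence /
#' SigDivergence). Boundary values are assigned to the higher-magnitude
#' category. `NA` maps to `Undefined`.
#'
#' @param z Numeric vector of z-scores (NA allowed).
#' @return Character vector of contribution categories.
#' @examples
#' classify_contribution(c(2.5, -1.5, 0.99, NA))
#' @export
classify_contribution <- function(z) {
  dplyr::case_when(
    is.na(z)          ~ "Undefined",
    abs(z) < 1        ~ "Insignificant",
    abs(z) < 2 & z < 0 ~ "Convergence",
    abs(z) < 2        ~ "Divergence",
    z < 0             ~ "SigConvergence",
    TRUE              ~ "SigDivergence"
  )
}
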