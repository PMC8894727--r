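#' Parse molecular formula strings
#'
#' Parses formulas written over the elements C, H, O, N, S, P (the elements
#' FTICR-MS assignment routines report), e.g. `"C47H68O10"` or `"C34H63O4P"`.
#' An omitted count means 1; an absent element means 0.
#'
#' @param x Character vector of formula strings.
#' @param feature_id Optional identifiers; defaults to the formula strings.
#' @return A tibble with columns `feature_id`, `formula`, `C`, `H`, `O`, `N`,
#'   `S`, `P`, and `elemental_group` (the letters of the elements present,
#'   in C,H,O,N,S,P order).
#' @examples
#' parse_formula(c("C6H12O6", "C34H63O4P"))
#' @export
parse_formula <- function(x, feature_id = x) {
  stopifnot(length(feature_id) == length(x))
  elements <- c("C", "H", "O", "N", "S", "P")
  rows <- lapply(seq_along(x), function(i) {
    s <- x[i]
    if (!grepl("^([CHONSP][0-9]*)+$", s)) {
      bad <- regmatches(s, regexpr("[^CHONSP0-9]", s))
      abort(sprintf("cannot parse formula '%s'%s", s,
                    if (length(bad)) paste0(": unknown element symbol '", bad, "'") else ""))
    }
    toks <- regmatches(s, gregexpr("[CHONSP][0-9]*", s))[[1]]
    sym <- substr(toks, 1, 1)
    if (anyDuplicated(sym)) {
      abort(sprintf("repeated element '%s' in formula '%s'",
                    sym[duplicated(sym)][1], s))
    }
    cnt <- ifelse(nchar(toks) == 1, 1L, as.integer(substring(toks, 2)))
    counts <- stats::setNames(integer(6), elements)
    counts[sym] <- cnt
    counts
  })
  m <- do.call(rbind, rows)
  out <- tibble(feature_id = feature_id, formula = x)
  out <- dplyr::bind_cols(out, as_tibble(m))
  if (any(out$C < 1)) {
    abort(sprintf("formula without carbon: %s",
                  paste(out$formula[out$C < 1], collapse = ", ")))
  }
  out$elemental_group <- elemental_group(out)
  out
}

elemental_group <- function(tbl) {
  elements <- c("C", "H", "O", "N", "S", "P")
  apply(as.matrix(tbl[elements]) > 0, 1, function(p) {
    paste(elements[p], collapse = "")
  })
}

#' Derived molecular properties
#'
#' Adds the standard FTICR-MS molecular descriptors to a formula table:
#' double-bond equivalents (DBE), the modified aromaticity index (AImod),
#' nominal oxidation state of carbon (NOSC), O/C and H/C ratios, and --
#' when a `mass` column is present -- the CH2-based Kendrick mass and defect.
#'
#' \itemize{
#'   \item `dbe = 1 + (2C - H + N + P) / 2`
#'   \item `ai_mod = (1 + C - O/2 - S - (N + P + H)/2) / (C - O/2 - N - S - P)`,
#'     clamped to 0 when the numerator is negative or the denominator is
#'     nonpositive (without the clamp, P-rich formulas yield meaningless
#'     negative aromaticities).
#'   \item `nosc = 4 - (4C + H - 3N - 2O + 5P - 2S) / C`
#'   \item `kendrick_mass = mass * 14 / 14.01565`;
#'     `kendrick_defect = round(kendrick_mass) - kendrick_mass`
#'     (nominal-minus-Kendrick sign convention; `kendrick = "floor"` switches
#'     the nominal mass to `floor()`).
#' }
#'
#' @param tbl A tibble from [parse_formula()] (or with columns `C`,`H`,`O`,
#'   `N`,`S`,`P`), optionally with a numeric `mass` column (neutral
#'   monoisotopic, Da).
#' @param kendrick `"round"` (default) or `"floor"` nominal-mass convention.
#' @return The input tibble with property columns appended.
#' @export
molecular_properties <- function(tbl, kendrick = c("round", "floor")) {
  kendrick <- match.arg(kendrick)
  stopifnot(all(c("C", "H", "O", "N", "S", "P") %in% names(tbl)))
  out <- dplyr::mutate(
    tbl,
    oc_ratio = .data$O / .data$C,
    hc_ratio = .data$H / .data$C,
    dbe = 1 + (2 * .data$C - .data$H + .data$N + .data$P) / 2,
    nosc = 4 - (4 * .data$C + .data$H - 3 * .data$N - 2 * .data$O +
                  5 * .data$P - 2 * .data$S) / .data$C
  )
  ai_num <- 1 + out$C - out$O / 2 - out$S - (out$N + out$P + out$H) / 2
  ai_den <- out$C - out$O / 2 - out$N - out$S - out$P
  out$ai_mod <- ifelse(ai_num < 0 | ai_den <= 0, 0, ai_num / ai_den)
  if ("mass" %in% names(out)) {
    out$kendrick_mass <- out$mass * 14 / 14.01565
    nominal <- if (kendrick == "round") round(out$kendrick_mass) else floor(out$kendrick_mass)
    out$kendrick_defect <- nominal - out$kendrick_mass
  } else {
    inform("no `mass` column: Kendrick mass and defect left undefined")
    out$kendrick_mass <- NA_real_
    out$kendrick_defect <- NA_real_
  }
  if (!"elemental_group" %in% names(out)) out$elemental_group <- elemental_group(out)
  out
}

#' Van Krevelen compound-class boundaries
#'
#' Reads a class-boundary table: one row per class with rectangular O/C and
#' H/C limits (`class`, `oc_min`, `oc_max`, `hc_min`, `hc_max`), matched in
#' table order. The packaged default table holds a widely used van Krevelen
#' boundary set; it is configuration, not hard-coded logic, and can be edited
#' or replaced.
#'
#' @param path Path to a boundaries TSV; default is the packaged table.
#' @return A tibble of class boundaries.
#' @export
class_boundaries <- function(path = NULL) {
  path <- path %||% system.file("extdata", "compound_class_boundaries.tsv",
                                package = "bntifeat")
  b <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  need <- c("class", "oc_min", "oc_max", "hc_min", "hc_max")
  if (!all(need %in% names(b))) {
    abort(paste0("boundary table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(b$oc_min > b$oc_max) || any(b$hc_min > b$hc_max)) {
    abort("malformed boundary table: min exceeds max")
  }
  b
}

#' Assign van Krevelen compound classes
#'
#' Each formula is placed in O/C x H/C space and assigned the first class (in
#' boundary-table order) whose rectangle contains it; formulas outside every
#' rectangle are `"Other"`. Points matched by several rectangles (shared
#' edges) take the first class, with a warning naming the classes involved.
#'
#' @param tbl A property table with `oc_ratio` and `hc_ratio` columns (see
#'   [molecular_properties()]).
#' @param boundaries A boundary tibble from [class_boundaries()].
#' @return `tbl` with a `compound_class` column appended.
#' @export
assign_compound_class <- function(tbl, boundaries = class_boundaries()) {
  stopifnot(all(c("oc_ratio", "hc_ratio") %in% names(tbl)))
  hits <- vapply(seq_len(nrow(tbl)), function(i) {
    inside <- which(tbl$oc_ratio[i] >= boundaries$oc_min &
                    tbl$oc_ratio[i] <= boundaries$oc_max &
                    tbl$hc_ratio[i] >= boundaries$hc_min &
                    tbl$hc_ratio[i] <= boundaries$hc_max)
    if (length(inside) > 1) {
      warn(sprintf("formula %d on the boundary of classes %s; taking '%s'",
                   i, paste(boundaries$class[inside], collapse = " / "),
                   boundaries$class[inside[1]]))
    }
    if (length(inside) == 0) "Other" else boundaries$class[inside[1]]
  }, character(1))
  tbl$compound_class <- hits
  tbl
}

#' Build a molecular characteristics dendrogram (MCD)
#'
#' Hierarchically clusters molecular formulas on their derived properties so
#' that the resulting tree can play the role of a phylogeny for organic
#' matter: selected properties are standardised to zero mean / unit variance,
#' pairwise Euclidean distances are computed, and UPGMA (average-linkage)
#' agglomeration produces an ultrametric dendrogram whose cophenetic
#' distances equal the merge heights.
#'
#' @param tbl A property table (see [molecular_properties()]) with a
#'   `feature_id` column.
#' @param properties Property columns to cluster on. The default covers the
#'   element counts plus every derived descriptor; `kendrick_defect` is used
#'   only when defined for all records.
#' @param linkage Only `"upgma"` is provided.
#' @return An ultrametric `phylo` object with formula identifiers as tips.
#' @export
build_mcd <- function(tbl,
                      properties = c("C", "H", "O", "N", "S", "P",
                                     "oc_ratio", "hc_ratio", "dbe",
                                     "ai_mod", "nosc", "kendrick_defect"),
                      linkage = "upgma") {
  linkage <- match.arg(linkage, "upgma")
  stopifnot("feature_id" %in% names(tbl))
  if (nrow(tbl) < 2) abort("need at least 2 formula records to build an MCD")
  if (anyDuplicated(tbl$feature_id)) abort("duplicate feature_id in formula table")
  properties <- intersect(properties, names(tbl))
  m <- as.matrix(tbl[properties])
  keep <- apply(m, 2, function(v) all(is.finite(v)))
  if (any(!keep)) {
    inform(paste0("dropping properties with undefined values: ",
                  paste(properties[!keep], collapse = ", ")))
    m <- m[, keep, drop = FALSE]
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    if (all(sds == 0)) abort("all selected properties are constant")
    warn(paste0("dropping constant properties: ",
                paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  rownames(z) <- tbl$feature_id
  hc <- hclust(dist(z, method = "euclidean"), method = "average")
  validate_tree(ape::as.phylo(hc))
}
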