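#' Community tables
#'
#' A community table is a tibble with one row per sample: a `sample` identifier
#' column followed by one numeric column per feature (an ASV, a molecular
#' formula, ...). The abundance mode -- `"counts"`, `"relative"`, or
#' `"presence"` -- is carried as an attribute so downstream normalisation knows
#' what it is looking at.
#'
#' @param x A data frame or matrix. For a data frame, either a `sample` column
#'   or row names supply sample identifiers; all remaining columns must be
#'   numeric. For a matrix, rows are samples and row/column names are required.
#' @param mode Abundance mode. If `NULL`, the mode is inferred: all values in
#'   \{0, 1\} gives `"presence"`; all row sums within `1e-9` of 1 gives
#'   `"relative"`; anything else gives `"counts"`. The inference is reported
#'   with a message.
#'
#' @return A `community_tbl`: a tibble with a `sample` column, numeric feature
#'   columns, and a `mode` attribute.
#' @examples
#' ct <- as_community_table(
#'   data.frame(sample = c("S1", "S2"), A = c(5, 0), B = c(3, 7))
#' )
#' ct_mode(ct)
#' @export
as_community_table <- function(x, mode = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs both row (sample) and column (feature) names")
    }
    x <- data.frame(sample = rownames(x), x, check.names = FALSE)
  }
  x <- as.data.frame(x)
  if (!"sample" %in% names(x)) {
    if (is.null(rownames(x)) || identical(rownames(x), as.character(seq_len(nrow(x))))) {
      abort("need a `sample` column or informative row names")
    }
    x <- cbind(sample = rownames(x), x)
  }
  x$sample <- as.character(x$sample)
  feat <- setdiff(names(x), "sample")
  if (length(feat) == 0) abort("community table has no feature columns")
  if (anyDuplicated(x$sample)) abort("duplicate sample identifiers")
  if (anyDuplicated(feat)) abort("duplicate feature identifiers")
  vals <- as.matrix(x[feat])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(x[feat], is.numeric, logical(1)))
    abort(paste0("non-numeric feature column(s): ", paste(feat[bad], collapse = ", ")))
  }
  if (anyNA(vals) || any(!is.finite(vals))) abort("community table values must be finite")
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative abundance at sample '%s', feature '%s'",
                  x$sample[idx[1]], feat[idx[2]]))
  }

  if (is.null(mode)) {
    mode <- infer_mode(vals)
    inform(paste0("abundance mode inferred as '", mode, "'"))
  }
  mode <- match.arg(mode, c("counts", "relative", "presence"))
  validate_mode(vals, mode, x$sample)

  out <- as_tibble(x)
  attr(out, "mode") <- mode
  class(out) <- c("community_tbl", class(out))
  out
}

infer_mode <- function(vals) {
  if (all(vals %in% c(0, 1))) return("presence")
  if (all(abs(rowSums(vals) - 1) <= 1e-9)) return("relative")
  "counts"
}

validate_mode <- function(vals, mode, samples) {
  if (mode == "presence" && !all(vals %in% c(0, 1))) {
    abort("mode 'presence' requires all values in {0, 1}")
  }
  if (mode == "relative") {
    bad <- which(abs(rowSums(vals) - 1) > 1e-9)
    if (length(bad)) {
      abort(sprintf("mode 'relative' requires row sums of 1; offending sample(s): %s",
                    paste(samples[bad], collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Read a community table from delimited text
#'
#' @param path Path to a TSV or CSV file (delimiter sniffed from the first
#'   line; `.csv` extension forces comma).
#' @param mode Optional abundance mode; inferred when `NULL`
#'   (see [as_community_table()]).
#' @param samples_as `"rows"` (default) when samples are rows and features are
#'   columns, `"cols"` for the transposed layout. Orientation is declared, not
#'   guessed: shape-based guessing corrupts square tables.
#' @return A `community_tbl`.
#' @export
read_community_table <- function(path, mode = NULL, samples_as = c("rows", "cols")) {
  samples_as <- match.arg(samples_as)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE) ||
             (!grepl("\t", first) && grepl(",", first))) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) {
    col <- names(df)[which(!num)[1]]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
    abort(sprintf("non-numeric cell at row '%s', column '%s'",
                  rownames(df)[row %||% 1], col))
  }
  m <- as.matrix(df)
  if (samples_as == "cols") m <- t(m)
  as_community_table(m, mode = mode)
}

#' @export
print.community_tbl <- function(x, ...) {
  cat(sprintf("# community table: %d samples x %d features, mode '%s'\n",
              nrow(x), length(ct_features(x)), ct_mode(x)))
  NextMethod()
}

#' Accessors for community tables
#'
#' @param x A `community_tbl`.
#' @return `ct_mode()` the abundance mode; `ct_samples()` / `ct_features()`
#'   identifier vectors; `ct_matrix()` a features x samples numeric matrix
#'   (the orientation the distance-matrix machinery uses).
#' @export
ct_mode <- function(x) attr(x, "mode")

#' @rdname ct_mode
#' @export
ct_samples <- function(x) x$sample

#' @rdname ct_mode
#' @export
ct_features <- function(x) setdiff(names(x), "sample")

#' @rdname ct_mode
#' @export
ct_matrix <- function(x) {
  m <- t(as.matrix(as.data.frame(x)[ct_features(x)]))
  colnames(m) <- x$sample
  m
}

#' Convert a community table to relative abundances
#'
#' Counts are divided by per-sample totals; presence rows by per-sample
#' occupancy; relative tables pass through unchanged. Feature abundance
#' \eqn{f_{ai}} in the feature-level nearest-taxon metric is always taken from
#' the relative-abundance view.
#'
#' @param table A `community_tbl`.
#' @return A `community_tbl` with mode `"relative"`.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "community_tbl"))
  feat <- ct_features(table)
  vals <- as.matrix(as.data.frame(table)[feat])
  tot <- rowSums(vals)
  if (any(tot == 0)) {
    abort(sprintf("all-zero sample(s): %s",
                  paste(table$sample[tot == 0], collapse = ", ")))
  }
  if (ct_mode(table) == "relative") return(table)
  out <- table
  out[feat] <- vals / tot
  attr(out, "mode") <- "relative"
  out
}

#' Align a community table with a distance matrix
#'
#' @param table A `community_tbl`.
#' @param D A labelled cophenetic [distance matrix][cophenetic_matrix].
#' @param prune If `FALSE` (default) the feature sets must match exactly;
#'   if `TRUE` both objects are restricted to the intersection of feature
#'   identifiers, dropped counts are reported, and samples left empty by
#'   pruning are removed with a warning.
#' @return A list with elements `table` and `dist`, features in matching order.
#' @export
harmonize <- function(table, D, prune = FALSE) {
  stopifnot(inherits(table, "community_tbl"), is.matrix(D))
  tf <- ct_features(table)
  df <- rownames(D)
  common <- intersect(tf, df)
  if (length(common) == 0) abort("no features shared between table and distance matrix")
  if (!prune && (length(common) < length(tf) || length(common) < length(df))) {
    abort("feature sets differ; rerun with prune = TRUE to intersect them")
  }
  drop_t <- length(tf) - length(common)
  drop_d <- length(df) - length(common)
  if (drop_t + drop_d > 0) {
    inform(sprintf("harmonize: dropped %d feature(s) from table, %d from distance matrix",
                   drop_t, drop_d))
  }
  tab <- table[c("sample", common)]
  attr(tab, "mode") <- ct_mode(table)
  class(tab) <- class(table)
  vals <- as.matrix(as.data.frame(tab)[common])
  empty <- rowSums(vals) == 0
  if (any(empty)) {
    warn(sprintf("harmonize: removing %d sample(s) left empty by pruning: %s",
                 sum(empty), paste(tab$sample[empty], collapse = ", ")))
    tab <- tab[!empty, ]
    attr(tab, "mode") <- ct_mode(table)
    class(tab) <- class(table)
  }
  list(table = tab, dist = D[common, common, drop = FALSE])
}
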