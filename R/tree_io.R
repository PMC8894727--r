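#' Read and validate a dendrogram or phylogenetic tree
#'
#' Reads a newick file into an [ape::phylo] object and enforces the contract
#' the nearest-taxon machinery relies on: at least two uniquely labelled tips
#' and finite, nonnegative branch lengths. Branch lengths of exactly zero are
#' allowed (polytomy-resolution artifacts); negative lengths are rejected.
#'
#' @param path Path to a newick file.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) abort(paste0("malformed newick in '", path, "': ", conditionMessage(e)))
  )
  if (is.null(tree)) abort(paste0("malformed newick in '", path, "'"))
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree A `phylo` object to validate in place.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) abort("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    abort("all branch lengths must be finite")
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  tree
}

#' Tip-to-tip cophenetic distance matrix
#'
#' Entry (a, b) is the sum of branch lengths on the path between tips a and b
#' -- the relational distance d used by the nearest-taxon metrics. Cophenetic
#' distances are rooting-invariant, so no rooting is imposed.
#'
#' @param tree A validated `phylo` object.
#' @return A symmetric, zero-diagonal numeric matrix with tip labels as
#'   dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  validate_tree(tree)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Shuffle the tip labels of a distance matrix
#'
#' The null model's randomisation: tip labels are permuted uniformly at
#' random, implemented as a joint row/column permutation of the cophenetic
#' matrix (exactly equivalent to relabelling the tips of the tree, without
#' re-traversing it). The multiset of off-diagonal distances is unchanged.
#'
#' @param D A labelled square distance matrix.
#' @param seed Optional integer; when given, fixes the permutation.
#' @return A matrix with the same labels in the same order but permuted
#'   underlying values.
#' @export
shuffle_labels <- function(D, seed = NULL) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), !is.null(rownames(D)))
  n <- nrow(D)
  p <- if (is.null(seed)) sample.int(n) else withr::with_seed(seed, sample.int(n))
  out <- D[p, p, drop = FALSE]
  dimnames(out) <- dimnames(D)
  out
}
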