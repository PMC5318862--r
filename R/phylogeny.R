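#' Read and validate a rooted Newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants all
#' downstream analyses rely on: unique tip labels, non-negative branch
#' lengths (required by default), and a single root. The returned tree
#' carries an `"ultrametric"` attribute computed from root-to-tip path sums
#' (relative tolerance 1e-6), which the grafting code consults.
#'
#' @param file Path to a Newick file. Ignored when `text` is given.
#' @param text Optional Newick string (instead of a file).
#' @param require_lengths If `TRUE` (default), every edge must carry a
#'   branch length; analysis trees need lengths in Myr.
#' @return An [ape::read.tree()] `"phylo"` object with attribute
#'   `"ultrametric"` (logical).
#' @export
read_newick <- function(file = NULL, text = NULL, require_lengths = TRUE) {
  if (is.null(text)) {
    if (is.null(file) || !file.exists(file))
      stop("Newick file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string (unbalanced parentheses or empty tree)")
  validate_phylogeny(tr, require_lengths = require_lengths)
}

#' Validate a phylo object against the package's tree invariants
#'
#' @param tree A `"phylo"` object.
#' @param require_lengths Require branch lengths on every edge.
#' @return The tree, with the `"ultrametric"` attribute set.
#' @export
validate_phylogeny <- function(tree, require_lengths = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (require_lengths) {
    if (is.null(tree$edge.length) ||
        length(tree$edge.length) != nrow(tree$edge) ||
        anyNA(tree$edge.length))
      stop("tree has missing branch lengths but lengths are required")
    if (any(tree$edge.length < 0))
      stop("tree has negative branch lengths")
  }
  attr(tree, "ultrametric") <-
    !is.null(tree$edge.length) && !anyNA(tree$edge.length) &&
    is_ultrametric_tree(tree)
  tree
}

#' Test ultrametricity by root-to-tip path sums
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param rel_tol Relative tolerance on the spread of root-to-tip depths.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, rel_tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (mx - min(d)) <= rel_tol * mx
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured back from the tips (tips have age 0, the root the crown
#' age), in the branch-length unit of the tree (Myr for dated trees).
#'
#' @param tree An ultrametric `"phylo"` object.
#' @return Numeric vector over tips then internal nodes (ape numbering).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Write a tree to Newick
#'
#' @param tree A `"phylo"` object.
#' @param file Output path; with `file = ""` the string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = "") {
  s <- ape::write.tree(tree, digits = 12)
  if (nzchar(file)) {
    writeLines(s, file)
    invisible(s)
  } else s
}
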