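#' Read and validate a rooted Newick tree
#'
#' Parses Newick text (or a file containing it) into an `ape::phylo` object
#' and validates the invariants the downstream analyses rely on: unique,
#' non-empty leaf labels and non-negative branch lengths. Polytomies are
#' preserved, never resolved.
#'
#' @param x Either a Newick string (contains `;`) or the path to a file
#'   holding one.
#' @return A rooted tree of class `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tree_total_length(tr)  # 6
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (grepl(";", x, fixed = TRUE)) x else {
    if (!file.exists(x)) stop("file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: malformed tree text", call. = FALSE)
  # unwrap quoted labels ('sp one') that ape keeps verbatim
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)
  validate_tree(tree)
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths (default 12, so that
#'   read/write round-trips are lossless at double precision for practical
#'   purposes).
#' @export
write_newick <- function(tree, file = NULL, digits = 12L) {
  validate_tree(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Internal: enforce PhyloTree invariants on a phylo object.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label")
  dup <- labs[duplicated(labs)]
  if (length(dup))
    stop("duplicate leaf label: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!is.null(tree$edge.length)) {
    bad <- tree$edge.length < 0
    if (any(bad))
      stop("negative branch length: ", paste(tree$edge.length[bad], collapse = ", "),
           call. = FALSE)
  }
  invisible(tree)
}

#' Sum of all branch lengths
#' @param tree a `phylo` object with branch lengths
#' @return total branch length (sum over all non-root nodes).
#' @export
tree_total_length <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

#' Root-to-tip path lengths
#' @param tree a `phylo` object with branch lengths
#' @return numeric vector of depths, named by tip label.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Test whether a tree is ultrametric
#'
#' A tree is taken as ultrametric (a chronogram) when the maximum and minimum
#' root-to-leaf path lengths differ by at most `rel_tolerance` times the
#' maximum depth. This is a checkable predicate, not an assumed property of
#' any input.
#'
#' @param tree a `phylo` object with branch lengths
#' @param rel_tolerance relative tolerance on depth spread (default `1e-8`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_ultrametric(read_newick("((A:1,B:1):1,C:2);"))   # TRUE
#' is_ultrametric(read_newick("((A:1,B:3):1,C:2);"))   # FALSE
#' @export
is_ultrametric <- function(tree, rel_tolerance = 1e-8) {
  d <- tip_depths(tree)
  if (length(d) < 2L) return(TRUE)
  (max(d) - min(d)) <= rel_tolerance * max(d)
}
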