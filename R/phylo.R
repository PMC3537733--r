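#' Newick input and output
#'
#' `read_newick()` parses a Newick string (or a file containing one) into an
#' \pkg{ape} `phylo` tree; a rooted binary root is collapsed by merging the
#' two root branches so that trees are handled in unrooted form throughout.
#' `write_newick()` serializes a tree back to Newick.
#'
#' @param text Newick string, or a path to a file containing one.
#' @return `read_newick()` returns a `phylo`; `write_newick()` a character
#'   scalar.
#' @export
read_newick <- function(text) {
  txt <- text
  if (length(txt) == 1L && !grepl("(", txt, fixed = TRUE) && file.exists(txt)) {
    txt <- paste(readLines(txt, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick near: ", substr(txt, 1, 60))
  }
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in Newick input")
  if (ape::Ntip(tr) > 2L && ape::is.rooted(tr)) {
    tr <- ape::unroot(tr)
  }
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Neighbor-joining tree from a genetic-distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative estimated branch
#' lengths, which NJ can produce on noisy or non-additive input, are clamped
#' to zero.  Used as the starting topology for maximum-likelihood branch
#' length optimization and optional NNI refinement.
#'
#' @param dm a [distance_matrix()] result, `dist`, or symmetric matrix with
#'   dimnames.
#' @return An unrooted `phylo` with nonnegative branch lengths.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "genetic_dist")) stats::as.dist(dm$values)
       else if (inherits(dm, "dist")) dm
       else stats::as.dist(as.matrix(dm))
  if (attr(d, "Size") < 3L) stop("neighbor joining requires at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson-Foulds distance between two topologies
#'
#' @param tree_a,tree_b `phylo` trees over the same leaf set.
#' @return The (unnormalized) RF bipartition distance.
#' @export
rf_distance <- function(tree_a, tree_b) {
  phangorn::RF.dist(tree_a, tree_b)
}

#' Path-length (patristic) distance matrix of a tree
#'
#' @param tree a `phylo`.
#' @return Symmetric matrix of leaf-to-leaf path lengths.
#' @export
tree_path_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
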