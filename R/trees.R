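#' Read a rooted tree from a newick file
#'
#' @param path newick file.
#' @param require_ultrametric verify that all root-to-tip path lengths agree
#'   within `tolerance` times the tree height.
#' @param tolerance relative tolerance for the ultrametricity check.
#' @param require_rooted error on unrooted input (default).
#' @param require_lengths error when branch lengths are absent or missing.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path, require_ultrametric = FALSE, tolerance = 0.01,
                      require_rooted = TRUE, require_lengths = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path)
  validate_tree(tr, require_ultrametric = require_ultrametric,
                tolerance = tolerance, require_rooted = require_rooted,
                require_lengths = require_lengths)
}

#' Validate a phylo object for downstream delimitation use
#'
#' @inheritParams read_tree
#' @param tree an `ape::phylo` tree.
#' @return the tree, invisibly unchanged, or an error.
#' @export
validate_tree <- function(tree, require_ultrametric = FALSE, tolerance = 0.01,
                          require_rooted = TRUE, require_lengths = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (require_rooted && !ape::is.rooted(tree)) stop("tree must be rooted")
  if (require_lengths) {
    if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
      stop("branch lengths are required but absent or incomplete")
    }
    if (any(tree$edge.length < 0)) stop("negative branch lengths")
  }
  if (require_ultrametric) {
    depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    h <- max(depths)
    if (h <= 0 || diff(range(depths)) > tolerance * h) {
      stop("tree is not ultrametric within relative tolerance ", tolerance,
           " (tip depth range ", signif(diff(range(depths)), 4), ")")
    }
  }
  tree
}

#' Node ages (height above the present)
#'
#' For an ultrametric tree, tip ages are 0 and internal node ages are the
#' branching times.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return numeric vector of ages indexed by ape node number
#'   (tips `1..n`, then internal nodes).
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_along(tree$tip.label)]) - depths
}

#' Prepare a tree for GMYC fitting
#'
#' Resolves polytomies into bifurcations with zero-length branches (using a
#' deterministic resolution order) and verifies ultrametricity.  Rate
#' smoothing of non-ultrametric trees is deliberately out of scope: trees
#' must arrive ultrametric.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tolerance relative ultrametricity tolerance.
#' @return a binary ultrametric `phylo`.
#' @export
prepare_ultrametric <- function(tree, tolerance = 0.01) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    # resolve first: a basal polytomy reads as "unrooted" until bifurcated
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  validate_tree(tree, require_ultrametric = TRUE, tolerance = tolerance)
}
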