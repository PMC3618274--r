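#' Rodrigo's randomly-distinct clade test
#'
#' A clade is "distinct" when it hangs from a long stem relative to its
#' crown depth.  The statistic is
#' `r_obs = (mean path length from the clade node to its tip descendants) /
#' (branch length from the node to its parent)`; small ratios mean more
#' distinct.  The null distribution is built from `n_sim` neutral
#' coalescent trees with the same number of tips as the full tree: ratios
#' of all internal (non-root) clades of the same size are pooled, and the
#' lower-tail p-value is the add-one proportion of null ratios at or below
#' the observed one.  A zero-length stem gives an infinite ratio and
#' `p = 1` (least distinct).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param clade internal node number, or a character vector of tip labels
#'   whose MRCA defines the clade.  Must not be the root.
#' @param n_sim simulated null trees (default 1000).
#' @param seed optional integer seed.
#' @return object of class `prd_result`: list with `node`, `clade_size`,
#'   `r_obs`, `p_value`, `n_sim`, `n_null` (pooled null clades), `seed`.
#' @export
rodrigo_prd <- function(tree, clade, n_sim = 1000, seed = NULL) {
  n_tip <- length(tree$tip.label)
  node <- if (is.character(clade)) {
    ape::getMRCA(tree, .tip_indices(tree, clade))
  } else as.integer(clade)
  root <- n_tip + 1L
  if (node == root) stop("the root has no stem branch")
  if (node <= n_tip) stop("clade must be an internal node")
  obs <- .clade_ratios(tree)
  r_obs <- obs$ratio[obs$node == node]
  size <- obs$size[obs$node == node]
  if (!is.null(seed)) set.seed(seed)
  null_ratios <- unlist(lapply(seq_len(n_sim), function(s) {
    sim <- .clade_ratios(ape::rcoal(n_tip))
    sim$ratio[sim$size == size]
  }))
  p <- (1 + sum(null_ratios <= r_obs)) / (1 + length(null_ratios))
  structure(list(node = node, clade_size = size, r_obs = r_obs,
                 p_value = p, n_sim = n_sim, n_null = length(null_ratios),
                 seed = seed),
            class = "prd_result")
}

#' @export
print.prd_result <- function(x, ...) {
  cat(sprintf("Rodrigo P(RD): clade of %d tips, r = %.4g, p = %.4g (%d null clades)\n",
              x$clade_size, x$r_obs, x$p_value, x$n_null))
  invisible(x)
}

#' @keywords internal
#' crown/stem ratio for every internal non-root node of a tree
.clade_ratios <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  depths <- ape::node.depth.edgelength(tree)
  stem <- numeric(n_tip + tree$Nnode)
  stem[tree$edge[, 2L]] <- tree$edge.length
  desc <- phangorn::Descendants(tree, type = "tips")
  nodes <- setdiff((n_tip + 1L):(n_tip + tree$Nnode), root)
  crown <- vapply(nodes, function(v)
    mean(depths[desc[[v]]] - depths[v]), numeric(1))
  ratio <- ifelse(stem[nodes] > 0, crown / stem[nodes], Inf)
  data.frame(node = nodes, size = lengths(desc[nodes]), ratio = ratio)
}
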