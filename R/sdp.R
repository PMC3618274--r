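#' SDP-style summary statistics for a putative species on a tree
#'
#' Patristic-distance summaries in the style of species-delimitation
#' plugins: `intra` is the mean pairwise patristic distance within the
#' focal group (`NA`, printed `n/c`, for singletons); the closest group is
#' the partner with the smallest mean between-group patristic distance and
#' `inter` is that minimum; `ratio = intra / inter`.  `P ID(Strict)` is the
#' leave-one-out proportion of focal members whose nearest tip (patristic,
#' excluding self) lies inside the focal group -- a tie with an outside tip
#' counts as failure -- with a Wilson 95\% confidence interval.  This
#' operationalises the plugin's diagnosability probability as a
#' nearest-neighbour criterion.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param groups a [group_map] over the tree's tips.
#' @param focal focal group label.
#' @param labels candidate partner labels (default: all terminal groups
#'   other than the focal one).
#' @return object of class `sdp_summary`: list with `group`, `n`,
#'   `closest_group`, `intra`, `inter`, `ratio`, `p_id_strict`, `ci`
#'   (Wilson 95\% bounds).
#' @export
sdp_summary <- function(tree, groups, focal, labels = NULL) {
  pat <- ape::cophenetic.phylo(tree)
  fids <- intersect(group_ids(groups, focal), tree$tip.label)
  if (length(fids) == 0L) stop("focal group '", focal, "' has no tips in the tree")
  if (is.null(labels)) {
    labels <- setdiff(group_labels(groups, terminal_only = TRUE), focal)
  }
  memb <- lapply(stats::setNames(nm = labels), function(l)
    setdiff(intersect(group_ids(groups, l), tree$tip.label), fids))
  memb <- memb[lengths(memb) > 0L]
  if (length(memb) == 0L) stop("no non-empty partner groups")
  intra <- if (length(fids) >= 2L) {
    m <- pat[fids, fids, drop = FALSE]
    mean(m[upper.tri(m)])
  } else NA_real_
  between <- vapply(memb, function(ids)
    mean(pat[fids, ids, drop = FALSE]), numeric(1))
  closest <- names(which.min(between))
  inter <- unname(min(between))
  # leave-one-out nearest-neighbour identification
  others <- setdiff(rownames(pat), character(0))
  hits <- vapply(fids, function(id) {
    d <- pat[id, setdiff(others, id)]
    d_in <- if (length(setdiff(fids, id))) min(d[setdiff(fids, id)]) else Inf
    d_out <- min(d[setdiff(names(d), fids)])
    d_in < d_out
  }, logical(1))
  p_hat <- mean(hits)
  ci <- .wilson_ci(sum(hits), length(hits))
  structure(list(group = focal, n = length(fids), closest_group = closest,
                 intra = intra, inter = inter,
                 ratio = if (is.na(intra)) NA_real_ else intra / inter,
                 p_id_strict = p_hat, ci = ci),
            class = "sdp_summary")
}

#' @export
print.sdp_summary <- function(x, ...) {
  cat(sprintf(
    "SDP summary for %s (n = %d): closest = %s\n  intra = %s, inter = %.4g, ratio = %s\n  P ID(Strict) = %.2f (%.2f, %.2f)\n",
    x$group, x$n, x$closest_group,
    if (is.na(x$intra)) "n/c" else sprintf("%.4g", x$intra), x$inter,
    if (is.na(x$ratio)) "n/c" else sprintf("%.3g", x$ratio),
    x$p_id_strict, x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' @keywords internal
.wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
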