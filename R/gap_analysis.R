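#' @keywords internal
.cross_dists <- function(D, ids1, ids2) {
  v <- as.vector(D$matrix[ids1, ids2, drop = FALSE])
  if (anyNA(v)) {
    warning(sum(is.na(v)), " inapplicable (saturated) distance(s) excluded")
    v <- v[!is.na(v)]
  }
  v
}

#' @keywords internal
.within_dists <- function(D, ids) {
  if (length(ids) < 2L) return(numeric(0))
  m <- D$matrix[ids, ids, drop = FALSE]
  v <- m[upper.tri(m)]
  if (anyNA(v)) {
    warning(sum(is.na(v)), " inapplicable (saturated) distance(s) excluded")
    v <- v[!is.na(v)]
  }
  v
}

#' @keywords internal
.gap_result <- function(focal, scope, intra, inter, blocking_group = NA_character_) {
  stopifnot(length(inter) >= 1L)
  intra_defined <- length(intra) > 0L
  gap_present <- if (intra_defined) min(inter) > max(intra) else TRUE
  delta <- if (intra_defined && gap_present) min(inter) - max(intra) else NA_real_
  structure(list(
    focal = focal, scope = scope,
    intra = intra, inter = inter,
    intra_defined = intra_defined,
    intra_summary = if (intra_defined)
      c(min = min(intra), mean = mean(intra), max = max(intra))
    else c(min = NA_real_, mean = NA_real_, max = NA_real_),
    inter_summary = c(min = min(inter), mean = mean(inter), max = max(inter)),
    gap_present = gap_present, delta = delta,
    blocking_group = blocking_group),
    class = "gap_analysis")
}

#' @export
print.gap_analysis <- function(x, ...) {
  cat("Barcode gap analysis: ", x$focal, " vs ", x$scope, "\n", sep = "")
  if (x$intra_defined) {
    cat(sprintf("  intra: n=%d  %.4f (%.4f-%.4f)\n", length(x$intra),
                x$intra_summary["mean"], x$intra_summary["min"], x$intra_summary["max"]))
  } else cat("  intra: undefined (singleton group)\n")
  cat(sprintf("  inter: n=%d  %.4f (%.4f-%.4f)\n", length(x$inter),
              x$inter_summary["mean"], x$inter_summary["min"], x$inter_summary["max"]))
  cat("  gap present:", x$gap_present,
      if (!is.na(x$delta)) sprintf(" (gap range = %.4f)", x$delta), "\n")
  invisible(x)
}

#' Overall gap analysis (focal group vs all other groups together)
#'
#' Compares the within-group distances of the focal group against its
#' distances to the amalgamation of all other sequences in scope.  A barcode
#' gap is present when the smallest between-group distance exceeds the
#' largest within-group distance; the gap range is their difference.
#' Singleton focal groups have no within-group distances: the result is
#' flagged `intra_defined = FALSE` and the gap decision rests on the
#' between-group distances alone.
#'
#' @param D a [dist_matrix].
#' @param groups a [group_map].
#' @param focal focal group label.
#' @param scope optional label restricting the comparison universe (e.g. a
#'   nominal species containing the focal MOTU); default: all ids in `D`.
#' @return a `gap_analysis` object.
#' @export
overall_gap_analysis <- function(D, groups, focal, scope = NULL) {
  fids <- intersect(group_ids(groups, focal), D$ids)
  uni <- if (is.null(scope)) D$ids else intersect(group_ids(groups, scope), D$ids)
  oids <- setdiff(uni, fids)
  if (length(fids) == 0L) stop("focal group '", focal, "' not in distance matrix")
  if (length(oids) == 0L) stop("no sequences outside '", focal, "' in scope")
  .gap_result(focal, if (is.null(scope)) "all-others" else scope,
              .within_dists(D, fids), .cross_dists(D, fids, oids))
}

#' Pairwise gap analysis (focal group vs one named partner)
#'
#' @inheritParams overall_gap_analysis
#' @param partner the single comparison group.
#' @return a `gap_analysis` object; `blocking_group` is the partner label
#'   when no gap is present.
#' @export
pairwise_gap_analysis <- function(D, groups, focal, partner) {
  if (identical(focal, partner)) stop("focal and partner group must differ")
  fids <- intersect(group_ids(groups, focal), D$ids)
  pids <- intersect(group_ids(groups, partner), D$ids)
  if (length(fids) == 0L || length(pids) == 0L) stop("empty group in distance matrix")
  if (length(intersect(fids, pids))) stop("focal and partner groups share ids")
  res <- .gap_result(focal, partner, .within_dists(D, fids),
                     .cross_dists(D, fids, pids))
  if (!res$gap_present) res$blocking_group <- partner
  res
}

#' Pairwise gap analysis against every partner
#'
#' Runs [pairwise_gap_analysis()] of the focal group against each other
#' label and aggregates: a focal group has an overall PGA gap when every
#' partner comparison shows one; otherwise the partners responsible for the
#' absence are reported as blocking groups.
#'
#' @inheritParams overall_gap_analysis
#' @param labels candidate partner labels (mutually disjoint with the focal
#'   group).
#' @return list with `per_partner` (named list of `gap_analysis`),
#'   `gap_present` and `blocking_groups` (character vector).
#' @export
pga_aggregate <- function(D, groups, focal, labels) {
  labels <- setdiff(labels, focal)
  per <- lapply(stats::setNames(nm = labels), function(l)
    pairwise_gap_analysis(D, groups, focal, l))
  blocking <- names(per)[!vapply(per, `[[`, logical(1), "gap_present")]
  list(per_partner = per, gap_present = length(blocking) == 0L,
       blocking_groups = blocking)
}

#' Apply fixed and fold-change threshold rules to a gap analysis
#'
#' Four published decision rules for single-locus barcodes:
#' * `fixed_3pct`: mean intra < 3\% and min inter >= 3\%;
#' * `fixed_4pct`: the same at the 4\% threshold proposed for
#'   stylommatophoran land snails;
#' * `fold_10x`: mean inter >= 10 x mean intra;
#' * `fold_3.2-4.1x`: mean inter >= 3.2 x mean intra (supported), with a
#'   `strong` flag at >= 4.1 x.
#'
#' The fixed rules compare the *mean* within-group divergence against the
#' threshold (a group may be supported even when its maximum intra exceeds
#' the threshold, provided no between-group distance falls below it).
#' Singleton focal groups cannot be scored: every rule returns `"na"`.
#'
#' @param result a `gap_analysis` object.
#' @return data frame with `rule`, `supported` (`"+"`, `"-"`, `"na"`),
#'   `strong` (only meaningful for the 3.2-4.1x rule), `mean_intra`,
#'   `min_inter`, `mean_inter`, `ratio`.
#' @export
apply_threshold_rules <- function(result) {
  stopifnot(inherits(result, "gap_analysis"))
  mean_intra <- unname(result$intra_summary["mean"])
  min_inter <- unname(result$inter_summary["min"])
  mean_inter <- unname(result$inter_summary["mean"])
  ratio <- if (!result$intra_defined) NA_real_
           else if (mean_intra == 0) Inf else mean_inter / mean_intra
  decide <- function(ok) if (!result$intra_defined) "na" else if (ok) "+" else "-"
  fixed <- function(t) decide(mean_intra < t && min_inter >= t)
  data.frame(
    rule = c("fixed_3pct", "fixed_4pct", "fold_10x", "fold_3.2-4.1x"),
    supported = c(fixed(0.03), fixed(0.04),
                  decide(isTRUE(ratio >= 10)),
                  decide(isTRUE(ratio >= 3.2))),
    strong = c(NA, NA, NA, if (result$intra_defined) isTRUE(ratio >= 4.1) else NA),
    mean_intra = mean_intra, min_inter = min_inter,
    mean_inter = mean_inter, ratio = ratio)
}

#' Threshold rules from bare summary statistics
#'
#' Convenience wrapper for scoring the rules when only the three summary
#' statistics are available (e.g. values transcribed from a publication).
#'
#' @param mean_intra,min_inter,mean_inter summary statistics of the focal
#'   group's distance distributions.
#' @return as [apply_threshold_rules()].
#' @export
threshold_rules_from_stats <- function(mean_intra, min_inter, mean_inter) {
  fake <- .gap_result("focal", "all-others",
                      intra = mean_intra, inter = c(min_inter, mean_inter))
  fake$intra_summary["mean"] <- mean_intra
  fake$inter_summary["min"] <- min_inter
  fake$inter_summary["mean"] <- mean_inter
  apply_threshold_rules(fake)
}

#' Histogram of intra- and inter-group distances
#'
#' Half-open bins `[k*w, (k+1)*w)`; the table is suitable for plotting the
#' classical grey/black barcode-gap frequency plots.
#'
#' @param result a `gap_analysis` object.
#' @param bin_width bin width on the distance scale.
#' @return data frame with `bin_lower`, `bin_upper`, `intra`, `inter`
#'   counts.
#' @export
export_gap_histogram <- function(result, bin_width = 0.01) {
  stopifnot(inherits(result, "gap_analysis"))
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin width must be positive")
  all_d <- c(result$intra, result$inter)
  if (length(all_d) == 0L) stop("no distances to bin")
  nbin <- floor(max(all_d) / bin_width) + 1L
  brk <- (0:nbin) * bin_width
  cnt <- function(v) {
    if (length(v) == 0L) return(integer(nbin))
    tabulate(findInterval(v, brk, rightmost.closed = FALSE), nbins = nbin)
  }
  data.frame(bin_lower = brk[-length(brk)], bin_upper = brk[-1L],
             intra = cnt(result$intra), inter = cnt(result$inter))
}
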