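#' Method-by-hypothesis support matrix
#'
#' Assembles per-method delimitation decisions into one matrix whose rows
#' are hypotheses (MOTU labels, including nested parents and composite
#' aliases) and whose columns are methods.  Cells are `"+"` (supported as a
#' putative species), `"-"` (tested, not supported), `"na"` (the method
#' cannot score this hypothesis, e.g. a singleton under distance rules) or
#' `""` (no decision recorded).
#'
#' @param decisions named list: method name -> named character vector
#'   (hypothesis label -> cell value).
#' @param groups a [group_map] that can resolve every hypothesis label.
#' @return object of class `support_matrix`: list with `cells` (character
#'   matrix hypotheses x methods) and `groups`.
#' @export
support_matrix <- function(decisions, groups) {
  stopifnot(is.list(decisions), length(decisions) >= 1L,
            inherits(groups, "group_map"))
  hyps <- unique(unlist(lapply(decisions, names)))
  if (is.null(hyps)) stop("decision vectors must be named by hypothesis")
  for (h in hyps) group_ids(groups, h)  # fails loudly on unknown labels
  cells <- matrix("", length(hyps), length(decisions),
                  dimnames = list(hyps, names(decisions)))
  for (mth in names(decisions)) {
    v <- decisions[[mth]]
    bad <- setdiff(unique(v), c("+", "-", "na", ""))
    if (length(bad)) stop("invalid cell value(s) for ", mth, ": ",
                          paste(bad, collapse = ", "))
    cells[names(v), mth] <- unname(v)
  }
  structure(list(cells = cells, groups = groups), class = "support_matrix")
}

#' @export
print.support_matrix <- function(x, ...) {
  cat("Support matrix:", nrow(x$cells), "hypotheses x", ncol(x$cells), "methods\n")
  print(as.data.frame(x$cells))
  invisible(x)
}

#' Write a support matrix as TSV
#'
#' @param sm a [support_matrix].
#' @param path output file.
#' @export
write_support_matrix <- function(sm, path) {
  utils::write.table(sm$cells, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Min/max putative-species count for one method over a scope
#'
#' Enumerates every tiling of the scope's id set by pairwise-disjoint,
#' collectively-exhaustive hypotheses and reports the fewest and most
#' species over all tilings.  A hypothesis scored `"+"` counts one species;
#' a hypothesis scored `"na"` may be used to cover ids the method cannot
#' assess (a singleton MOTU, say) but contributes zero to the count;
#' hypotheses scored `"-"` or without a decision cannot be used.  Nesting
#' makes a parent and its children mutually exclusive alternatives, which
#' is what produces ranges such as "7 or 8".
#'
#' @param sm a [support_matrix].
#' @param method method column name.
#' @param scope label of the scope to tile (e.g. a nominal species or the
#'   genus), or a character vector of ids.
#' @return object of class `species_count_range`: list with `scope`,
#'   `min`, `max`, `tilings` (all tilings, each a character vector of
#'   hypothesis labels), `counts` (species count of each tiling).
#' @export
count_species_range <- function(sm, method, scope) {
  stopifnot(inherits(sm, "support_matrix"))
  if (!method %in% colnames(sm$cells)) stop("unknown method column: ", method)
  scope_ids <- if (length(scope) == 1L) group_ids(sm$groups, scope) else sort(scope)
  cells <- sm$cells[, method]
  usable <- names(cells)[cells %in% c("+", "na")]
  hyp_ids <- lapply(stats::setNames(nm = usable), function(h)
    group_ids(sm$groups, h))
  hyp_ids <- hyp_ids[vapply(hyp_ids, function(ids)
    all(ids %in% scope_ids), logical(1))]
  counts_unit <- ifelse(cells[names(hyp_ids)] == "+", 1L, 0L)
  if (!any(counts_unit == 1L)) {
    stop("method '", method, "' supports no hypothesis inside the scope; ",
         "nothing to count")
  }
  tilings <- list()
  recurse <- function(uncovered, used) {
    if (length(uncovered) == 0L) {
      tilings[[length(tilings) + 1L]] <<- used
      return(invisible())
    }
    target <- uncovered[1L]
    for (h in names(hyp_ids)) {
      ids <- hyp_ids[[h]]
      if (target %in% ids && all(ids %in% uncovered)) {
        recurse(setdiff(uncovered, ids), c(used, h))
      }
    }
  }
  recurse(sort(scope_ids), character(0))
  if (length(tilings) == 0L) {
    stop("no valid tiling of scope under method '", method,
         "'; uncovered ids include: ", paste(utils::head(scope_ids, 5), collapse = ", "))
  }
  counts <- vapply(tilings, function(t) sum(counts_unit[t]), integer(1))
  structure(list(scope = if (length(scope) == 1L) scope else "(id set)",
                 method = method,
                 min = min(counts), max = max(counts),
                 tilings = tilings, counts = counts),
            class = "species_count_range")
}

#' @export
print.species_count_range <- function(x, ...) {
  cat(sprintf("Putative species within %s by %s: %s\n", x$scope, x$method,
              if (x$min == x$max) x$min else paste(x$min, "or", x$max)))
  invisible(x)
}

#' Map ensemble results onto support-matrix cells
#'
#' Convenience converters from upstream result objects to the named
#' decision vectors consumed by [support_matrix()].
#'
#' @param gap_results named list of `gap_analysis` objects (one per
#'   hypothesis label); singleton groups yield `"na"`.
#' @return named character decision vector.
#' @export
decisions_from_gap <- function(gap_results) {
  vapply(gap_results, function(r) {
    if (!r$intra_defined) "na" else if (r$gap_present) "+" else "-"
  }, character(1))
}

#' @rdname decisions_from_gap
#' @param gap_results named list of `gap_analysis` objects.
#' @param rule one of the rule names of [apply_threshold_rules()].
#' @export
decisions_from_threshold_rule <- function(gap_results, rule) {
  vapply(gap_results, function(r) {
    tab <- apply_threshold_rules(r)
    tab$supported[tab$rule == rule]
  }, character(1))
}

#' @rdname decisions_from_gap
#' @param partition list of id sets (an ABGD partition for one prior, or
#'   GMYC entities).
#' @param groups a [group_map].
#' @param labels hypothesis labels to score: `"+"` when the hypothesis' id
#'   set is exactly one of the partition's groups, else `"-"`.
#' @export
decisions_from_partition <- function(partition, groups, labels) {
  keys <- vapply(partition, function(ids) paste(sort(ids), collapse = "\r"),
                 character(1))
  vapply(stats::setNames(nm = labels), function(l) {
    if (paste(group_ids(groups, l), collapse = "\r") %in% keys) "+" else "-"
  }, character(1))
}
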