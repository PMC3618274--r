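#' Group map: assignment of ids to delimitation hypotheses
#'
#' A group map assigns every id to exactly one terminal-level group and,
#' optionally, declares nesting among hypothesis labels (a parent label is
#' the union of its children) and composite aliases (a label defined as the
#' union of arbitrary other labels, e.g. a clade that absorbs two haplotypes
#' from a neighbouring group).
#'
#' @param assignments named character vector (names = ids, values = terminal
#'   group labels) or a two-column data frame (`id`, `group`).
#' @param nesting optional two-column data frame (`parent`, `child`); a child
#'   may itself be a parent.  Children of one parent must resolve to disjoint
#'   id sets.
#' @param aliases optional named list: alias label -> character vector of
#'   component labels (components may overlap other hypotheses; aliases are
#'   alternatives, not partitions).
#' @return an object of class `group_map`.
#' @export
group_map <- function(assignments, nesting = NULL, aliases = NULL) {
  if (is.data.frame(assignments)) {
    assignments <- stats::setNames(as.character(assignments[[2L]]),
                                   as.character(assignments[[1L]]))
  }
  ids <- names(assignments)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("assignments must map each id to exactly one terminal label")
  }
  if (!is.null(nesting)) {
    nesting <- data.frame(parent = as.character(nesting[[1L]]),
                          child = as.character(nesting[[2L]]))
  }
  gm <- structure(list(assignments = assignments, nesting = nesting,
                       aliases = aliases),
                  class = "group_map")
  # validate nesting: children of a parent disjoint
  if (!is.null(nesting)) {
    for (p in unique(nesting$parent)) {
      kids <- nesting$child[nesting$parent == p]
      sets <- lapply(kids, function(k) group_ids(gm, k))
      all_ids <- unlist(sets)
      if (anyDuplicated(all_ids)) {
        stop("children of '", p, "' overlap: ",
             paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
      }
    }
  }
  gm
}

#' @export
print.group_map <- function(x, ...) {
  cat("Group map: ", length(x$assignments), " ids, ",
      length(unique(x$assignments)), " terminal groups",
      if (!is.null(x$nesting)) paste0(", ", length(unique(x$nesting$parent)),
                                      " nested parents"), "\n", sep = "")
  invisible(x)
}

#' Resolve a hypothesis label to its id set
#'
#' @param gm a [group_map].
#' @param label terminal, parent or alias label.
#' @return character vector of ids.
#' @export
group_ids <- function(gm, label) {
  stopifnot(inherits(gm, "group_map"), length(label) == 1L)
  resolve <- function(lab, seen = character(0)) {
    if (lab %in% seen) stop("cyclic nesting at '", lab, "'")
    seen <- c(seen, lab)
    out <- names(gm$assignments)[gm$assignments == lab]
    if (!is.null(gm$nesting) && lab %in% gm$nesting$parent) {
      kids <- gm$nesting$child[gm$nesting$parent == lab]
      out <- c(out, unlist(lapply(kids, resolve, seen = seen)))
    }
    if (!is.null(gm$aliases) && lab %in% names(gm$aliases)) {
      out <- c(out, unlist(lapply(gm$aliases[[lab]], resolve, seen = seen)))
    }
    unique(out)
  }
  ids <- resolve(label)
  if (length(ids) == 0L) stop("unknown group label: '", label, "'")
  sort(ids)
}

#' All labels known to a group map
#'
#' @param gm a [group_map].
#' @param terminal_only if `TRUE`, only terminal-level labels.
#' @return character vector of labels.
#' @export
group_labels <- function(gm, terminal_only = FALSE) {
  labs <- unique(unname(gm$assignments))
  if (!terminal_only) {
    labs <- unique(c(labs,
                     if (!is.null(gm$nesting)) gm$nesting$parent,
                     names(gm$aliases)))
  }
  labs
}

#' Terminal group of each id
#'
#' @param gm a [group_map].
#' @param ids ids to look up (default: all).
#' @return named character vector id -> terminal label.
#' @export
group_of <- function(gm, ids = names(gm$assignments)) {
  miss <- setdiff(ids, names(gm$assignments))
  if (length(miss)) stop("ids without group assignment: ", paste(miss, collapse = ", "))
  gm$assignments[ids]
}

#' Read a group map from TSV files
#'
#' @param path two-column TSV (`id`, `group`), with header.
#' @param nesting_path optional two-column TSV (`parent`, `child`).
#' @return a [group_map].
#' @export
read_group_map <- function(path, nesting_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  nest <- if (!is.null(nesting_path)) {
    utils::read.delim(nesting_path, header = TRUE, colClasses = "character")
  }
  group_map(df, nesting = nest)
}
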