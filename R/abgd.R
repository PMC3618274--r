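#' ABGD configuration
#'
#' Defaults follow the method's canonical settings: prior intraspecific
#' divergence screened over a log-spaced series from `p_min` to `p_max`
#' (inclusive), relative gap width `X`, and the number of histogram bins
#' used for diagnostics.  The relative gap width defaults to 1.5, the
#' reference implementation's default; values around 15 make the gap
#' criterion unsatisfiable at typical COI divergence scales and are only
#' useful to demonstrate that no partition is returned (see the methods
#' vignette).
#'
#' @param p_min,p_max prior minimum / maximum intraspecific divergence.
#' @param steps number of priors in the log-spaced series (>= 2).
#' @param X relative gap width.
#' @param n_bins histogram bins for diagnostic output.
#' @return an `abgd_config` list.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, steps = 10, X = 1.5,
                        n_bins = 20) {
  stopifnot(p_min > 0, p_max > p_min, steps >= 2, X > 0, n_bins >= 1)
  structure(list(p_min = p_min, p_max = p_max, steps = steps, X = X,
                 n_bins = n_bins),
            class = "abgd_config")
}

#' Prior series of an ABGD configuration
#'
#' @param config an [abgd_config].
#' @return log-spaced priors from `p_min` to `p_max`, inclusive.
#' @export
abgd_priors <- function(config) {
  exp(seq(log(config$p_min), log(config$p_max), length.out = config$steps))
}

#' Detect a barcode gap in a sorted distance list
#'
#' Scans the sorted pairwise distances for the first position whose jump to
#' the next distance exceeds `X` times the local divergence scale
#' `theta_i = max(P, mean(d[1..i]))`.  Candidate positions require the
#' upper distance to be at least the prior `P` (distances wholly below the
#' prior are screened as intraspecific).  Returns the midpoint of the gap
#' interval, or `NULL` when no gap qualifies.
#'
#' @param distances numeric vector of pairwise distances (any order).
#' @param P prior maximum intraspecific divergence.
#' @param X relative gap width.
#' @return gap distance (midpoint), with attributes `lower` and `upper`,
#'   or `NULL`.
#' @export
detect_barcode_gap <- function(distances, P, X) {
  d <- sort(distances)
  if (length(d) < 2L) stop("need at least two distances")
  w <- diff(d)
  theta <- pmax(P, cumsum(d)[-length(d)] / seq_len(length(d) - 1L))
  ok <- d[-1L] >= P & w > X * theta
  if (!any(ok)) return(NULL)
  i <- which(ok)[1L]
  structure((d[i] + d[i + 1L]) / 2, lower = d[i], upper = d[i + 1L])
}

#' @keywords internal
#' single-linkage components of the graph linking pairs closer than `thr`
.link_components <- function(m, thr) {
  ids <- sort(rownames(m))
  m <- m[ids, ids, drop = FALSE]
  n <- length(ids)
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(is.na(comp) & !is.na(m[v, ]) & m[v, ] < thr)
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  unname(split(ids, comp))
}

#' Automatic barcode gap discovery with recursive partitioning
#'
#' For each prior in the log-spaced series, detects the barcode gap in the
#' ranked pairwise-distance distribution ([detect_barcode_gap()]), forms
#' the primary partition as connected components of the graph linking
#' pairs closer than the gap (single linkage), and then recursively
#' re-applies gap detection within each component until no further gap is
#' found.  Ids are processed in sorted order, so results are deterministic.
#'
#' @param D a [dist_matrix] (K2P by convention).
#' @param config an [abgd_config].
#' @return object of class `abgd_result`: list with one element per prior,
#'   each holding `prior`, `gap` (or `NULL`), `primary` (list of id sets),
#'   `recursive`, `n_primary`, `n_recursive`.
#' @export
abgd_partition <- function(D, config = abgd_config()) {
  stopifnot(inherits(D, "dist_matrix"))
  m <- D$matrix
  if (anyNA(m)) stop("distance matrix contains inapplicable entries")
  ids <- sort(D$ids)
  m <- m[ids, ids]
  partition_at <- function(sub_ids, P) {
    # a lone pairwise distance carries no distribution to find a gap in
    if (length(sub_ids) < 3L) return(list(sub_ids))
    sm <- m[sub_ids, sub_ids, drop = FALSE]
    d <- sm[upper.tri(sm)]
    gap <- detect_barcode_gap(d, P, config$X)
    if (is.null(gap)) return(list(sub_ids))
    .link_components(sm, as.numeric(gap))
  }
  recurse <- function(sub_ids, P) {
    parts <- partition_at(sub_ids, P)
    if (length(parts) == 1L) return(parts)
    do.call(c, lapply(parts, recurse, P = P))
  }
  res <- lapply(abgd_priors(config), function(P) {
    d <- m[upper.tri(m)]
    gap <- detect_barcode_gap(d, P, config$X)
    primary <- if (is.null(gap)) list(ids) else .link_components(m, as.numeric(gap))
    recursive <- do.call(c, lapply(primary, recurse, P = P))
    list(prior = P, gap = gap, primary = primary, recursive = recursive,
         n_primary = length(primary), n_recursive = length(recursive))
  })
  structure(list(per_prior = res, config = config), class = "abgd_result")
}

#' @export
print.abgd_result <- function(x, ...) {
  cat("ABGD partitions (X =", x$config$X, ")\n")
  for (r in x$per_prior) {
    cat(sprintf("  prior %.4g: primary %d group(s), recursive %d group(s)%s\n",
                r$prior, r$n_primary, r$n_recursive,
                if (is.null(r$gap)) " [no gap]" else
                  sprintf(" [gap at %.4f]", as.numeric(r$gap))))
  }
  invisible(x)
}

#' Stable primary partition across the prior series
#'
#' ABGD output is customarily summarised by the partition that stays stable
#' over the range of priors.  This returns the modal primary group count
#' across the prior series together with one representative partition and
#' the priors at which it was found.  Very small priors typically
#' over-split and priors near the gap scale may detect no gap at all; the
#' mode ignores both extremes.
#'
#' @param result an `abgd_result`.
#' @param recursive summarise the recursive (rather than primary)
#'   partitions.
#' @return list with `n_groups` (modal count), `partition`
#'   (representative), `priors` (priors achieving the modal count).
#' @export
abgd_stable_count <- function(result, recursive = FALSE) {
  counts <- vapply(result$per_prior, `[[`,
                   numeric(1), if (recursive) "n_recursive" else "n_primary")
  tab <- table(counts)
  mode_n <- as.integer(names(tab)[which.max(tab)])
  at <- which(counts == mode_n)
  list(n_groups = mode_n,
       partition = result$per_prior[[at[1L]]][[if (recursive) "recursive" else "primary"]],
       priors = vapply(result$per_prior[at], `[[`, numeric(1), "prior"))
}

#' Group membership table for one ABGD prior
#'
#' @param result an `abgd_result`.
#' @param prior_index index into the prior series.
#' @param recursive use the recursive (rather than primary) partition.
#' @return data frame with `id` and `group`.
#' @export
abgd_membership <- function(result, prior_index = 1L, recursive = FALSE) {
  r <- result$per_prior[[prior_index]]
  parts <- if (recursive) r$recursive else r$primary
  data.frame(id = unlist(parts),
             group = rep(sprintf("G%02d", seq_along(parts)), lengths(parts)))
}
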