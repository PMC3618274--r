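#' @keywords internal
.comparable <- function(chars) chars %in% c("A", "C", "G", "T")

#' @keywords internal
.purine <- function(chars) chars %in% c("A", "G")

#' Kimura 2-parameter distance between two aligned rows
#'
#' With `P` the proportion of transition differences and `Q` the proportion
#' of transversion differences over comparable sites (both rows in
#' `A,C,G,T`), `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.  Pairs for
#' which a logarithm argument is non-positive are saturated: `NA` is
#' returned (flagged, never clamped).
#'
#' @param a,b aligned sequences (strings or character vectors) of equal
#'   length.
#' @return the distance, with attributes `P`, `Q` and `sites` (number of
#'   comparable sites).
#' @export
k2p_distance <- function(a, b) {
  pq <- .pair_pq(a, b)
  arg1 <- 1 - 2 * pq$P - pq$Q
  arg2 <- 1 - 2 * pq$Q
  d <- if (arg1 <= 0 || arg2 <= 0) NA_real_ else -0.5 * log(arg1) - 0.25 * log(arg2) + 0
  structure(d, P = pq$P, Q = pq$Q, sites = pq$sites)
}

#' Uncorrected p-distance between two aligned rows
#'
#' Proportion of differing comparable sites.
#'
#' @inheritParams k2p_distance
#' @return the distance, with attribute `sites`.
#' @export
p_distance <- function(a, b) {
  pq <- .pair_pq(a, b)
  structure(pq$P + pq$Q, sites = pq$sites)
}

#' @keywords internal
.pair_pq <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences differ in length")
  comp <- .comparable(a) & .comparable(b)
  n <- sum(comp)
  if (n == 0L) stop("no comparable sites between the two sequences")
  diff <- comp & a != b
  ts <- diff & (.purine(a) == .purine(b))
  list(P = sum(ts) / n, Q = (sum(diff) - sum(ts)) / n, sites = n)
}

#' Pairwise distance matrix for an aligned locus
#'
#' Computes all pairwise p- or K2P distances.  Under `"complete"` deletion
#' a single global set of columns (comparable in every sequence) is used;
#' under `"pairwise"` deletion each pair uses all sites comparable for that
#' pair.  Saturated K2P pairs are `NA` and a warning reports how many.
#'
#' @param locus an [aligned_locus].
#' @param model `"K2P"` or `"p"`.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return an object of class `dist_matrix`: list with `ids`, symmetric
#'   `matrix` (zero diagonal), `P` and `Q` matrices (transition and
#'   transversion proportions), `sites` matrix, `model`, `deletion`.
#' @export
dist_matrix <- function(locus, model = c("K2P", "p"),
                        deletion = c("pairwise", "complete")) {
  stopifnot(inherits(locus, "aligned_locus"))
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- seq_matrix(locus)
  comp <- matrix(.comparable(m), nrow = nrow(m))
  if (deletion == "complete") {
    keep <- colSums(comp) == nrow(m)
    if (!any(keep)) stop("complete deletion leaves no comparable sites")
    m <- m[, keep, drop = FALSE]
    comp <- comp[, keep, drop = FALSE]
  }
  n <- nrow(m)
  pur <- matrix(.purine(m), nrow = n)
  D <- P <- Q <- S <- matrix(0, n, n, dimnames = list(locus$ids, locus$ids))
  for (i in seq_len(max(n - 1L, 0L))) for (j in (i + 1L):n) {
    cc <- comp[i, ] & comp[j, ]
    ns <- sum(cc)
    if (ns == 0L) stop("no comparable sites for pair ", locus$ids[i], " / ", locus$ids[j])
    df <- cc & m[i, ] != m[j, ]
    ts <- sum(df & pur[i, ] == pur[j, ])
    p <- ts / ns
    q <- (sum(df) - ts) / ns
    P[i, j] <- P[j, i] <- p
    Q[i, j] <- Q[j, i] <- q
    S[i, j] <- S[j, i] <- ns
    D[i, j] <- D[j, i] <- if (model == "p") p + q else {
      a1 <- 1 - 2 * p - q; a2 <- 1 - 2 * q
      if (a1 <= 0 || a2 <= 0) NA_real_ else -0.5 * log(a1) - 0.25 * log(a2) + 0
    }
  }
  nsat <- sum(is.na(D[upper.tri(D)]))
  if (nsat > 0L) warning(nsat, " saturated K2P pair(s) flagged NA")
  structure(list(ids = locus$ids, matrix = D, P = P, Q = Q, sites = S,
                 model = model, deletion = deletion),
            class = "dist_matrix")
}

#' Construct a dist_matrix from a plain matrix
#'
#' Used when distances come from an external source (e.g. a TSV export).
#'
#' @param m symmetric numeric matrix with id dimnames, zero diagonal.
#' @param model,deletion provenance labels.
#' @return a `dist_matrix`.
#' @export
as_dist_matrix <- function(m, model = "K2P", deletion = "pairwise") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12) stop("matrix is not symmetric")
  if (any(diag(m) != 0)) stop("diagonal must be zero")
  structure(list(ids = rownames(m), matrix = m, P = NULL, Q = NULL,
                 sites = NULL, model = model, deletion = deletion),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Pairwise ", x$model, " distances (", x$deletion, " deletion): ",
      length(x$ids), " sequences\n", sep = "")
  invisible(x)
}

#' Write a distance matrix as TSV or square PHYLIP
#'
#' @param D a `dist_matrix`.
#' @param path output file.
#' @param format `"tsv"` or `"phylip"`.
#' @export
write_dist_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(D$matrix, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(D$ids)), con)
    for (i in seq_along(D$ids)) {
      writeLines(paste(formatC(D$ids[i], width = -10),
                       paste(sprintf("%.6f", D$matrix[i, ]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Within- and between-group distance summaries with bootstrap SEs
#'
#' Means of pairwise distances within each group (diagonal) and between each
#' group pair, with standard errors from a bootstrap over alignment sites
#' (distances recomputed on resampled columns).  Groups with a single member
#' have no within-group distance: reported as `NA` (printed `n/c`).
#'
#' @param locus an [aligned_locus].
#' @param groups a [group_map] covering the locus ids.
#' @param labels group labels to summarise (default: all terminal groups).
#' @param model,deletion as in [dist_matrix()].
#' @param n_boot bootstrap replicates for the SEs (default 500).
#' @param seed optional integer seed for the bootstrap.
#' @return object of class `group_distance_summary`: list with `within`
#'   (data frame: group, n, mean, se) and `between` (data frame: group1,
#'   group2, mean, se).
#' @export
group_distance_summary <- function(locus, groups, labels = NULL,
                                   model = c("p", "K2P"),
                                   deletion = c("pairwise", "complete"),
                                   n_boot = 500, seed = NULL) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (is.null(labels)) labels <- group_labels(groups, terminal_only = TRUE)
  memb <- lapply(stats::setNames(nm = labels), function(l)
    intersect(group_ids(groups, l), locus$ids))
  if (any(lengths(memb) == 0L)) {
    stop("group(s) with no members in the alignment: ",
         paste(labels[lengths(memb) == 0L], collapse = ", "))
  }
  m <- seq_matrix(locus)
  comp <- matrix(.comparable(m), nrow = nrow(m),
                 dimnames = dimnames(m))
  if (deletion == "complete") {
    keep <- colSums(comp) == nrow(m)
    if (!any(keep)) stop("complete deletion leaves no comparable sites")
    m <- m[, keep, drop = FALSE]
    comp <- comp[, keep, drop = FALSE]
  }
  L <- ncol(m)
  pur <- matrix(.purine(m), nrow = nrow(m), dimnames = dimnames(m))
  ids <- locus$ids
  pairs <- utils::combn(ids, 2L)
  np <- ncol(pairs)
  # per-column indicator matrices for every pair: comparable, transition,
  # transversion -- so bootstrap replicates are one matrix product each
  Cc <- Ts <- Tv <- matrix(0, np, L)
  for (k in seq_len(np)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cc <- comp[i, ] & comp[j, ]
    df <- cc & m[i, ] != m[j, ]
    ts <- df & pur[i, ] == pur[j, ]
    Cc[k, ] <- cc
    Ts[k, ] <- ts
    Tv[k, ] <- df & !ts
  }
  pair_dist <- function(w) {
    den <- Cc %*% w
    Pm <- (Ts %*% w) / den
    Qm <- (Tv %*% w) / den
    if (model == "p") Pm + Qm else {
      a1 <- 1 - 2 * Pm - Qm; a2 <- 1 - 2 * Qm
      ifelse(a1 > 0 & a2 > 0, -0.5 * log(a1) - 0.25 * log(a2) + 0, NA_real_)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  W <- cbind(rep(1, L),
             stats::rmultinom(n_boot, L, rep(1 / L, L)))
  DD <- pair_dist(W)  # np x (1 + n_boot); column 1 = observed
  pair_key <- paste(pmin(pairs[1L, ], pairs[2L, ]), pmax(pairs[1L, ], pairs[2L, ]))
  sel_mean <- function(id1, id2) {
    # mean distance over all pairs with one end in id1, other in id2
    if (identical(id1, id2)) {
      if (length(id1) < 2L) return(NULL)
      want <- utils::combn(id1, 2L)
    } else {
      want <- rbind(rep(id1, each = length(id2)), rep(id2, length(id1)))
    }
    keys <- paste(pmin(want[1L, ], want[2L, ]), pmax(want[1L, ], want[2L, ]))
    colMeans(DD[match(keys, pair_key), , drop = FALSE], na.rm = TRUE)
  }
  within <- do.call(rbind, lapply(labels, function(l) {
    v <- sel_mean(memb[[l]], memb[[l]])
    data.frame(group = l, n = length(memb[[l]]),
               mean = if (is.null(v)) NA_real_ else v[1L],
               se = if (is.null(v)) NA_real_ else stats::sd(v[-1L]))
  }))
  between <- if (length(labels) >= 2L) {
    pr <- utils::combn(labels, 2L)
    do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
      v <- sel_mean(memb[[pr[1L, k]]], memb[[pr[2L, k]]])
      data.frame(group1 = pr[1L, k], group2 = pr[2L, k],
                 mean = v[1L], se = stats::sd(v[-1L]))
    }))
  } else {
    data.frame(group1 = character(0), group2 = character(0),
               mean = numeric(0), se = numeric(0))
  }
  structure(list(within = within, between = between, model = model,
                 deletion = deletion, n_boot = n_boot),
            class = "group_distance_summary")
}

#' @export
print.group_distance_summary <- function(x, ...) {
  cat("Group ", x$model, "-distance summary (", x$n_boot,
      " site-bootstrap replicates)\nWithin groups:\n", sep = "")
  w <- x$within
  w$mean <- ifelse(is.na(w$mean), "n/c", sprintf("%.3f", w$mean))
  w$se <- ifelse(is.na(w$se), "", sprintf("%.3f", w$se))
  print(w, row.names = FALSE)
  cat("Between groups:\n")
  print(transform(x$between, mean = sprintf("%.3f", mean),
                  se = sprintf("%.3f", se)), row.names = FALSE)
  invisible(x)
}
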