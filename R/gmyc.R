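#' @keywords internal
#' Interval bookkeeping for GMYC likelihoods.
#'
#' Orders the n-1 branching times from root to present, breaks exact ties
#' (zero-length branches from resolved polytomies) with a deterministic
#' epsilon of 1e-8 x tree height applied parent-first, and records which
#' branch crosses which inter-event interval.  Each non-root event is
#' associated with the interval on its younger side, so the rate of a
#' coalescence is evaluated while its daughter lineages coexist, and the
#' deepest coalescence of a cluster sees a positive rate.  The root event
#' is conditioned out: n-2 waiting times enter the likelihood.
.gmyc_data <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 3L) stop("need at least three tips")
  if (!ape::is.binary(tree)) stop("tree must be binary; see prepare_ultrametric()")
  tree <- stats::reorder(tree, "cladewise")   # parents precede children
  m <- tree$Nnode
  ages <- node_ages(tree)
  ages[seq_len(n)] <- 0
  height <- max(ages)
  eps <- 1e-8 * height
  int_nodes <- (n + 1L):(n + m)
  # topological depth, to put parents before children inside tied age blocks
  parent <- integer(n + m)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  depth <- integer(n + m)
  for (r in seq_len(nrow(tree$edge))) {
    depth[tree$edge[r, 2L]] <- depth[tree$edge[r, 1L]] + 1L
  }
  ord <- int_nodes[order(-ages[int_nodes], depth[int_nodes])]
  t_sorted <- ages[ord]
  for (k in seq_along(t_sorted)[-1L]) {
    if (t_sorted[k] >= t_sorted[k - 1L] - eps) {
      t_sorted[k] <- t_sorted[k - 1L] - eps
    }
  }
  if (t_sorted[m] <= 0) stop("tree height too small to separate branching times")
  adj <- ages
  adj[ord] <- t_sorted
  # likelihood intervals: rank k = 2..m, interval (t_{k+1}, t_k), t_{m+1} = 0
  lo <- c(t_sorted[-1L], 0)[-1L]   # length m-1, for ranks 2..m
  hi <- t_sorted[-1L]
  x <- hi - lo
  tol <- eps / 4
  age_p <- adj[tree$edge[, 1L]]
  age_c <- adj[tree$edge[, 2L]]
  cross <- matrix(FALSE, m - 1L, nrow(tree$edge))
  for (k in seq_len(m - 1L)) {
    cross[k, ] <- age_c <= lo[k] + tol & age_p >= hi[k] - tol
  }
  list(tree = tree, n_tip = n, m = m, parent = parent,
       rank_nodes = ord,            # internal nodes by decreasing age
       t_sorted = t_sorted, adj_ages = adj,
       event_nodes = ord[-1L],      # ranks 2..m
       x = x, cross = cross, height = height)
}

#' @keywords internal
#' Maximised mixed Yule-coalescent likelihood for one div/coal labelling.
#'
#' `coal` is a logical over internal nodes (ape numbering), downward-closed
#' (every descendant of a coalescent node is coalescent).  Branches inherit
#' the class of their parent node; maximal coalescent subtrees are the
#' clusters.  Each inter-event interval i contributes
#' `log b_i - b_i x_i` with the total rate
#' `b_i = lambda_div * A_i^p_div + lambda_coal * sum_j (c_ij (c_ij - 1))^p_coal`,
#' so likelihoods of labellings with different class structures are directly
#' comparable (the event times are the data; class membership is not a mark).
#' Rate multipliers and exponents are optimised jointly (log-lambda scale,
#' exponents bounded in [0, 2], multi-start).
.gmyc_fit_classification <- function(gd, coal) {
  tree <- gd$tree
  n <- gd$n_tip
  cluster <- integer(n + gd$m)
  for (v in gd$rank_nodes) {
    if (!coal[v]) next
    p <- gd$parent[v]
    cluster[v] <- if (p != 0L && coal[p]) cluster[p] else v
  }
  edge_coal <- coal[tree$edge[, 1L]]
  edge_cluster <- cluster[tree$edge[, 1L]]
  clusters <- sort(unique(edge_cluster[edge_coal]))
  A <- as.numeric(gd$cross[, !edge_coal, drop = FALSE] %*%
                    rep(1, sum(!edge_coal)))
  C <- matrix(0, nrow(gd$cross), length(clusters))
  for (j in seq_along(clusters)) {
    sel <- edge_coal & edge_cluster == clusters[j]
    C[, j] <- gd$cross[, sel, drop = FALSE] %*% rep(1, sum(sel))
  }
  ev_coal <- coal[gd$event_nodes]
  m_d <- sum(!ev_coal)
  m_c <- sum(ev_coal)
  x <- gd$x
  CC <- C * (C - 1)
  logCC <- log(CC)           # -Inf where a cluster has < 2 lineages
  logA <- log(A)             # -Inf where no diversification lineage crosses
  # exponents are kept strictly positive so exp(p * -Inf) = 0 handles empty
  # classes without branching
  a_of <- function(p_d) exp(p_d * logA)
  s_of <- function(p_c) {
    if (ncol(CC) == 0L) return(numeric(length(x)))
    rowSums(exp(p_c * logCC))
  }
  loglik <- function(log_ld, p_d, log_lc, p_c) {
    b <- exp(log_ld) * a_of(p_d) + exp(log_lc) * s_of(p_c)
    if (any(b <= 0)) return(-Inf)
    sum(log(b) - b * x)
  }
  # data-driven start: per-class event counts over per-class exposure at p = 1
  start_l <- function(p_d, p_c) {
    ld <- if (m_d && any(A > 0)) m_d / sum(x * a_of(p_d)) else 1e-8
    lc <- if (m_c) m_c / sum(x * s_of(p_c)) else 1e-8
    c(log(ld), p_d, log(lc), p_c)
  }
  obj <- function(par) -loglik(par[1L], par[2L], par[3L], par[4L])
  starts <- list(start_l(1, 1), c(0, 1, 0, 1))
  fits <- lapply(starts, function(s)
    suppressWarnings(stats::optim(s, obj, method = "L-BFGS-B",
                                  lower = c(-25, 1e-6, -25, 1e-6),
                                  upper = c(25, 2, 25, 2),
                                  control = list(factr = 1e8))))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  ll <- -best$value
  lam_d <- exp(best$par[1L]); p_d <- best$par[2L]
  lam_c <- exp(best$par[3L]); p_c <- best$par[4L]
  if (m_d == 0L) { lam_d <- 0; p_d <- NA_real_ }
  if (m_c == 0L) { lam_c <- 0; p_c <- NA_real_ }
  # entities: cluster subtrees plus tips whose parent is a diversification node
  roots_j <- clusters
  ent <- lapply(roots_j, function(r)
    tree$tip.label[phangorn::Descendants(tree, r, "tips")[[1L]]])
  singles <- tree$tip.label[!coal[gd$parent[seq_len(n)]]]
  entities <- c(ent, as.list(singles))
  list(logL = ll, lambda_div = lam_d, p_div = p_d,
       lambda_coal = lam_c, p_coal = p_c,
       n_div_events = m_d, n_coal_events = m_c,
       cluster_roots = roots_j, entities = entities,
       n_clusters = length(ent), n_entities = length(entities))
}

#' @keywords internal
.gmyc_result <- function(model, gd, fit, thresholds, null_logL, df) {
  lr <- 2 * (fit$logL - null_logL)
  structure(c(list(model = model, thresholds = thresholds,
                   LR = lr, df = df,
                   p_value = if (!is.null(df)) stats::pchisq(lr, df, lower.tail = FALSE),
                   null_logL = null_logL, n_tip = gd$n_tip),
              fit),
            class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("GMYC fit (", x$model, " model), ", x$n_tip, " tips\n", sep = "")
  cat(sprintf("  logL = %.3f", x$logL))
  if (x$model != "null") {
    cat(sprintf("  (null %.3f; LR = %.2f, df = %d, p = %.3g)",
                x$null_logL, x$LR, x$df, x$p_value))
  }
  cat("\n")
  if (length(x$thresholds)) {
    cat("  threshold age(s):", paste(signif(x$thresholds, 4), collapse = ", "), "\n")
  }
  cat(sprintf("  entities: %d (%d clusters + %d singletons)\n",
              x$n_entities, x$n_clusters, x$n_entities - x$n_clusters))
  invisible(x)
}

#' Null (single-process) branching model
#'
#' All tips are assumed to derive from a single species: one rate block
#' `lambda (n(n-1))^p` governs every inter-event interval.  `lambda`
#' profiles out in closed form; `p` is optimised over `[0, 2]`.
#'
#' @param tree binary ultrametric `phylo` (see [prepare_ultrametric()]).
#' @return a `gmyc_fit` of model `"null"`.
#' @export
fit_gmyc_null <- function(tree) {
  gd <- .gmyc_data(tree)
  coal <- rep(FALSE, gd$n_tip + gd$m)
  coal[(gd$n_tip + 1L):(gd$n_tip + gd$m)] <- TRUE
  fit <- .gmyc_fit_classification(gd, coal)
  .gmyc_result("null", gd, fit, numeric(0), fit$logL, NULL)
}

#' Single-threshold GMYC model
#'
#' Fits the general mixed Yule-coalescent model: nodes older than a
#' threshold age T belong to the between-species (diversification) process
#' with rate `lambda_div * n_div^p_div`; each subtree crossing T is a
#' within-species coalescent with shared rate block
#' `lambda_coal * (n_j (n_j - 1))^p_coal`.  T is profiled over the observed
#' node ages (including the configuration with no transition, so the null
#' is nested and the likelihood-ratio statistic is non-negative).  The LR
#' test against the null uses `df = 3` by default.
#'
#' @param tree binary ultrametric `phylo`.
#' @param df degrees of freedom for the chi-square LR test (default 3).
#' @return a `gmyc_fit` of model `"single"` carrying the threshold age,
#'   parameter estimates, LR test and the entity decomposition (clusters
#'   plus singletons).
#' @export
fit_gmyc_single <- function(tree, df = 3) {
  gd <- .gmyc_data(tree)
  null_fit <- NULL
  best <- NULL
  best_k <- NA_integer_
  coal <- rep(FALSE, gd$n_tip + gd$m)
  for (k in seq_len(gd$m)) {
    coal_k <- coal
    coal_k[gd$rank_nodes[k:gd$m]] <- TRUE
    fit <- .gmyc_fit_classification(gd, coal_k)
    if (k == 1L) null_fit <- fit  # all-coalescent = single-process null
    if (is.null(best) || fit$logL > best$logL) { best <- fit; best_k <- k }
  }
  thr <- if (best_k == 1L) numeric(0) else gd$t_sorted[best_k]
  .gmyc_result("single", gd, best, thr, null_fit$logL, df)
}

#' Multiple-threshold GMYC model
#'
#' Greedy forward refinement of the best single-threshold fit: at each step
#' every move that splits one existing cluster at a younger node age inside
#' it is scored (re-fitting the shared rate blocks), the move with the best
#' AIC is accepted, and the search stops when AIC no longer improves or
#' `max_thresholds` is reached.  Different clades may therefore transition
#' from speciation to coalescent branching at different ages.
#'
#' @param tree binary ultrametric `phylo`.
#' @param max_thresholds maximum number of transition ages (default 5).
#' @param df degrees of freedom for the LR test against the null; default
#'   `2 * (number of thresholds)`.
#' @return a `gmyc_fit` of model `"multiple"`.
#' @export
fit_gmyc_multiple <- function(tree, max_thresholds = 5, df = NULL) {
  gd <- .gmyc_data(tree)
  single <- fit_gmyc_single(tree)
  null_logL <- single$null_logL
  coal <- rep(FALSE, gd$n_tip + gd$m)
  if (length(single$thresholds)) {
    k <- match(single$thresholds[1L], gd$t_sorted)
    coal[gd$rank_nodes[k:gd$m]] <- TRUE
  } else {
    coal[(gd$n_tip + 1L):(gd$n_tip + gd$m)] <- TRUE
  }
  current <- .gmyc_fit_classification(gd, coal)
  thresholds <- single$thresholds
  aic <- function(fit, n_thr) 2 * (4 + n_thr) - 2 * fit$logL
  current_aic <- aic(current, length(thresholds))
  repeat {
    if (length(thresholds) >= max_thresholds) break
    best_move <- NULL
    for (r in current$cluster_roots) {
      inner <- setdiff(phangorn::Descendants(gd$tree, r, "all"), seq_len(gd$n_tip))
      if (length(inner) == 0L) next
      for (T2 in sort(unique(gd$adj_ages[inner]), decreasing = TRUE)) {
        coal2 <- coal
        sub <- c(r, phangorn::Descendants(gd$tree, r, "all"))
        sub <- sub[sub > gd$n_tip]
        coal2[sub] <- gd$adj_ages[sub] <= T2 + 1e-12 * gd$height
        fit2 <- .gmyc_fit_classification(gd, coal2)
        a2 <- aic(fit2, length(thresholds) + 1L)
        if (is.null(best_move) || a2 < best_move$aic) {
          best_move <- list(fit = fit2, coal = coal2, aic = a2, T2 = T2)
        }
      }
    }
    if (is.null(best_move) || best_move$aic >= current_aic) break
    current <- best_move$fit
    coal <- best_move$coal
    thresholds <- c(thresholds, best_move$T2)
    current_aic <- best_move$aic
  }
  if (is.null(df)) df <- max(2 * length(thresholds), 1L)
  .gmyc_result("multiple", gd, current, thresholds, null_logL, df)
}

#' Chi-square p-value for a GMYC likelihood-ratio statistic
#'
#' @param lr likelihood ratio `2 (logL_model - logL_null)`.
#' @param df degrees of freedom (3 for the single-threshold model).
#' @return upper-tail chi-square p-value.
#' @export
gmyc_lr_pvalue <- function(lr, df = 3) {
  stats::pchisq(lr, df, lower.tail = FALSE)
}

#' Entities implied by an age threshold
#'
#' Each maximal subtree whose root age lies at or below the threshold forms
#' one entity; entities with two or more tips are clusters, the rest are
#' singletons.  With several thresholds the largest applies (per-clade
#' thresholds live in the `"multiple"` model fit itself).
#'
#' @param tree rooted ultrametric `phylo`.
#' @param thresholds threshold age(s), strictly between 0 and tree height.
#' @return list with `entities` (list of tip-label sets), `n_entities`,
#'   `n_clusters`, `n_singletons`.
#' @export
extract_entities <- function(tree, thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L)
  T <- max(thresholds)
  n <- length(tree$tip.label)
  ages <- node_ages(tree)
  ages[seq_len(n)] <- 0
  tol <- 1e-9 * max(ages)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  coal <- ages <= T + tol
  coal[seq_len(n)] <- FALSE
  roots <- which(coal & (parent == 0L | !coal[pmax(parent, 1L)]))
  ent <- lapply(roots, function(r)
    tree$tip.label[phangorn::Descendants(tree, r, "tips")[[1L]]])
  singles <- tree$tip.label[parent[seq_len(n)] != 0L & !coal[parent[seq_len(n)]]]
  entities <- c(ent, as.list(sort(singles)))
  list(entities = entities, n_entities = length(entities),
       n_clusters = length(ent),
       n_singletons = length(entities) - length(ent))
}
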