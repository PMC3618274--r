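test_that("overall gap analysis detects gaps and computes the gap range", {
  # two well-separated groups: intra max 0.083, inter min 0.189
  ids <- c("s1", "s2", "s3", "d1", "d2")
  m <- matrix(0.2, 5, 5, dimnames = list(ids, ids))
  m[1, 2] <- m[2, 1] <- 0.005
  m[1, 3] <- m[3, 1] <- 0.065
  m[2, 3] <- m[3, 2] <- 0.083
  m[4, 5] <- m[5, 4] <- 0.01
  m[1, 4] <- m[4, 1] <- 0.189
  diag(m) <- 0
  D <- as_dist_matrix(m)
  gm <- group_map(c(s1 = "S", s2 = "S", s3 = "S", d1 = "Dc", d2 = "Dc"))
  res <- overall_gap_analysis(D, gm, "S")
  expect_true(res$gap_present)
  expect_equal(res$delta, 0.189 - 0.083, tolerance = 1e-12)
  expect_equal(unname(res$intra_summary["max"]), 0.083)

  # overlapping ranges: no gap
  m2 <- m
  m2[1, 4] <- m2[4, 1] <- 0.05
  res2 <- overall_gap_analysis(as_dist_matrix(m2), gm, "S")
  expect_false(res2$gap_present)
  expect_true(is.na(res2$delta))
})

test_that("gap range matches the exhaustive pairwise oracle on toy matrices", {
  set.seed(61)
  for (rep in 1:20) {
    n <- 6
    ids <- sprintf("x%d", 1:n)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    gm <- group_map(stats::setNames(rep(c("g", "h"), each = 3), ids))
    res <- overall_gap_analysis(as_dist_matrix(m), gm, "g")
    intra <- c(m[1, 2], m[1, 3], m[2, 3])
    inter <- as.vector(m[1:3, 4:6])
    expect_equal(res$gap_present, min(inter) > max(intra))
    if (res$gap_present) {
      expect_equal(res$delta, min(inter) - max(intra))
    }
  }
})

test_that("pairwise analysis names the blocking partner", {
  D <- toy_two_cluster_matrix()
  gm <- toy_two_cluster_groups()
  res <- pairwise_gap_analysis(D, gm, "A", "B")
  expect_true(res$gap_present)
  expect_error(pairwise_gap_analysis(D, gm, "A", "A"), "differ")

  # pull the groups together so A's intra (0.01) overlaps the inter range
  m <- D$matrix
  m["a1", "b1"] <- m["b1", "a1"] <- 0.005
  res2 <- pairwise_gap_analysis(as_dist_matrix(m), gm, "A", "B")
  expect_false(res2$gap_present)
  expect_equal(res2$blocking_group, "B")
  agg <- pga_aggregate(as_dist_matrix(m), gm, "A", c("B"))
  expect_false(agg$gap_present)
  expect_equal(agg$blocking_groups, "B")
})

test_that("OGA inter distances equal the union of PGA inter distances", {
  set.seed(62)
  n <- 9
  ids <- sprintf("x%d", 1:n)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  gm <- group_map(stats::setNames(rep(c("g", "h", "k"), each = 3), ids))
  D <- as_dist_matrix(m)
  oga <- overall_gap_analysis(D, gm, "g")
  agg <- pga_aggregate(D, gm, "g", c("h", "k"))
  pga_inter <- unlist(lapply(agg$per_partner, `[[`, "inter"))
  expect_equal(sort(oga$inter), sort(unname(pga_inter)))
})

test_that("threshold rules follow their definitions", {
  rules <- threshold_rules_from_stats(mean_intra = 0.033, min_inter = 0.189,
                                      mean_inter = 0.210)
  expect_equal(rules$supported, c("-", "+", "-", "+"))
  expect_true(rules$strong[4])    # ratio 6.4x clears the 4.1x upper bound

  # zero intra: all fold rules supported (infinite ratio)
  r0 <- threshold_rules_from_stats(0, 0.05, 0.06)
  expect_equal(r0$supported[r0$rule == "fold_10x"], "+")
  expect_equal(r0$supported[r0$rule == "fold_3.2-4.1x"], "+")
  expect_true(is.infinite(r0$ratio[1]))
})

test_that("randomised statistics agree with an independent rule oracle", {
  set.seed(63)
  for (rep in 1:50) {
    mi <- runif(1, 0, 0.1)
    lo <- runif(1, 0, 0.3)
    me <- lo + runif(1, 0, 0.1)
    rules <- threshold_rules_from_stats(mi, lo, me)
    oracle <- c(
      if (mi < 0.03 && lo >= 0.03) "+" else "-",
      if (mi < 0.04 && lo >= 0.04) "+" else "-",
      if (me >= 10 * mi) "+" else "-",
      if (me >= 3.2 * mi) "+" else "-")
    expect_equal(rules$supported, oracle)
  }
})

test_that("raising every inter distance never withdraws support", {
  set.seed(64)
  for (rep in 1:25) {
    mi <- runif(1, 0, 0.05)
    lo <- runif(1, 0, 0.2)
    me <- lo + runif(1, 0, 0.05)
    before <- threshold_rules_from_stats(mi, lo, me)$supported
    shift <- runif(1, 0, 0.2)
    after <- threshold_rules_from_stats(mi, lo + shift, me + shift)$supported
    expect_true(all(!(before == "+" & after == "-")))
  }
})

test_that("singleton focal groups yield na decisions but a gap verdict", {
  D <- toy_two_cluster_matrix()
  gm <- group_map(c(a1 = "solo", a2 = "rest", b1 = "rest", b2 = "rest"))
  res <- overall_gap_analysis(D, gm, "solo")
  expect_false(res$intra_defined)
  expect_true(res$gap_present)
  expect_equal(unique(apply_threshold_rules(res)$supported), "na")
})

test_that("gap histograms bin on half-open intervals and conserve counts", {
  res <- structure(list(intra = c(0.0, 0.01), inter = numeric(0),
                        intra_defined = TRUE), class = "gap_analysis")
  h <- export_gap_histogram(res, bin_width = 0.01)
  expect_equal(h$intra[1:2], c(1, 1))  # 0.01 falls in [0.01, 0.02)
  expect_true(all(h$inter == 0))
  expect_error(export_gap_histogram(res, 0), "positive")

  set.seed(65)
  res2 <- structure(list(intra = runif(40, 0, 0.1), inter = runif(60, 0, 0.3),
                         intra_defined = TRUE), class = "gap_analysis")
  h2 <- export_gap_histogram(res2, 0.013)
  expect_equal(sum(h2$intra), 40)
  expect_equal(sum(h2$inter), 60)
})
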