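test_that("monophyly agrees with brute-force descendant enumeration", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_error(is_monophyletic(tr, character(0)), "empty")

  set.seed(81)
  for (rep in 1:10) {
    tr <- ape::rcoal(10)
    grp <- sample(tr$tip.label, sample(2:8, 1))
    mrca <- ape::getMRCA(tr, grp)
    oracle <- setequal(ape::extract.clade(tr, mrca)$tip.label, grp)
    expect_equal(is_monophyletic(tr, grp), oracle)
  }
})

test_that("gsi is 1 exactly for monophyletic groups and in [0,1] always", {
  set.seed(82)
  tr <- ape::rcoal(20)
  node <- length(tr$tip.label) + 5
  clade <- ape::extract.clade(tr, node)$tip.label
  if (length(clade) >= 2 && length(clade) < 20) {
    r <- gsi_test(tr, clade, n_perm = 49, seed = 1)
    expect_identical(r$gsi, 1)
  }
  for (rep in 1:10) {
    tr <- ape::rcoal(12)
    grp <- sample(tr$tip.label, sample(2:10, 1))
    g <- gsi_test(tr, grp, n_perm = 19, seed = rep)$gsi
    expect_gte(g, 0); expect_lte(g, 1)
  }
})

test_that("gsi matches a direct evaluation of the normalisation formula", {
  # 8-tip caterpillar, group = the two tips farthest apart (t1 and t8)
  tr <- caterpillar_tree(8)
  r <- gsi_test(tr, c("t1", "t8"), n_perm = 9, seed = 1)
  # spanning subtree from t1 up to the root (the MRCA) passes through every
  # internal node: U = all 7, each binary, so GS = 2/7;
  # GS_max = 2/1, GS_min = 2/7 -> gsi = 0
  gs <- 2 / 7; gs_max <- 2; gs_min <- 2 / 7
  expect_equal(r$gsi, (gs - gs_min) / (gs_max - gs_min))

  # group {t1, t2}: U = {their parent}, GS = 2/1 -> gsi = 1
  expect_identical(gsi_test(tr, c("t1", "t2"), n_perm = 9, seed = 1)$gsi, 1)

  # group {t1, t3}: U = two deepest internal nodes, GS = 2/2
  r3 <- gsi_test(tr, c("t1", "t3"), n_perm = 9, seed = 1)
  expect_equal(r3$gsi, (1 - 2 / 7) / (2 - 2 / 7))
})

test_that("permutation p-values flag monophyletic groups as unusual", {
  set.seed(83)
  tr <- ape::rcoal(20)
  # pick a clade of exactly 5 tips if one exists, else grow the tree
  sizes <- lengths(phangorn::Descendants(tr, type = "tips"))
  node <- which(sizes == 5)[1]
  while (is.na(node)) {
    tr <- ape::rcoal(20)
    sizes <- lengths(phangorn::Descendants(tr, type = "tips"))
    node <- which(sizes == 5)[1]
  }
  grp <- tr$tip.label[phangorn::Descendants(tr, node, "tips")[[1]]]
  r <- gsi_test(tr, grp, n_perm = 999, seed = 3)
  expect_lte(r$p_value, 0.01)
})

test_that("gsi permutation p-values are valid under random labelling", {
  # the statistic is discrete, so the add-one permutation p-value is
  # super-uniform (valid, slightly conservative) rather than exactly
  # uniform: P(p <= a) must never exceed a by more than sampling noise,
  # and the distribution must not collapse to 1 either
  set.seed(84)
  tr <- ape::rcoal(16)
  pvals <- vapply(1:400, function(b) {
    grp <- sample(tr$tip.label, 5)
    gsi_test(tr, grp, n_perm = 99)$p_value
  }, numeric(1))
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= a), a + 2 * sqrt(a * (1 - a) / 400))
  }
  expect_gte(mean(pvals <= 0.5), 0.2)
  expect_gt(stats::sd(pvals), 0.1)
})

test_that("sequential Bonferroni reproduces Holm's step-down decisions", {
  expect_equal(sequential_bonferroni(c(0.001, 0.04), 0.05), c(TRUE, TRUE))
  expect_equal(sequential_bonferroni(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_true(sequential_bonferroni(0.04, 0.05))
  # order preserved relative to input
  expect_equal(sequential_bonferroni(c(0.04, 0.001), 0.05), c(TRUE, TRUE))
  expect_equal(sequential_bonferroni(c(0.03, 0.04), 0.05), c(FALSE, FALSE))
})

test_that("rosenberg closed form equals the join-sequence oracle", {
  expect_equal(rosenberg_pab(1, 1)$p_ab, 1)
  expect_equal(rosenberg_pab(2, 2)$p_ab, 1 / 9, tolerance = 1e-12)
  for (a in 1:7) for (b in 1:(8 - a)) {
    expect_equal(rosenberg_pab(a, b)$p_ab,
                 rosenberg_pab(a, b, "enumeration")$p_ab,
                 tolerance = 1e-12)
  }
  # monotone: bigger groups make chance reciprocal monophyly rarer
  expect_lt(rosenberg_pab(5, 5)$p_ab, rosenberg_pab(3, 3)$p_ab)
})

test_that("rodrigo's test ranks distinct clades as unusual", {
  # long stem, shallow crown: distinct
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):2,(c:1.0,d:1.05):1.05);")
  node <- ape::getMRCA(tr, c("a", "b"))
  r <- rodrigo_prd(tr, node, n_sim = 200, seed = 5)
  expect_lt(r$p_value, 0.1)
  expect_equal(r$clade_size, 2)
  # zero-length stem: infinitely indistinct, p = 1
  tr0 <- ape::read.tree(text = "((a:1,b:1):0,(c:0.5,d:0.5):0.5);")
  r0 <- rodrigo_prd(tr0, ape::getMRCA(tr0, c("a", "b")), n_sim = 50, seed = 5)
  expect_true(is.infinite(r0$r_obs))
  expect_equal(r0$p_value, 1)
  # tip-label interface and root guard
  expect_equal(rodrigo_prd(tr, c("a", "b"), n_sim = 10, seed = 1)$node, node)
  expect_error(rodrigo_prd(tr, length(tr$tip.label) + 1L), "root")
})

test_that("sdp summaries report patristic structure and P ID(Strict)", {
  tr <- ape::read.tree(text = "((a1:0.01,a2:0.01):0.5,((b1:0.01,b2:0.01):0.3,(c1:0.02,c2:0.02):0.29):0.2);")
  gm <- group_map(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C"))
  s <- sdp_summary(tr, gm, "B")
  expect_equal(s$closest_group, "C")
  expect_equal(s$intra, 0.02, tolerance = 1e-12)
  expect_equal(s$p_id_strict, 1)           # long internal branches
  expect_true(s$ci[1] <= 1 && s$ci[2] >= s$ci[1])
  # closest group minimises the mean patristic distance (exhaustive scan)
  pat <- ape::cophenetic.phylo(tr)
  means <- c(A = mean(pat[c("b1", "b2"), c("a1", "a2")]),
             C = mean(pat[c("b1", "b2"), c("c1", "c2")]))
  expect_equal(s$inter, unname(min(means)))
  # singleton focal: intra inapplicable
  gm2 <- group_map(c(a1 = "solo", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C"))
  s2 <- sdp_summary(tr, gm2, "solo")
  expect_true(is.na(s2$intra))
  expect_true(is.na(s2$ratio))
})
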