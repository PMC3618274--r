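test_that("support matrices validate cells and pass decisions through", {
  gm <- group_map(c(x1 = "X", x2 = "X", y1 = "Y"),
                  nesting = data.frame(parent = "XY", child = c("X", "Y")))
  sm <- support_matrix(list(m1 = c(X = "+", Y = "-"),
                            m2 = c(X = "na", XY = "+")), gm)
  expect_equal(sm$cells["X", "m1"], "+")
  expect_equal(sm$cells["XY", "m1"], "")    # no decision recorded
  expect_equal(sm$cells["XY", "m2"], "+")
  expect_error(support_matrix(list(m = c(Z = "+")), gm), "unknown")
  expect_error(support_matrix(list(m = c(X = "yes")), gm), "invalid")
})

test_that("species counting enumerates tilings under nesting", {
  gm <- group_map(c(x1 = "X", x2 = "X", y1 = "Y"),
                  nesting = data.frame(parent = "XY", child = c("X", "Y")))
  sm <- support_matrix(list(m = c(X = "+", Y = "+", XY = "+")), gm)
  r <- count_species_range(sm, "m", "XY")
  expect_equal(r$min, 1)   # the parent alone
  expect_equal(r$max, 2)   # the two children
  # unsupported parent: only the children tile
  sm2 <- support_matrix(list(m = c(X = "+", Y = "+", XY = "-")), gm)
  r2 <- count_species_range(sm2, "m", "XY")
  expect_equal(c(r2$min, r2$max), c(2, 2))
  # na hypotheses cover but do not count
  sm3 <- support_matrix(list(m = c(X = "+", Y = "na", XY = "-")), gm)
  r3 <- count_species_range(sm3, "m", "XY")
  expect_equal(c(r3$min, r3$max), c(1, 1))
  # a column with no supported hypothesis cannot be counted
  sm4 <- support_matrix(list(m = c(X = "na", Y = "na", XY = "na")), gm)
  expect_error(count_species_range(sm4, "m", "XY"), "supports no")
  # uncovered ids are an error
  sm5 <- support_matrix(list(m = c(X = "+", Y = "-", XY = "-")), gm)
  expect_error(count_species_range(sm5, "m", "XY"), "tiling")
})

test_that("the recursive search agrees with brute-force subset enumeration", {
  brute_range <- function(hyp_ids, units, scope_ids) {
    hyps <- names(hyp_ids)
    counts <- integer(0)
    for (mask in 0:(2^length(hyps) - 1)) {
      sel <- hyps[bitwAnd(mask, 2^(seq_along(hyps) - 1)) > 0]
      ids <- unlist(hyp_ids[sel])
      if (length(ids) == length(unique(ids)) && setequal(ids, scope_ids)) {
        counts <- c(counts, sum(units[sel]))
      }
    }
    if (!length(counts)) NULL else c(min(counts), max(counts))
  }
  set.seed(101)
  for (rep in 1:20) {
    ids <- letters[1:6]
    gm <- group_map(stats::setNames(ids, ids),
                    nesting = data.frame(
                      parent = c("ab", "ab", "cd", "cd", "all", "all", "all", "all"),
                      child = c("a", "b", "c", "d", "ab", "cd", "e", "f")))
    cells <- sample(c("+", "-", "na"), 8, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2))
    names(cells) <- c("a", "b", "c", "d", "e", "f", "ab", "cd")
    sm <- support_matrix(list(m = cells), gm)
    usable <- names(cells)[cells %in% c("+", "na")]
    hyp_ids <- lapply(stats::setNames(nm = usable), function(h) group_ids(gm, h))
    units <- stats::setNames(as.integer(cells[usable] == "+"), usable)
    oracle <- brute_range(hyp_ids, units, ids)
    if (is.null(oracle) || !any(units == 1)) {
      expect_error(count_species_range(sm, "m", "all"))
    } else {
      r <- count_species_range(sm, "m", "all")
      expect_equal(c(r$min, r$max), oracle)
    }
  }
})

test_that("supported child pairs can only widen the count range", {
  gm <- group_map(c(a = "A", b1 = "B1", b2 = "B2"),
                  nesting = data.frame(parent = c("B", "B", "all", "all"),
                                       child = c("B1", "B2", "A", "B")))
  narrow <- support_matrix(list(m = c(A = "+", B = "+", B1 = "-", B2 = "-")), gm)
  wide <- support_matrix(list(m = c(A = "+", B = "+", B1 = "+", B2 = "+")), gm)
  rn <- count_species_range(narrow, "m", "all")
  rw <- count_species_range(wide, "m", "all")
  expect_lte(rw$min, rn$min)
  expect_gte(rw$max, rn$max)
})

test_that("the published Rumina decision matrix reproduces its count ranges", {
  ex <- rumina_example()
  gmyc <- count_species_range(ex$support, "GMYC", "Rumina")
  expect_equal(c(gmyc$min, gmyc$max), c(10, 10))
  oga_d <- count_species_range(ex$support, "OGA", "R.decollata")
  expect_equal(c(oga_d$min, oga_d$max), c(7, 8))
  oga_s <- count_species_range(ex$support, "OGA", "R.saharica")
  expect_equal(c(oga_s$min, oga_s$max), c(1, 2))
  abgd <- count_species_range(ex$support, "ABGD", "Rumina")
  expect_equal(c(abgd$min, abgd$max), c(9, 9))
  gsi_ml <- count_species_range(ex$support, "GSI_ML", "Rumina")
  expect_equal(c(gsi_ml$min, gsi_ml$max), c(7, 10))
})

test_that("upstream decisions map onto cells", {
  D <- toy_two_cluster_matrix()
  gm <- toy_two_cluster_groups()
  gaps <- list(A = overall_gap_analysis(D, gm, "A"),
               B = overall_gap_analysis(D, gm, "B"))
  expect_equal(unname(decisions_from_gap(gaps)), c("+", "+"))
  parts <- list(c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(decisions_from_partition(parts, gm, c("A", "B"))),
               c("+", "+"))
  expect_equal(unname(decisions_from_partition(list(c("a1", "a2", "b1", "b2")),
                                               gm, c("A", "B"))),
               c("-", "-"))
})
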