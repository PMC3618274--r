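test_that("gap detection follows the ranked-distance rule", {
  g <- detect_barcode_gap(c(0.00, 0.01, 0.20, 0.21), P = 0.05, X = 2)
  expect_false(is.null(g))
  expect_gt(as.numeric(g), 0.01)
  expect_lt(as.numeric(g), 0.20)
  expect_equal(attr(g, "lower"), 0.01)
  expect_equal(attr(g, "upper"), 0.20)

  expect_null(detect_barcode_gap(rep(0.1, 6), P = 0.05, X = 2))
  expect_null(detect_barcode_gap(c(0.01, 0.02, 0.03), P = 0.05, X = 2))
  expect_error(detect_barcode_gap(0.1, P = 0.05, X = 2), "two distances")
})

test_that("a huge relative gap width finds nothing at realistic scales", {
  # with X = 15 and priors floored at theta, a 0.12-wide gap cannot qualify
  d <- c(runif(30, 0, 0.03), runif(30, 0.15, 0.25))
  expect_null(detect_barcode_gap(d, P = 0.1, X = 15))
  expect_false(is.null(detect_barcode_gap(d, P = 0.01, X = 1.5)))
})

test_that("abgd partitions identical and well-separated data correctly", {
  loc <- toy_locus(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC"))
  D <- dist_matrix(loc, "p")
  res <- abgd_partition(D, abgd_config())
  expect_true(all(vapply(res$per_prior, `[[`, numeric(1), "n_primary") == 1))

  D2 <- toy_two_cluster_matrix()
  res2 <- abgd_partition(D2, abgd_config(p_min = 0.05, p_max = 0.05001,
                                         steps = 2, X = 2))
  expect_equal(res2$per_prior[[1]]$n_primary, 2)
  expect_setequal(vapply(res2$per_prior[[1]]$primary, paste, character(1),
                         collapse = ","),
                  c("a1,a2", "b1,b2"))
})

test_that("partitions equal brute-force single-linkage components", {
  brute_components <- function(m, thr) {
    ids <- rownames(m)
    comp <- seq_along(ids)
    repeat {
      changed <- FALSE
      for (i in seq_along(ids)) for (j in seq_along(ids)) {
        if (i != j && m[i, j] < thr && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    sort(unname(vapply(split(ids, comp),
                       function(g) paste(sort(g), collapse = ","),
                       character(1))))
  }
  set.seed(71)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    ids <- sprintf("q%02d", 1:n)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- sample(c(runif(n, 0, 0.02), runif(n * n, 0.1, 0.3)),
                              n * (n - 1) / 2, replace = TRUE)
    m <- m + t(m)
    res <- abgd_partition(as_dist_matrix(m),
                          abgd_config(p_min = 0.04, p_max = 0.05, steps = 2))
    r <- res$per_prior[[1]]
    got <- sort(vapply(r$primary, function(g) paste(sort(g), collapse = ","),
                       character(1)))
    thr <- if (is.null(r$gap)) Inf else as.numeric(r$gap)
    expect_equal(got, if (is.infinite(thr)) paste(sort(ids), collapse = ",")
                      else brute_components(m, thr))
  }
})

test_that("recursion refines the primary partition and priors act monotonically", {
  set.seed(72)
  for (rep in 1:10) {
    ds <- simulate_dataset(sim_config(K = 4, n_k = c(5, 4, 3, 2),
                                      seq_length = 300, seed = 7200 + rep))
    D <- dist_matrix(ds$locus, "K2P")
    res <- abgd_partition(D, abgd_config(steps = 6))
    nprim <- vapply(res$per_prior, `[[`, numeric(1), "n_primary")
    nrec <- vapply(res$per_prior, `[[`, numeric(1), "n_recursive")
    expect_true(all(nrec >= nprim))
    expect_true(all(diff(nprim) <= 0))   # higher prior, never more groups
    for (r in res$per_prior) {
      # every recursive group sits inside one primary group
      prim_of <- rep(seq_along(r$primary), lengths(r$primary))
      names(prim_of) <- unlist(r$primary)
      for (g in r$recursive) expect_equal(length(unique(prim_of[g])), 1L)
      # partitions cover all ids exactly once
      expect_setequal(unlist(r$primary), D$ids)
      expect_equal(anyDuplicated(unlist(r$recursive)), 0L)
    }
  }
})

test_that("well-separated synthetic data is recovered at intermediate priors", {
  ds <- simulate_dataset(sim_config(K = 5, n_k = c(6, 5, 4, 3, 2),
                                    seq_length = 500, seed = 7301))
  D <- dist_matrix(ds$locus, "K2P")
  res <- abgd_partition(D, abgd_config())
  st <- abgd_stable_count(res)
  expect_equal(st$n_groups, 5)
  truth <- split(names(ds$partition), ds$partition)
  got <- lapply(st$partition, sort)
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(truth, function(g) paste(sort(g), collapse = ","),
                         character(1)))
})
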