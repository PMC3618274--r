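#' Rosenberg's probability of reciprocal monophyly
#'
#' Probability that two labelled groups of sizes `a` and `b` are
#' reciprocally monophyletic when the `a + b` tips coalesce under the
#' neutral null in which every join sequence (labelled history) is
#' equiprobable.  Small values mean that the observed reciprocal monophyly
#' is unlikely to be a chance outcome of random branching.
#'
#' The closed form counts the labelled histories in which all within-A and
#' within-B joins precede the final join:
#' `P_AB = 2 a! b! (a+b-2)! / ((a+b)! (a+b-1)!)`.
#' The `"enumeration"` method computes the same probability by recursion
#' over the equiprobable join sequences (memoised on the multiset of
#' lineage compositions) and serves as an independent check.
#'
#' @param a,b group sizes (>= 1).
#' @param method `"closed-form"` (default) or `"enumeration"`.
#' @return object of class `pab_result`: list with `a`, `b`, `p_ab`,
#'   `method`.
#' @export
rosenberg_pab <- function(a, b, method = c("closed-form", "enumeration")) {
  method <- match.arg(method)
  stopifnot(a >= 1, b >= 1, a == round(a), b == round(b))
  p <- if (method == "closed-form") {
    exp(log(2) + lfactorial(a) + lfactorial(b) + lfactorial(a + b - 2) -
          lfactorial(a + b) - lfactorial(a + b - 1))
  } else {
    .pab_enumerate(a, b)
  }
  structure(list(a = a, b = b, p_ab = p, method = method),
            class = "pab_result")
}

#' @export
print.pab_result <- function(x, ...) {
  cat(sprintf("Rosenberg P_AB(a = %d, b = %d) = %.6g [%s]\n",
              x$a, x$b, x$p_ab, x$method))
  invisible(x)
}

#' @keywords internal
#' Probability of reciprocal monophyly by recursion over join sequences.
#' State: multiset of pure lineages, each counted by how many A-tips or
#' B-tips it spans.  A join of two pure-A (or two pure-B) lineages keeps the
#' state valid; a mixed join succeeds only as the very last join between the
#' completed A lineage and the completed B lineage, and fails otherwise.
.pab_enumerate <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  recurse <- function(as, bs) {
    k <- length(as) + length(bs)
    if (k == 2L && length(as) == 1L && length(bs) == 1L) return(1)
    key <- paste(paste(sort(as), collapse = ","), paste(sort(bs), collapse = ","),
                 sep = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- k * (k - 1) / 2
    acc <- 0
    na <- length(as); nb <- length(bs)
    if (na >= 2L) {
      for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
        acc <- acc + recurse(c(as[-c(i, j)], as[i] + as[j]), bs)
      }
    }
    if (nb >= 2L) {
      for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
        acc <- acc + recurse(as, c(bs[-c(i, j)], bs[i] + bs[j]))
      }
    }
    # mixed joins with k > 2 lineages remaining contribute 0
    p <- acc / total
    memo[[key]] <- p
    p
  }
  recurse(rep(1, a), rep(1, b))
}
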