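# Fixtures built in code: tiny alignments, trees and distance matrices.

write_fasta_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_locus <- function(seqs, name = "toy") {
  aligned_locus(seqs, name)
}

# two tight clusters far apart, plus group labels
toy_two_cluster_matrix <- function() {
  ids <- c("a1", "a2", "b1", "b2")
  m <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  m[1, 2] <- m[2, 1] <- 0.01
  m[3, 4] <- m[4, 3] <- 0.02
  diag(m) <- 0
  as_dist_matrix(m)
}

toy_two_cluster_groups <- function() {
  group_map(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
}

random_locus <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  seqs <- vapply(seq_len(n), function(i)
    paste0(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("s%02d", seq_len(n))
  aligned_locus(seqs, "rand")
}

caterpillar_tree <- function(n) {
  # ((((t1,t2),t3),t4),...) with unit branch lengths, ultrametric-ised ages
  txt <- "(t1:1,t2:1)"
  for (k in 3:n) txt <- sprintf("(%s:1,t%d:%d)", txt, k, k - 1)
  ape::read.tree(text = paste0(txt, ";"))
}
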