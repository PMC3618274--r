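#' Aligned locus container
#'
#' Holds one aligned locus as equal-length upper-case character strings over
#' `A,C,G,T`, IUPAC ambiguity codes, the gap state `-` and the missing state
#' `?`.  Row names are specimen (or haplotype) identifiers and must be unique.
#'
#' @param seqs named character vector of aligned sequences (one string per
#'   specimen), or a character matrix with one row per specimen.
#' @param locus_name name of the locus (e.g. `"COI"`).
#' @return an object of class `aligned_locus` with elements `locus_name`,
#'   `ids`, `seq` (named character vector) and `length` (alignment columns).
#' @export
aligned_locus <- function(seqs, locus_name = "locus") {
  if (is.matrix(seqs)) {
    ids <- rownames(seqs)
    seqs <- apply(seqs, 1L, paste0, collapse = "")
    names(seqs) <- ids
  }
  if (length(seqs) == 0L) stop("alignment has no records")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every sequence needs an identifier")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("unequal row lengths in alignment (", paste(unique(lens), collapse = ", "),
         "); refusing to pad")
  }
  if (lens[1L] == 0L) stop("alignment has zero columns")
  structure(list(locus_name = locus_name, ids = ids, seq = seqs,
                 length = unname(lens[1L])),
            class = "aligned_locus")
}

#' @export
print.aligned_locus <- function(x, ...) {
  cat("Aligned locus '", x$locus_name, "': ", length(x$ids), " sequences x ",
      x$length, " bp\n", sep = "")
  invisible(x)
}

#' Character matrix view of an aligned locus
#'
#' @param locus an [aligned_locus].
#' @return character matrix (sequences x columns) with id row names.
#' @export
seq_matrix <- function(locus) {
  stopifnot(inherits(locus, "aligned_locus"))
  m <- do.call(rbind, strsplit(locus$seq, "", fixed = TRUE))
  rownames(m) <- locus$ids
  m
}

#' Read an aligned FASTA file
#'
#' Reads a multi-FASTA alignment.  Case is normalised to upper; unequal row
#' lengths and duplicate identifiers are errors (no silent padding).
#'
#' @param path FASTA file.
#' @param locus_name locus label to attach.
#' @return an [aligned_locus].
#' @export
read_alignment <- function(path, locus_name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  aligned_locus(seqs, locus_name)
}

#' Write an aligned locus as FASTA
#'
#' @param locus an [aligned_locus].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(locus, path) {
  stopifnot(inherits(locus, "aligned_locus"))
  seqinr::write.fasta(as.list(locus$seq), names = locus$ids, file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Collapse identical sequences into haplotypes
#'
#' Two specimens share a haplotype when their aligned rows are equal under
#' the chosen rule.  `"strict"` means exact string equality (gaps and
#' ambiguity codes are ordinary states).  `"missing-tolerant"` treats `?`
#' and `N` as compatible with any state and merges by transitive closure of
#' pairwise compatibility, with ids processed in lexicographic order so the
#' result is deterministic.
#'
#' @param locus an [aligned_locus].
#' @param equality `"strict"` or `"missing-tolerant"`.
#' @return an object of class `haplotype_table`: a list with `members`
#'   (named list: haplotype id -> member specimen ids), `representative`
#'   (named character vector of sequences) and `n_haplotypes`.
#' @export
collapse_haplotypes <- function(locus, equality = c("strict", "missing-tolerant")) {
  stopifnot(inherits(locus, "aligned_locus"))
  equality <- match.arg(equality)
  ids <- sort(locus$ids)
  seqs <- locus$seq[ids]
  if (equality == "strict") {
    groups <- split(ids, factor(seqs, levels = unique(seqs)))
  } else {
    m <- seq_matrix(locus)[ids, , drop = FALSE]
    miss <- m == "?" | m == "N"
    n <- length(ids)
    # union-find over pairwise compatibility
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- all(m[i, ] == m[j, ] | miss[i, ] | miss[j, ])
      if (ok) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <- min(ri, rj) }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    groups <- split(ids, factor(roots, levels = unique(roots)))
  }
  hap_ids <- sprintf("H%02d", seq_along(groups))
  members <- stats::setNames(unname(groups), hap_ids)
  representative <- stats::setNames(
    vapply(members, function(g) unname(seqs[g[1L]]), character(1)), hap_ids)
  structure(list(members = members, representative = representative,
                 n_haplotypes = length(members), equality = equality,
                 locus_name = locus$locus_name),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table (", x$equality, "): ", x$n_haplotypes, " haplotypes from ",
      length(unlist(x$members)), " sequences\n", sep = "")
  invisible(x)
}

#' Write a haplotype table as TSV
#'
#' @param ht a `haplotype_table`.
#' @param path output file.
#' @export
write_haplotype_table <- function(ht, path) {
  df <- data.frame(
    haplotype = rep(names(ht$members), lengths(ht$members)),
    id = unlist(ht$members, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate loci into a supermatrix
#'
#' @param loci list of [aligned_locus] objects sharing an id namespace.
#' @param policy `"drop-incomplete"` keeps only ids present in every locus
#'   (the usual treatment when some specimens lack a marker);
#'   `"pad-missing"` keeps all ids and fills absent loci with `?` columns.
#' @return an [aligned_locus] whose `provenance` attribute is a data frame
#'   (`locus`, `column`) mapping every supermatrix column back to its locus
#'   and original column, so partitioned analyses and [split_loci()] can
#'   recover the inputs.
#' @export
concatenate_loci <- function(loci, policy = c("drop-incomplete", "pad-missing")) {
  policy <- match.arg(policy)
  stopifnot(length(loci) >= 1L, all(vapply(loci, inherits, logical(1), "aligned_locus")))
  all_ids <- lapply(loci, function(l) l$ids)
  ids <- if (policy == "drop-incomplete") Reduce(intersect, all_ids)
         else Reduce(union, all_ids)
  if (length(ids) == 0L) stop("no id present in every locus under drop-incomplete")
  ids <- sort(ids)
  parts <- lapply(loci, function(l) {
    out <- character(length(ids))
    present <- ids %in% l$ids
    out[present] <- l$seq[ids[present]]
    out[!present] <- strrep("?", l$length)
    out
  })
  seqs <- stats::setNames(do.call(paste0, parts), ids)
  res <- aligned_locus(seqs, paste(vapply(loci, `[[`, character(1), "locus_name"),
                                   collapse = "+"))
  attr(res, "provenance") <- data.frame(
    locus = rep(vapply(loci, `[[`, character(1), "locus_name"),
                vapply(loci, `[[`, numeric(1), "length")),
    column = unlist(lapply(loci, function(l) seq_len(l$length))))
  res
}

#' Split a concatenated supermatrix back into its loci
#'
#' Inverse of [concatenate_loci()], using the stored column provenance.
#'
#' @param concat an [aligned_locus] produced by [concatenate_loci()].
#' @return named list of [aligned_locus] objects.
#' @export
split_loci <- function(concat) {
  prov <- attr(concat, "provenance")
  if (is.null(prov)) stop("no column provenance on this alignment")
  m <- seq_matrix(concat)
  lapply(stats::setNames(nm = unique(prov$locus)), function(nm) {
    aligned_locus(m[, prov$locus == nm, drop = FALSE], nm)
  })
}

#' Find group-diagnostic alignment columns
#'
#' A column is diagnostic for the focal group when the set of states observed
#' inside the group is disjoint from the set observed in all other sequences.
#' Polymorphic-but-disjoint columns qualify.  `?` is unobserved and ignored;
#' the gap state `-` is an ordinary (and typically the interesting) state,
#' so group-specific indel blocks are recovered.  Columns are reported
#' 1-based in alignment coordinates.
#'
#' @param locus an [aligned_locus].
#' @param groups a [group_map] covering the locus ids.
#' @param focal focal group label.
#' @return data frame with `column`, `focal_states`, `other_states`
#'   (states collapsed with `/`).
#' @export
find_diagnostic_columns <- function(locus, groups, focal) {
  stopifnot(inherits(locus, "aligned_locus"))
  fids <- intersect(group_ids(groups, focal), locus$ids)
  oids <- setdiff(locus$ids, fids)
  if (length(fids) == 0L) stop("focal group '", focal, "' has no sequences in this locus")
  if (length(oids) == 0L) stop("complement of '", focal, "' is empty")
  m <- seq_matrix(locus)
  fm <- m[fids, , drop = FALSE]
  om <- m[oids, , drop = FALSE]
  res <- lapply(seq_len(ncol(m)), function(j) {
    fs <- setdiff(unique(fm[, j]), "?")
    os <- setdiff(unique(om[, j]), "?")
    if (length(fs) > 0L && length(os) > 0L && length(intersect(fs, os)) == 0L) {
      data.frame(column = j,
                 focal_states = paste(sort(fs), collapse = "/"),
                 other_states = paste(sort(os), collapse = "/"))
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(column = integer(0), focal_states = character(0),
                      other_states = character(0))
  }
  out
}
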