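#' Configuration for the multispecies-coalescent simulator
#'
#' Defaults emulate the divergence structure typical of a deeply structured
#' land-snail barcoding study: seven species whose sample sizes span a
#' singleton to 26 haplotypes, species-tree node heights mapped into
#' `species_depth_range` so pairwise between-species divergence spans about
#' 14--21\% (substitutions/site), and shallow within-species coalescents
#' (`pop_scale`; the default keeps the expected between/within depth ratio
#' at 20, with within-group divergence well under 1\%).
#' Sequences evolve under a two-parameter transition/transversion process
#' (`kappa`), and each species can receive group-specific indel blocks in a
#' second, rDNA-like locus.
#'
#' @param K number of species (>= 1).
#' @param n_k samples per species (recycled to length `K`); singletons
#'   allowed.
#' @param species_depth_range range (min, max) into which species-tree
#'   internal node heights are mapped, in substitutions/site.
#' @param pop_scale population scale of the within-species coalescents:
#'   coalescent branch lengths are drawn on the standard scale
#'   (`ape::rcoal`) and multiplied by `pop_scale`, so the expected pairwise
#'   within-species divergence is about `2 * pop_scale` and the expected
#'   coalescent depth of a large sample about `2 * pop_scale` as well.
#' @param seq_length alignment columns per locus.
#' @param kappa transition/transversion rate ratio for sequence evolution.
#' @param indel_blocks indel blocks per species for [inject_indels()].
#' @param indel_length columns per indel block.
#' @param seed integer seed recorded in the config and used by the
#'   simulation entry points.
#' @return a `sim_config` list.
#' @export
sim_config <- function(K = 7, n_k = c(26, 1, 12, 6, 12, 6, 19),
                       species_depth_range = c(0.07, 0.105),
                       pop_scale = 0.00175, seq_length = 600, kappa = 4,
                       indel_blocks = 1, indel_length = 3, seed = NULL) {
  stopifnot(K >= 1, all(n_k >= 1), pop_scale > 0, seq_length >= 1,
            kappa > 0, length(species_depth_range) == 2L,
            species_depth_range[1L] > 0, diff(species_depth_range) >= 0)
  structure(list(K = as.integer(K), n_k = rep_len(as.integer(n_k), K),
                 species_depth_range = species_depth_range,
                 pop_scale = pop_scale, seq_length = as.integer(seq_length),
                 kappa = kappa, indel_blocks = as.integer(indel_blocks),
                 indel_length = as.integer(indel_length), seed = seed),
            class = "sim_config")
}

#' @keywords internal
#' coalescent subtree with branch lengths on the pop_scale, tips renamed
#' sp<k>_<i>; returns the newick fragment (no semicolon) and its height.
#' The height is capped at max_height (rescaling, with a warning) so the
#' subtree always fits under its species stem.
.coal_newick <- function(n, pop_scale, prefix, max_height = Inf) {
  ct <- ape::rcoal(n)
  ct$edge.length <- ct$edge.length * pop_scale
  h <- max(ape::node.depth.edgelength(ct))
  if (h > max_height) {
    warning("within-species coalescent rescaled to fit under its stem")
    ct$edge.length <- ct$edge.length * max_height / h
    h <- max_height
  }
  ct$tip.label <- sprintf("%s_%d", prefix, seq_len(n))
  list(newick = gsub(";$", "", ape::write.tree(ct)), height = h)
}

#' Simulate a gene tree: Yule species tree with grafted coalescents
#'
#' Draws a Yule topology for the `K` species, maps its internal node
#' heights linearly into `species_depth_range` (so every between-species
#' split is deep, as in the emulated data), and grafts onto each species
#' tip an `n_k`-sample neutral coalescent on the `pop_scale`.  The
#' result is binary and ultrametric with tip labels `sp<k>_<i>`.
#'
#' @param config a [sim_config()]; `config$seed` (if non-`NULL`) seeds the
#'   draw.
#' @return object of class `truth_set`: list with `tree` (ultrametric
#'   `phylo`), `partition` (named character: tip -> species label),
#'   `species` (labels) and `config`.
#' @export
simulate_tree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$K
  labels <- sprintf("sp%d", seq_len(K))
  if (K == 1L) {
    n <- config$n_k[1L]
    if (n < 2L) stop("K = 1 needs at least two samples")
    cn <- .coal_newick(n, config$pop_scale, "sp1")
    tree <- ape::read.tree(text = paste0(cn$newick, ";"))
  } else {
    sp <- ape::rphylo(K, birth = 1, death = 0)
    sp$tip.label <- labels[seq_len(K)]
    ages <- node_ages(sp)
    ages[seq_len(K)] <- 0
    int <- (K + 1L):(K + sp$Nnode)
    lo <- config$species_depth_range[1L]; hi <- config$species_depth_range[2L]
    h <- ages[int]
    ages[int] <- if (length(int) == 1L || diff(range(h)) == 0) {
      rep(hi, length(int))
    } else {
      lo + (h - min(h)) / (max(h) - min(h)) * (hi - lo)
    }
    sp$edge.length <- ages[sp$edge[, 1L]] - ages[sp$edge[, 2L]]
    if (config$pop_scale >= lo) {
      stop("pop_scale must be smaller than the minimum species depth")
    }
    txt <- ape::write.tree(sp)
    for (k in seq_len(K)) {
      n <- config$n_k[k]
      if (n < 2L) {
        txt <- sub(sprintf("(?<![A-Za-z0-9_])%s:", labels[k]),
                   sprintf("%s_1:", labels[k]), txt, perl = TRUE)
        next
      }
      mt <- regmatches(txt, regexpr(sprintf("(?<![A-Za-z0-9_])%s:[0-9.eE+-]+",
                                            labels[k]), txt, perl = TRUE))
      stem_total <- as.numeric(sub(".*:", "", mt))
      cn <- .coal_newick(n, config$pop_scale, labels[k],
                         max_height = 0.9 * stem_total)
      txt <- sub(mt, sprintf("%s:%.10f", cn$newick, stem_total - cn$height),
                 txt, fixed = TRUE)
    }
    tree <- ape::read.tree(text = txt)
  }
  partition <- stats::setNames(sub("_.*$", "", tree$tip.label), tree$tip.label)
  structure(list(tree = tree, partition = partition,
                 species = labels, config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Synthetic truth set:", length(x$tree$tip.label), "tips,",
      x$config$K, "species\n")
  invisible(x)
}

#' Evolve sequences along a tree
#'
#' Sites evolve independently under the two-parameter
#' transition/transversion process with ratio `kappa` and equal base
#' frequencies; branch lengths are expected substitutions per site, so the
#' expected pairwise corrected distance equals the path length.
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param config a [sim_config()] (uses `seq_length` and `kappa`).
#' @param locus_name locus label for the result.
#' @return an [aligned_locus].
#' @export
evolve_sequences <- function(tree, config = sim_config(), locus_name = "COI") {
  stopifnot(inherits(tree, "phylo"))
  if (config$seq_length < 1L) stop("zero-length sequences requested")
  dat <- phangorn::simSeq(tree, l = config$seq_length,
                          Q = c(1, config$kappa, 1, 1, config$kappa, 1),
                          bf = rep(0.25, 4))
  m <- toupper(as.character(dat))
  aligned_locus(m, locus_name)
}

#' Inject group-diagnostic indel blocks
#'
#' Deletes (`-`) species-specific column blocks in all members of each
#' species, mimicking group-diagnostic indels in rDNA-like loci.  Blocks of
#' different species never overlap by construction, so every injected block
#' is diagnosable.
#'
#' @param locus an [aligned_locus].
#' @param partition named character vector: id -> species label.
#' @param config a [sim_config()] (uses `indel_blocks`, `indel_length`).
#' @return list with `locus` (modified alignment) and `truth` (data frame:
#'   `species`, `column`).
#' @export
inject_indels <- function(locus, partition, config = sim_config()) {
  stopifnot(inherits(locus, "aligned_locus"))
  species <- unique(unname(partition))
  B <- config$indel_blocks; Lb <- config$indel_length
  if (B == 0L || Lb == 0L) {
    return(list(locus = locus, truth = data.frame(species = character(0),
                                                  column = integer(0))))
  }
  need <- length(species) * B * Lb
  if (need > locus$length) {
    stop("indel blocks (", need, " columns) exceed alignment length ", locus$length)
  }
  m <- seq_matrix(locus)
  truth <- list()
  slot <- 0L
  for (k in seq_along(species)) {
    ids <- names(partition)[partition == species[k]]
    ids <- intersect(ids, locus$ids)
    for (b in seq_len(B)) {
      cols <- (slot * Lb + 1L):(slot * Lb + Lb)
      slot <- slot + 1L
      m[ids, cols] <- "-"
      truth[[length(truth) + 1L]] <- data.frame(species = species[k],
                                                column = cols)
    }
  }
  list(locus = aligned_locus(m, locus$locus_name),
       truth = do.call(rbind, truth))
}

#' Simulate a complete dataset
#'
#' Seeds the generator, simulates the gene tree, evolves a barcode-like
#' locus and (optionally) an indel-bearing locus, and returns everything a
#' delimitation pipeline consumes, together with the truth.
#'
#' @param config a [sim_config()].
#' @param indel_locus also produce a second locus carrying the injected
#'   species-diagnostic indels.
#' @return list with `tree`, `partition`, `groups` (a [group_map]),
#'   `locus`, `indel_locus` (or `NULL`), `indel_truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), indel_locus = FALSE) {
  ts <- simulate_tree(config)
  locus <- evolve_sequences(ts$tree, config, locus_name = "COI")
  groups <- group_map(ts$partition)
  res <- list(tree = ts$tree, partition = ts$partition, groups = groups,
              locus = locus, indel_locus = NULL, indel_truth = NULL,
              config = config)
  if (indel_locus) {
    second <- evolve_sequences(ts$tree, config, locus_name = "rDNA")
    inj <- inject_indels(second, ts$partition, config)
    res$indel_locus <- inj$locus
    res$indel_truth <- inj$truth
  }
  res
}

#' Write a simulated dataset to disk
#'
#' Writes one FASTA per locus, the truth tree (newick), the truth partition
#' (TSV) and the configuration (TSV of key-value pairs, seed included), and
#' returns a manifest of files with MD5 checksums.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return data frame manifest (`file`, `md5`), also written as
#'   `manifest.tsv`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  files <- character(0)
  fa <- file.path(dir, paste0(dataset$locus$locus_name, ".fasta"))
  write_alignment(dataset$locus, fa)
  files <- c(files, fa)
  if (!is.null(dataset$indel_locus)) {
    fa2 <- file.path(dir, paste0(dataset$indel_locus$locus_name, ".fasta"))
    write_alignment(dataset$indel_locus, fa2)
    files <- c(files, fa2)
  }
  nwk <- file.path(dir, "truth_tree.nwk")
  ape::write.tree(dataset$tree, file = nwk)
  part <- file.path(dir, "truth_partition.tsv")
  utils::write.table(data.frame(id = names(dataset$partition),
                                group = unname(dataset$partition)),
                     part, sep = "\t", quote = FALSE, row.names = FALSE)
  cfgf <- file.path(dir, "config.tsv")
  cfg <- dataset$config
  utils::write.table(
    data.frame(key = names(cfg),
               value = vapply(cfg, function(v)
                 paste(format(v, digits = 12), collapse = ","), character(1))),
    cfgf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, nwk, part, cfgf)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
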