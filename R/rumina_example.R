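#' Published COI support matrix for the Rumina land snails
#'
#' A transcription of the per-method delimitation decisions for the MOTUs of
#' *Rumina decollata* and *R. saharica* (decollate snails) from a published
#' COI barcoding study: fourteen method columns (overall and pairwise gap
#' analysis, four threshold rules, ABGD, Rosenberg's P_AB and Rodrigo's
#' P(RD) on BI and ML trees, GSI on BI and ML trees, single-threshold GMYC)
#' scored over seventeen nested MOTU hypotheses.  Each haplotype group is
#' represented by one placeholder id; the nesting declares D = Da+Db,
#' E = Ea+Eb, Ea = Ea1-2 + Ea3-4, Eb = Eb1-4 + Eb5-8, S = Sa+Sb, the two
#' nominal species, and the genus; the composite hypothesis "F+Ea1-2"
#' (MOTU F absorbing haplotypes Ea1 and Ea2) is declared as an alias.
#'
#' @return list with `support` (a [support_matrix]) and `groups` (the
#'   underlying [group_map]).
#' @examples
#' ex <- rumina_example()
#' count_species_range(ex$support, "GMYC", "Rumina")
#' @export
rumina_example <- function() {
  path <- function(f) system.file("extdata", f, package = "motudelim",
                                  mustWork = TRUE)
  groups <- read_group_map(path("rumina_groups.tsv"), path("rumina_nesting.tsv"))
  groups$aliases <- list("F+Ea1-2" = c("F", "Ea1-2"))
  cells <- utils::read.delim(path("rumina_coi_support.tsv"), row.names = 1L,
                             check.names = FALSE, colClasses = "character")
  cells[is.na(cells)] <- ""
  decisions <- lapply(stats::setNames(nm = colnames(cells)), function(mth)
    stats::setNames(cells[[mth]], rownames(cells)))
  list(support = support_matrix(decisions, groups), groups = groups)
}
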