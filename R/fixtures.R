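# Accessors for the data shipped with the package: arrangement catalogs of
# the two Polyplax rat lice (plus a synthetic reconstruction of their common
# ancestor), coding-region sizes, tRNA T-arm measurements, life-history
# values for five louse species, the fixed louse phylogeny, and the shared
# gene-arrangement (junction) characters used for ancestral-state inference.

mc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "minichrom",
                      mustWork = TRUE)
  path
}

#' Packaged arrangement catalogs of the Polyplax rat lice
#'
#' @param species `"asiatica"`, `"spinulosa"`, or `"ancestor"` (a synthetic
#'   reconstruction of the arrangement of the two species' most recent
#'   common ancestor, built from the arrangements they share with pig and
#'   human lice; it is not a sequenced genome).
#' @return [arrangement_catalog()].
#' @export
#' @examples
#' pa <- polyplax_catalog("asiatica")
#' length(pa$entries)  # 11 minichromosomes
polyplax_catalog <- function(species = c("asiatica", "spinulosa",
                                         "ancestor")) {
  species <- match.arg(species)
  file <- switch(species,
                 asiatica = "catalog_polyplax_asiatica.tsv",
                 spinulosa = "catalog_polyplax_spinulosa.tsv",
                 ancestor = "catalog_polyplax_ancestor_synthetic.tsv")
  load_catalog(mc_extdata(file))
}

#' Coding-region sizes and read support per minichromosome
#'
#' @return data frame with columns `species`, `minichrom_id`, `coding_bp`,
#'   `n_reads` for both Polyplax species.
#' @export
coding_region_sizes <- function() {
  read.delim(mc_extdata("coding_region_sizes.tsv"), comment.char = "#",
             header = FALSE,
             col.names = c("species", "minichrom_id", "coding_bp",
                           "n_reads"),
             stringsAsFactors = FALSE)
}

#' T-arm measurements of the 22 mitochondrial tRNAs
#'
#' T-stem pairs, T-loop nucleotide counts and the reported T-arm lengths
#' for both Polyplax species; the T-arm length in nt is `2 * stem + loop`.
#'
#' @return data frame with columns `trna`, `anticodon`, `pa_t_stem`,
#'   `ps_t_stem`, `pa_t_loop`, `ps_t_loop`, `pa_t_arm`, `ps_t_arm`.
#' @export
trna_arm_measurements <- function() {
  read.delim(mc_extdata("trna_t_arms.tsv"), comment.char = "#",
             header = FALSE,
             col.names = c("trna", "anticodon", "pa_t_stem", "ps_t_stem",
                           "pa_t_loop", "ps_t_loop", "pa_t_arm",
                           "ps_t_arm"),
             stringsAsFactors = FALSE)
}

#' Life-history table for five blood-sucking louse species
#'
#' Adult body length (mm) and life-cycle length (days) as (lo, hi) ranges,
#' plus mitochondrial genes per minichromosome. The Pediculus metric is a
#' catalog-provided constant and is never recomputed.
#'
#' @return data frame with columns `species`, `body_lo`, `body_hi`,
#'   `cycle_lo`, `cycle_hi`, `genes_per_mc`, `source`.
#' @export
life_history_table <- function() {
  read.delim(mc_extdata("life_history.tsv"), comment.char = "#",
             header = FALSE,
             col.names = c("species", "body_lo", "body_hi", "cycle_lo",
                           "cycle_hi", "genes_per_mc", "source"),
             stringsAsFactors = FALSE)
}

#' Fixed rooted phylogeny of the louse species
#'
#' The rat lice (Polyplax) are sister to the human lice
#' (Pediculus + Pthirus), with the pig lice (Haematopinus) as the deepest
#' split. Topology is fixed input, not estimated here.
#'
#' @return an [ape::read.tree()] `phylo` object with named internal nodes.
#' @export
louse_phylogeny <- function() {
  ape::read.tree(mc_extdata("louse_phylogeny.nwk"))
}

#' Shared gene-arrangement characters across louse species
#'
#' Presence/absence of seven minichromosome or gene-adjacency states across
#' the rat lice, human lice and pig lice, used for Dollo-style
#' ancestral-state inference.
#'
#' @return named list; each element is a character vector of species in
#'   which the state is present.
#' @export
junction_characters <- function() {
  pa <- "Polyplax_asiatica"; ps <- "Polyplax_spinulosa"
  pigs <- c("Haematopinus_suis", "Haematopinus_apri")
  humans <- c("Pediculus_humanus", "Pediculus_capitis", "Pthirus_pubis")
  list(
    `rrnS-trnC_minichromosome` = c(pa, pigs),
    `nad1-trnT-trnG-nad3-trnW` = c(pa, pigs),
    `cox3-trnA`                = c(pa, pigs, humans),
    `trnP-cox3`                = c(ps, pigs),
    `nad5-trnF`                = c(ps, pigs),
    `cox1-trnL2`               = c(pa, pigs),
    `trnL1-rrnL`               = c(pa, pigs, "Pediculus_humanus",
                                   "Pediculus_capitis")
  )
}
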