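# Fragmentation metrics and their relationship to life-history traits.
# The extent of mitochondrial genome fragmentation is summarised as the
# mean number of genes per minichromosome (lower = more fragmented).

#' Genes per minichromosome
#'
#' The fragmentation metric: number of canonical genes divided by number
#' of minichromosomes, rounded half-up to one decimal.
#'
#' @param x an [arrangement_catalog()], a [fragmented_genome()], or a
#'   gene count (with `n_minichromosomes` supplied).
#' @param n_minichromosomes minichromosome count when `x` is a number.
#' @param species species label for the record.
#' @return data frame (one row) with columns `species`, `n_genes`,
#'   `n_minichromosomes`, `genes_per_minichromosome`, `source`.
#' @export
#' @examples
#' genes_per_minichromosome(37, 11)$genes_per_minichromosome  # 3.4
genes_per_minichromosome <- function(x, n_minichromosomes = NULL,
                                     species = NULL) {
  if (inherits(x, "arrangement_catalog")) {
    genes <- unlist(lapply(x$entries, `[[`, "gene"))
    n_g <- sum(is_canonical_gene(genes))
    n_m <- length(x$entries)
    species <- species %||% x$species
  } else if (inherits(x, "fragmented_genome")) {
    n_g <- n_genes(x)
    n_m <- length(x$minichromosomes)
    species <- species %||% x$species
  } else {
    n_g <- as.integer(x)
    n_m <- as.integer(n_minichromosomes)
    species <- species %||% NA_character_
  }
  if (is.na(n_m) || n_m < 1) stop("need at least one minichromosome")
  data.frame(species = species, n_genes = n_g, n_minichromosomes = n_m,
             genes_per_minichromosome = round_half_up(n_g / n_m, 1),
             source = "computed", stringsAsFactors = FALSE)
}

#' Association between fragmentation and a life-history trait
#'
#' Converts the trait's (lo, hi) range to its midpoint and computes the
#' Spearman rank correlation (average ranks for ties) between trait
#' midpoint and genes per minichromosome, plus a concordance indicator:
#' whether the fragmentation metric is weakly monotone in the trait
#' midpoint across all records. No p-value is attached — with a handful
#' of species and tied metrics the output is descriptive.
#'
#' @param records data frame in the layout of [life_history_table()]
#'   (columns `species`, `body_lo`, `body_hi`, `cycle_lo`, `cycle_hi`,
#'   `genes_per_mc`).
#' @param trait `"life_cycle"` or `"body_length"`.
#' @return list with `trait`, `spearman_rho`, `concordant_ordering`,
#'   `midpoints` (named), `metric` (named).
#' @export
life_history_association <- function(records = life_history_table(),
                                     trait = c("life_cycle",
                                               "body_length")) {
  trait <- match.arg(trait)
  if (nrow(records) < 4) stop("need at least 4 records")
  mid <- switch(trait,
                life_cycle = (records$cycle_lo + records$cycle_hi) / 2,
                body_length = (records$body_lo + records$body_hi) / 2)
  metric <- records$genes_per_mc
  if (length(unique(mid)) < 2 || length(unique(metric)) < 2)
    stop("zero variance in trait or metric")
  rho <- cor(mid, metric, method = "spearman")
  ord <- order(mid)
  concordant <- all(diff(metric[ord]) >= 0) || all(diff(metric[ord]) <= 0)
  list(trait = trait, spearman_rho = unname(rho),
       concordant_ordering = concordant,
       midpoints = setNames(mid, records$species),
       metric = setNames(metric, records$species))
}
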