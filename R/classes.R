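# S3 containers for fragmented mitochondrial genomes.
#
# Coordinates are 0-based half-open on the circle. The origin is fixed at the
# first base of the first gene of the coding region on the reference strand,
# so the coding span is contiguous starting at 0 and the non-coding region
# follows it. `end` may exceed the sequence length to encode origin-spanning
# features (positions are taken modulo length).

#' Construct a gene annotation table
#'
#' @param name gene symbols from the canonical 37-gene vocabulary
#'   ([mt_gene_names()]), or `"pseudo-"`-prefixed for pseudogene remnants.
#' @param start,end 0-based half-open coordinates on the circular
#'   minichromosome; `end` may exceed the sequence length for features that
#'   span the origin.
#' @param orientation `"+"` or `"-"` relative to the reference strand (the
#'   strand on which the majority of genes are transcribed).
#' @param anticodon anticodon triplets (RNA alphabet) for tRNAs; filled from
#'   the vocabulary when omitted.
#' @param seq_length circular sequence length used to validate coordinates
#'   (optional).
#' @return data.frame with columns `name`, `category`, `start`, `end`,
#'   `orientation`, `anticodon`.
#' @export
gene_annotation <- function(name, start, end, orientation = "+",
                            anticodon = NULL, seq_length = NULL) {
  n <- length(name)
  orientation <- rep_len(orientation, n)
  category <- gene_category(name)
  if (anyNA(category)) {
    stop("unknown gene symbol(s): ",
         paste(name[is.na(category)], collapse = ", "))
  }
  if (is.null(anticodon)) {
    anticodon <- ifelse(category == "tRNA", trna_anticodon(name), "")
  }
  bad <- category == "tRNA" & (is.na(anticodon) | anticodon == "")
  if (any(bad)) stop("tRNA annotation without anticodon: ",
                     paste(name[bad], collapse = ", "))
  if (any(category != "tRNA" & anticodon != ""))
    stop("anticodon given for non-tRNA gene")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must exceed start")
  if (!is.null(seq_length)) {
    if (any(start >= seq_length)) stop("start must be < sequence length")
    if (any(end - start > seq_length))
      stop("feature longer than the circular sequence")
  }
  data.frame(name = name, category = category,
             start = as.integer(start), end = as.integer(end),
             orientation = orientation, anticodon = anticodon,
             stringsAsFactors = FALSE)
}

#' Construct a minichromosome
#'
#' A small circular mitochondrial chromosome consisting of a coding region
#' (its genes) and a non-coding region shared, in well-conserved form, with
#' the other minichromosomes of the same genome.
#'
#' @param id label for the minichromosome.
#' @param sequence circular nucleotide sequence over ACGT, or `NA` in
#'   catalog-only (sequence-free) mode.
#' @param genes a [gene_annotation()] data frame (may be empty).
#' @param coding_span,noncoding_span 0-based half-open intervals
#'   `c(start, end)` on the circle; when both are given they must partition
#'   the circle.
#' @return object of class `minichromosome`.
#' @export
minichromosome <- function(id, sequence = NA_character_,
                           genes = gene_annotation(character(0), integer(0),
                                                   integer(0))[0, ],
                           coding_span = NULL, noncoding_span = NULL) {
  len <- if (is.na(sequence)) NA_integer_ else nchar(sequence)
  if (!is.na(sequence)) {
    if (grepl("[^ACGT]", sequence)) stop("sequence must be over {A,C,G,T}")
    if (nrow(genes)) {
      if (any(genes$start >= len)) stop("gene start beyond sequence length")
      if (any(genes$end - genes$start > len))
        stop("gene longer than the circle")
    }
  }
  if (!is.null(coding_span) && !is.null(noncoding_span) && !is.na(len)) {
    covered <- (coding_span[2] - coding_span[1]) +
      (noncoding_span[2] - noncoding_span[1])
    if (covered != len)
      stop("coding and non-coding spans must partition the circle")
  }
  structure(list(id = id, sequence = sequence, genes = genes,
                 coding_span = coding_span, noncoding_span = noncoding_span),
            class = "minichromosome")
}

#' Construct a fragmented mitochondrial genome
#'
#' @param species species label.
#' @param minichromosomes list of [minichromosome()] objects.
#' @param complete if `TRUE`, require all 37 canonical genes exactly once.
#' @return object of class `fragmented_genome`.
#' @export
fragmented_genome <- function(species, minichromosomes, complete = FALSE) {
  genes <- unlist(lapply(minichromosomes, function(m) {
    m$genes$name[m$genes$category != "pseudogene"]
  }))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("gene(s) present on more than one minichromosome: ",
         paste(dup, collapse = ", "))
  }
  if (complete && !setequal(genes, mt_gene_names())) {
    stop("genome flagged complete but missing: ",
         paste(setdiff(mt_gene_names(), genes), collapse = ", "))
  }
  names(minichromosomes) <- vapply(minichromosomes, `[[`, "", "id")
  structure(list(species = species, minichromosomes = minichromosomes),
            class = "fragmented_genome")
}

#' @export
print.minichromosome <- function(x, ...) {
  len <- if (is.na(x$sequence)) "no sequence" else paste0(nchar(x$sequence), " bp")
  cat("<minichromosome> ", x$id, " (", len, ", ",
      nrow(x$genes), " genes)\n", sep = "")
  invisible(x)
}

#' @export
print.fragmented_genome <- function(x, ...) {
  ng <- sum(vapply(x$minichromosomes, function(m)
    sum(m$genes$category != "pseudogene"), 0L))
  cat("<fragmented_genome> ", x$species, ": ",
      length(x$minichromosomes), " minichromosomes, ", ng, " genes\n",
      sep = "")
  invisible(x)
}

# Number of canonical (non-pseudo) genes in a genome.
n_genes <- function(genome) {
  sum(vapply(genome$minichromosomes, function(m)
    sum(m$genes$category != "pseudogene"), 0L))
}
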