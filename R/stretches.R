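# Shared identical stretches between genes: the recombination-length
# signal. Pairs of mitochondrial genes that share identical stretches
# several times longer than expected by chance are candidate traces of
# recombination between genes and between minichromosomes.

#' Longest identical stretch shared by two sequences
#'
#' Exact longest common substring by dynamic programming; ties are broken
#' by the smallest `(pos_a, pos_b)` pair. With `search_revcomp`, the
#' reverse complement of `b` is also scanned and the overall maximum
#' returned.
#'
#' @param a,b nucleotide sequences (character).
#' @param search_revcomp also search `b`'s reverse complement.
#' @param mask_primary re-run the search once with the primary match masked
#'   and also return the longest secondary stretch (for multi-stretch
#'   reports).
#' @return list with `length`, `pos_a`, `pos_b` (0-based starts;
#'   `strand_b` is `"-"` when the reverse-complement search won), and, if
#'   requested, `secondary` (the same triple for the masked re-run).
#' @export
longest_shared_stretch <- function(a, b, search_revcomp = FALSE,
                                   mask_primary = FALSE) {
  if (!nchar(a) || !nchar(b)) stop("empty input sequence")
  hit <- lcs_pair(a, b)
  strand <- "+"
  if (search_revcomp) {
    rc <- revcomp(b)
    hit_rc <- lcs_pair(a, rc)
    if (hit_rc$length > hit$length) {
      hit <- hit_rc
      strand <- "-"
    }
  }
  out <- list(length = hit$length, pos_a = hit$start_a,
              pos_b = hit$start_b, strand_b = strand)
  if (mask_primary && hit$length > 0) {
    am <- a; bm <- if (strand == "+") b else revcomp(b)
    substr(am, hit$start_a + 1L, hit$start_a + hit$length) <-
      paste(rep("#", hit$length), collapse = "")
    substr(bm, hit$start_b + 1L, hit$start_b + hit$length) <-
      paste(rep("$", hit$length), collapse = "")
    sec <- lcs_pair(am, bm)
    out$secondary <- list(length = sec$length, pos_a = sec$start_a,
                          pos_b = sec$start_b)
  }
  out
}

#' Monte-Carlo null distribution of the longest shared stretch
#'
#' Chance baseline for [longest_shared_stretch()]: the distribution of the
#' longest identical stretch between two independent random sequences of
#' matched lengths and base composition. Matching composition (rather than
#' shuffling the originals) controls the dominant driver of chance
#' matches.
#'
#' @param len_a,len_b sequence lengths (at least 10).
#' @param base_composition per-base probabilities, named `A`,`C`,`G`,`T`.
#' @param reps Monte-Carlo replicates (at least 100).
#' @param seed integer seed; the distribution is reproducible for a given
#'   seed on any platform.
#' @return list with `mean`, `q95` (95th percentile, type-1 quantile) and
#'   `distribution` (the `reps` longest-stretch lengths).
#' @export
null_longest_stretch <- function(len_a, len_b,
                                 base_composition = c(A = 0.25, C = 0.25,
                                                      G = 0.25, T = 0.25),
                                 reps = 1000, seed = 1L) {
  if (reps < 100) stop("reps must be at least 100")
  if (len_a < 2 || len_b < 2) stop("lengths must be at least 2")
  p <- base_composition[c("A", "C", "G", "T")]
  if (anyNA(p)) stop("base_composition must be named A, C, G, T")
  if (sum(p > 0) < 2)
    stop("degenerate base composition (single base)")
  d <- lcs_null_distribution(as.integer(len_a), as.integer(len_b),
                             as.numeric(p), as.integer(reps),
                             as.integer(seed))
  list(mean = mean(d), q95 = as.numeric(quantile(d, 0.95, type = 1)),
       distribution = d)
}

#' Scan all gene pairs of a genome for shared stretches
#'
#' Computes the longest identical stretch for every unordered pair of
#' canonical genes, calibrates a chance expectation per pair by
#' Monte-Carlo over composition-matched random sequences, and flags pairs
#' whose observed stretch is at least `fold_flag` times the null mean or
#' exceeds the null 95th percentile. Null distributions are cached across
#' pairs with equal lengths and (rounded) composition.
#'
#' @param genome an annotated [fragmented_genome()] with sequences, or a
#'   `generate_genome()` result.
#' @param reps Monte-Carlo replicates per null distribution.
#' @param seed integer seed.
#' @param search_revcomp also search reverse complements.
#' @param fold_flag fold-over-chance threshold for flagging.
#' @return data frame with one row per gene pair, columns `gene_a`,
#'   `gene_b`, `observed_len`, `pos_a`, `pos_b`, `null_mean`, `null_q95`,
#'   `fold`, `flagged`, sorted by decreasing `fold`.
#' @export
scan_gene_pairs <- function(genome, reps = 200, seed = 1L,
                            search_revcomp = FALSE, fold_flag = 2.0) {
  seqs <- gene_sense_sequences(genome)
  if (!length(seqs)) stop("genome carries no gene sequences")
  genes <- names(seqs)
  pairs <- utils::combn(genes, 2)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    sa <- seqs[[ga]]; sb <- seqs[[gb]]
    obs <- longest_shared_stretch(sa, sb, search_revcomp = search_revcomp)
    comp <- pooled_composition(sa, sb)
    key <- paste(nchar(sa), nchar(sb),
                 paste(round(comp, 2), collapse = ","), sep = "|")
    if (!exists(key, envir = cache, inherits = FALSE)) {
      nul <- null_longest_stretch(nchar(sa), nchar(sb), comp, reps = reps,
                                  seed = derive_seed(seed, i))
      assign(key, nul, envir = cache)
    }
    nul <- get(key, envir = cache)
    fold <- obs$length / nul$mean
    rows[[i]] <- data.frame(
      gene_a = ga, gene_b = gb, observed_len = obs$length,
      pos_a = obs$pos_a, pos_b = obs$pos_b,
      null_mean = nul$mean, null_q95 = nul$q95, fold = fold,
      flagged = (fold >= fold_flag) | (obs$length > nul$q95),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(-out$fold, out$gene_a, out$gene_b), ]
}

# Named sense-strand gene sequences of an annotated genome (canonical genes
# only, pseudogenes excluded).
gene_sense_sequences <- function(genome) {
  if (!is.null(genome$truth) &&
      !is.null(genome$truth$reference_genes)) {
    refs <- genome$truth$reference_genes
    return(refs[!startsWith(names(refs), "pseudo-")])
  }
  if (!is.null(genome$genome)) genome <- genome$genome
  out <- list()
  for (m in genome$minichromosomes) {
    if (!nrow(m$genes) || is.na(m$sequence)) next
    d <- paste0(m$sequence, m$sequence)
    g <- m$genes[m$genes$category != "pseudogene", , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      s <- substr(d, g$start[i] + 1L, g$end[i])
      if (g$orientation[i] == "-") s <- revcomp(s)
      out[[g$name[i]]] <- s
    }
  }
  unlist(out)
}

pooled_composition <- function(a, b) {
  bases <- strsplit(paste0(a, b), "")[[1]]
  counts <- table(factor(bases, levels = c("A", "C", "G", "T")))
  p <- as.numeric(counts) / length(bases)
  names(p) <- c("A", "C", "G", "T")
  # guard against degenerate compositions in the null sampler
  p <- pmax(p, 0.01)
  p / sum(p)
}

#' Write a shared-stretch report to TSV
#'
#' @param report data frame from [scan_gene_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stretch_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# minichrom shared-stretch report"), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
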