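# Desk-scale greedy overlap-layout assembler for circular minichromosomes.
# Assembly parameters default to minimum overlap 50 bp at minimum overlap
# identity 98%, the settings used for the louse minichromosome amplicon
# reads this package models. Overlap identity is computed on an ungapped
# suffix-prefix alignment (substitutions only, no indels), which matches the
# substitution-only read simulator; a documented limitation for real data.

#' Assemble short reads into (circular) contigs
#'
#' Greedy overlap-layout-consensus: the pair of contigs with the longest
#' suffix-prefix overlap of at least `min_overlap` bases and at least
#' `min_identity` ungapped identity is merged first (both strands are
#' considered), with per-position majority-vote consensus, until no merge
#' qualifies. Contigs whose prefix and suffix overlap are then trimmed and
#' flagged circular (see [circularize()]). The procedure is deterministic
#' and independent of read order: reads are deduplicated onto a canonical
#' strand and ties are broken by the lexicographically smaller merged
#' sequence.
#'
#' @param reads character vector of reads, or a `Biostrings::DNAStringSet`,
#'   or a path to a FASTQ/FASTA file.
#' @param min_overlap minimum suffix-prefix overlap in bases.
#' @param min_identity minimum overlap identity (fraction).
#' @param circularize also run the circularity check on each contig.
#' @return list of contigs; each is a list with `sequence`, `circular`,
#'   `n_reads`, of class `contig`.
#' @export
assemble <- function(reads, min_overlap = 50, min_identity = 0.98,
                     circularize = TRUE) {
  reads <- as_read_strings(reads)
  if (!length(reads)) stop("empty read set")
  if (min_overlap >= max(nchar(reads)))
    stop("min_overlap must be shorter than the reads")
  raw <- assemble_reads(reads, as.integer(min_overlap), min_identity)
  contigs <- lapply(raw, function(x) {
    # In well-covered assemblies, trim single-read tips: their consensus
    # may carry read errors that would mask the terminal redundancy of a
    # circular contig. Shallow assemblies are left untouched.
    s <- x$sequence
    sup <- x$support
    n <- nchar(s)
    if (stats::median(sup) >= 5) {
      lo <- 1L
      while (lo <= min(30L, n) && sup[lo] < 2) lo <- lo + 1L
      hi <- n
      while (hi >= max(n - 30L, lo) && sup[hi] < 2) hi <- hi - 1L
      if (lo > 1L || hi < n) s <- substr(s, lo, hi)
    }
    structure(list(sequence = s, circular = FALSE,
                   n_reads = x$n_reads), class = "contig")
  })
  if (circularize) {
    contigs <- lapply(contigs, minichrom::circularize,
                      min_overlap = min_overlap,
                      min_identity = min_identity)
  }
  contigs
}

#' Circularity check for a contig
#'
#' If the contig's prefix and suffix overlap by at least `min_overlap` bases
#' at `min_identity` or better, the terminal redundancy is trimmed and the
#' contig is marked circular; otherwise it is returned unchanged. This is
#' the in-silico analogue of verifying a minichromosome's circular
#' organisation with outbound primers.
#'
#' @param contig a `contig` (from [assemble()]) or a character sequence.
#' @param min_overlap minimum self-overlap in bases.
#' @param min_identity minimum overlap identity.
#' @return a `contig` object.
#' @export
circularize <- function(contig, min_overlap = 50, min_identity = 0.98) {
  if (is.character(contig)) {
    contig <- structure(list(sequence = contig, circular = FALSE,
                             n_reads = NA_real_), class = "contig")
  }
  if (isTRUE(contig$circular)) return(contig)
  res <- circularize_contig(contig$sequence, as.integer(min_overlap),
                            min_identity)
  contig$sequence <- res$sequence
  contig$circular <- res$circular
  contig
}

#' @export
print.contig <- function(x, ...) {
  cat("<contig> ", nchar(x$sequence), " bp, ",
      if (isTRUE(x$circular)) "circular" else "linear",
      if (!is.na(x$n_reads)) paste0(", ", x$n_reads, " reads") else "",
      "\n", sep = "")
  invisible(x)
}

# Accept character vectors, DNAStringSet or FASTA/FASTQ paths.
as_read_strings <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    set <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE)) {
      Biostrings::readDNAStringSet(reads, format = "fastq")
    } else {
      Biostrings::readDNAStringSet(reads)
    }
    return(as.character(set))
  }
  if (methods::is(reads, "DNAStringSet")) return(as.character(reads))
  as.character(reads)
}

#' Write contigs to FASTA
#'
#' Headers carry `circular=true|false` and the read support, mirroring the
#' convention used for minichromosome sequences.
#'
#' @param contigs list of `contig` objects.
#' @param path output FASTA path.
#' @param prefix contig name prefix.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path, prefix = "contig") {
  seqs <- Biostrings::DNAStringSet(vapply(contigs, `[[`, "", "sequence"))
  names(seqs) <- sprintf("%s_%d|circular=%s|length=%d|reads=%s",
                         prefix, seq_along(contigs),
                         ifelse(vapply(contigs, `[[`, TRUE, "circular"),
                                "true", "false"),
                         nchar(vapply(contigs, `[[`, "", "sequence")),
                         vapply(contigs, function(x)
                           format(x$n_reads), ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
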