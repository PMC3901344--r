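# Annotation of minichromosomes: coding/non-coding partition by conserved
# k-mer blocks, compositional motif detection, gene identification by
# best-hit similarity against a reference gene set, exhaustive cloverleaf
# folding of tRNAs, T-arm summary tables, and pseudogene-remnant detection.

# --- coding / non-coding partition ----------------------------------------

#' Partition each minichromosome into coding and non-coding regions
#'
#' The non-coding region (NCR) is the segment shared, in well-conserved
#' form, across the minichromosomes of one genome, while coding regions are
#' distinct. Conserved blocks are found by exact k-mer anchoring: a
#' position is conserved when its k-mer occurs in at least half of the
#' minichromosomes; covered positions are merged into blocks tolerating
#' short gaps (substitution breaks in the conserved region), and the
#' largest block system on each circle is its NCR. The complement is the
#' coding span.
#'
#' @param genome a [fragmented_genome()] with sequences (at least 2
#'   minichromosomes).
#' @param k k-mer length for anchoring.
#' @param max_gap largest gap (bases) bridged when merging conserved
#'   blocks.
#' @param min_block minimum NCR length; below it the partition fails.
#' @return the genome with `coding_span`/`noncoding_span` set on every
#'   minichromosome (0-based half-open; the non-coding span may extend past
#'   the sequence length when it wraps the origin).
#' @export
partition_coding_noncoding <- function(genome, k = 15, max_gap = 60,
                                       min_block = 200) {
  if (!is.null(genome$genome)) genome <- genome$genome
  mcs <- genome$minichromosomes
  n <- length(mcs)
  if (n < 2) stop("need at least 2 minichromosomes to find the shared NCR")
  lens <- vapply(mcs, function(m) nchar(m$sequence), 0L)
  kmers_of <- lapply(mcs, function(m) {
    d <- paste0(m$sequence, m$sequence)
    unique(substring(d, 1:nchar(m$sequence),
                     (1:nchar(m$sequence)) + k - 1L))
  })
  tab <- table(unlist(kmers_of))
  need <- max(2, ceiling(n / 2))  # a k-mer always occurs in its own circle
  shared <- names(tab)[tab >= need]
  shared_set <- new.env(hash = TRUE, parent = emptyenv())
  for (s in shared) assign(s, TRUE, envir = shared_set)
  out <- lapply(seq_len(n), function(i) {
    m <- mcs[[i]]
    len <- lens[i]
    d <- paste0(m$sequence, m$sequence)
    starts <- 1:len
    kms <- substring(d, starts, starts + k - 1L)
    hit <- vapply(kms, function(x)
      exists(x, envir = shared_set, inherits = FALSE), TRUE)
    # mark covered bases on the doubled circle, then find the best run
    cov <- logical(2L * len)
    for (p in which(hit)) cov[p:(p + k - 1L)] <- TRUE
    runs <- best_gapped_run(cov, max_gap, len)
    if (is.null(runs) || runs$length < min_block)
      stop("no shared non-coding region found (no conserved block >= ",
           min_block, " bp)")
    if (runs$length >= len)
      stop("minichromosomes are conserved over the whole circle; ",
           "no distinct coding region")
    s0 <- (runs$start - 1L) %% len          # 0-based NCR start
    e0 <- s0 + runs$length                  # may exceed len (wraps)
    m$noncoding_span <- c(s0, e0)
    m$coding_span <- c(e0 %% len, e0 %% len + (len - runs$length))
    m
  })
  genome$minichromosomes <- out
  names(genome$minichromosomes) <-
    vapply(out, `[[`, "", "id")
  genome
}

# Longest run of TRUE values in `cov` (doubled-circle logical vector),
# bridging gaps of at most `max_gap` FALSEs, capped at circle length `len`.
# Returns list(start, length) with start a 1-based index into `cov`.
best_gapped_run <- function(cov, max_gap, len) {
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_idx <- which(r$values)
  if (!length(true_idx)) return(NULL)
  best <- NULL
  for (a in true_idx) {
    b <- a
    while (b + 2L <= length(r$lengths) && r$values[b + 2L] &&
           r$lengths[b + 1L] <= max_gap &&
           (ends[b + 2L] - starts[a] + 1L) <= len) {
      b <- b + 2L
    }
    run_len <- min(ends[b] - starts[a] + 1L, len)
    if (is.null(best) || run_len > best$length) {
      best <- list(start = starts[a], length = run_len)
    }
  }
  best
}

# --- compositional motifs --------------------------------------------------

#' Find AT-rich and GC-rich motifs flanking the coding region
#'
#' Scans the non-coding region windows adjacent to the two coding
#' boundaries: the maximal window touching the coding 5' end with AT
#' fraction at least `at_min`, and the maximal window touching the coding
#' 3' end with GC fraction at least `gc_min`, each at least `min_len`
#' bases. Thresholds default to values that admit the weakest motif
#' observed in the rat lice (a 57% GC motif).
#'
#' @param m a [minichromosome()] with spans set (see
#'   [partition_coding_noncoding()]).
#' @param at_min,gc_min composition thresholds.
#' @param min_len minimum motif length in bases.
#' @return data frame with columns `side` (`"upstream_AT"`,
#'   `"downstream_GC"`), `start`, `end` (0-based half-open on the circle,
#'   `end` may exceed the length), `length`, `fraction`; zero rows for
#'   absent motifs.
#' @export
find_compositional_motifs <- function(m, at_min = 0.60, gc_min = 0.55,
                                      min_len = 50) {
  if (is.null(m$coding_span) || is.null(m$noncoding_span))
    stop("spans not set; run partition_coding_noncoding() first")
  len <- nchar(m$sequence)
  ns <- m$noncoding_span[1]; ne <- m$noncoding_span[2]
  d <- paste0(m$sequence, m$sequence)
  ncr <- substr(d, ns + 1L, ne)           # NCR sequence, 5'->3'
  nl <- nchar(ncr)
  bases <- strsplit(ncr, "")[[1]]
  is_at <- bases %in% c("A", "T")
  hits <- list()
  # upstream AT motif: suffix of the NCR, touching the coding 5' boundary
  cum_at_rev <- cumsum(rev(is_at))
  L <- seq_len(nl)
  frac_suffix <- cum_at_rev / L
  ok <- which(frac_suffix >= at_min & L >= min_len)
  if (length(ok)) {
    Lbest <- max(ok)
    hits[[length(hits) + 1]] <- data.frame(
      side = "upstream_AT", start = (ne - Lbest) %% len,
      end = (ne - Lbest) %% len + Lbest, length = Lbest,
      fraction = frac_suffix[Lbest], stringsAsFactors = FALSE)
  }
  # downstream GC motif: prefix of the NCR, touching the coding 3' boundary
  cum_gc <- cumsum(!is_at)
  frac_prefix <- cum_gc / L
  ok <- which(frac_prefix >= gc_min & L >= min_len)
  if (length(ok)) {
    Lbest <- max(ok)
    hits[[length(hits) + 1]] <- data.frame(
      side = "downstream_GC", start = ns %% len,
      end = ns %% len + Lbest, length = Lbest,
      fraction = frac_prefix[Lbest], stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(side = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      fraction = numeric(0)))
  }
  do.call(rbind, hits)
}

# --- gene identification ---------------------------------------------------

#' Identify genes on a circular sequence by reference similarity
#'
#' Each reference gene is located by best-hit similarity on the circular
#' sequence (both strands): a gene is called when a local alignment reaches
#' `min_identity` identity over at least `min_coverage` of the reference
#' length, at the best-scoring location and strand. Overlapping calls are
#' resolved by score. Exact matches are found by fast string search;
#' diverged genes fall back to local pairwise alignment.
#'
#' @param sequence circular nucleotide sequence (character).
#' @param reference named character vector of sense-strand reference gene
#'   sequences, one per canonical gene.
#' @param min_identity minimum alignment identity.
#' @param min_coverage minimum aligned fraction of the reference length.
#' @return a [gene_annotation()] data frame (0-based circular coordinates,
#'   sorted by start), with additional columns `identity` and `score`.
#' @export
assign_gene_identity <- function(sequence, reference, min_identity = 0.70,
                                 min_coverage = 0.60) {
  if (!length(reference) || is.null(names(reference)))
    stop("reference must be a named vector of gene sequences")
  len <- nchar(sequence)
  d <- Biostrings::DNAString(paste0(sequence, sequence))
  calls <- list()
  for (g in names(reference)) {
    ref <- reference[[g]]
    hit <- locate_gene(d, ref, len)
    if (is.null(hit)) next
    cov <- hit$ref_span / nchar(ref)
    if (hit$identity < min_identity || cov < min_coverage) next
    calls[[length(calls) + 1]] <- data.frame(
      name = g, start = hit$start, end = hit$end,
      orientation = hit$orientation, identity = hit$identity,
      score = hit$score, stringsAsFactors = FALSE)
  }
  if (!length(calls)) {
    ann <- gene_annotation(character(0), integer(0), integer(0))
    ann$identity <- numeric(0); ann$score <- numeric(0)
    return(ann)
  }
  df <- do.call(rbind, calls)
  # resolve overlaps by score: greedily accept best-scoring calls that do
  # not overlap an accepted call by more than half their length
  df <- df[order(-df$score), , drop = FALSE]
  accepted <- list()
  for (i in seq_len(nrow(df))) {
    cand <- df[i, ]
    clash <- FALSE
    for (a in accepted) {
      ov <- circular_overlap(cand$start, cand$end, a$start, a$end, len)
      if (ov > 0.5 * (cand$end - cand$start)) { clash <- TRUE; break }
    }
    if (!clash) accepted[[length(accepted) + 1]] <- cand
  }
  df <- do.call(rbind, accepted)
  df <- df[order(df$start), , drop = FALSE]
  ann <- gene_annotation(df$name, df$start, df$end, df$orientation,
                         seq_length = len)
  ann$identity <- df$identity
  ann$score <- df$score
  rownames(ann) <- NULL
  ann
}

# Overlap in bases between two arcs on a circle of length len (intervals
# 0-based half-open, end may exceed len).
circular_overlap <- function(s1, e1, s2, e2, len) {
  ov <- 0
  for (shift in c(-len, 0, len)) {
    ov <- max(ov, min(e1, e2 + shift) - max(s1, s2 + shift))
  }
  max(ov, 0)
}

# Locate one reference gene on the doubled circle `d` (DNAString). Returns
# coordinates of the best hit with start in [0, len), or NULL.
locate_gene <- function(d, ref, len) {
  refs <- list(`+` = Biostrings::DNAString(ref),
               `-` = Biostrings::reverseComplement(
                 Biostrings::DNAString(ref)))
  # fast path: exact occurrence
  for (ori in c("+", "-")) {
    hits <- Biostrings::matchPattern(refs[[ori]], d)
    if (length(hits)) {
      st <- BiocGenerics::start(hits)[BiocGenerics::start(hits) <= len][1]
      if (!is.na(st)) {
        return(list(start = st - 1L, end = st - 1L + nchar(ref),
                    orientation = ori, identity = 1,
                    ref_span = nchar(ref), score = 2 * nchar(ref)))
      }
    }
  }
  # slow path: local alignment on either strand
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  best <- NULL
  for (ori in c("+", "-")) {
    aln <- Biostrings::pairwiseAlignment(refs[[ori]], d, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 6, gapExtension = 3)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$sc) {
      sub_rng <- Biostrings::subject(aln)
      pat_rng <- Biostrings::pattern(aln)
      st <- BiocGenerics::start(sub_rng@range) - 1L
      en <- BiocGenerics::end(sub_rng@range)
      pid <- Biostrings::pid(aln, type = "PID1") / 100
      best <- list(sc = sc, start = st %% len,
                   end = st %% len + (en - st),
                   orientation = ori, identity = pid,
                   ref_span = BiocGenerics::width(pat_rng@range),
                   score = sc)
    }
  }
  if (is.null(best) || best$sc <= 0) return(NULL)
  best
}

# --- cloverleaf folding ----------------------------------------------------

is_base_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}
is_wc_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Fold a tRNA gene into a cloverleaf
#'
#' Exhaustive search over cloverleaf decompositions: acceptor stem 6-7
#' pairs, D-stem 3-4 pairs with a 3-10 nt D-loop, anticodon stem 4-5 pairs
#' with a 7-nt loop, 3-6 nt variable region, and T-stem 3-8 pairs with a
#' 3-11 nt T-loop. The wide T-arm bounds accommodate the aberrant tRNAs of
#' louse mitochondria. Watson-Crick and G-U pairs are allowed in stems;
#' every stem position must pair. Among valid decompositions the one with
#' the most pairs wins (ties: more Watson-Crick pairs, then the smallest
#' T-stem).
#'
#' @param seq tRNA gene sequence, sense strand, DNA alphabet, 50-90 nt.
#' @return a `trna_structure` list with per-arm stem/loop lengths, the
#'   anticodon (RNA alphabet, centre of the anticodon loop), and
#'   `t_arm = 2 * t_stem + t_loop`; or `NULL` when no valid cloverleaf
#'   exists.
#' @export
fold_trna <- function(seq) {
  n <- nchar(seq)
  if (n < 50 || n > 90)
    stop("sequence length ", n, " outside the tRNA range [50, 90]")
  b <- strsplit(seq, "")[[1]]
  best <- NULL
  for (acc in 6:7) for (ds in 3:4) for (dl in 3:10) for (acs in 4:5)
    for (vr in 3:6) for (ts in 3:8) {
      tl <- n - (2L * acc + 2L * ds + dl + 2L * acs + 7L + vr + 2L * ts)
      if (tl < 3 || tl > 11) next
      # positions (1-based) of the paired regions
      p <- 0L
      acc5 <- p + seq_len(acc); p <- p + acc
      d5 <- p + seq_len(ds); p <- p + ds + dl
      d3 <- p + seq_len(ds); p <- p + ds
      ac5 <- p + seq_len(acs); p <- p + acs
      loop_start <- p
      p <- p + 7L
      ac3 <- p + seq_len(acs); p <- p + acs + vr
      t5 <- p + seq_len(ts); p <- p + ts + tl
      t3 <- p + seq_len(ts); p <- p + ts
      acc3 <- p + seq_len(acc)
      pair_idx <- rbind(cbind(acc5, rev(acc3)), cbind(d5, rev(d3)),
                        cbind(ac5, rev(ac3)), cbind(t5, rev(t3)))
      x <- b[pair_idx[, 1]]; y <- b[pair_idx[, 2]]
      if (!all(is_base_pair(x, y))) next
      total <- nrow(pair_idx)
      wc <- sum(is_wc_pair(x, y))
      cand <- list(total = total, wc = wc, acc_stem = acc, d_stem = ds,
                   d_loop = dl, ac_stem = acs, ac_loop = 7L, var = vr,
                   t_stem = ts, t_loop = tl,
                   anticodon = chartr("T", "U",
                                      paste(b[loop_start + 3:5],
                                            collapse = "")))
      if (is.null(best) || cand$total > best$total ||
          (cand$total == best$total && cand$wc > best$wc) ||
          (cand$total == best$total && cand$wc == best$wc &&
           cand$t_stem < best$t_stem)) {
        best <- cand
      }
    }
  if (is.null(best)) return(NULL)
  structure(list(
    acceptor = list(stem_pairs = best$acc_stem),
    d_arm = list(stem_pairs = best$d_stem, loop_nt = best$d_loop),
    anticodon_arm = list(stem_pairs = best$ac_stem, loop_nt = 7L),
    variable_nt = best$var,
    t_arm = list(stem_pairs = best$t_stem, loop_nt = best$t_loop,
                 arm_nt = 2L * best$t_stem + best$t_loop),
    anticodon = best$anticodon,
    n_pairs = best$total, n_wc_pairs = best$wc),
    class = "trna_structure")
}

#' @export
print.trna_structure <- function(x, ...) {
  cat("<trna_structure> anticodon ", x$anticodon,
      "; T-arm ", x$t_arm$arm_nt, " nt (stem ", x$t_arm$stem_pairs,
      " pairs, loop ", x$t_arm$loop_nt, " nt)\n", sep = "")
  invisible(x)
}

# --- T-arm summary table ---------------------------------------------------

#' Summarise T-arm architecture over the 22 tRNAs
#'
#' Builds the per-tRNA table of T-stem pairs, T-loop nucleotides and T-arm
#' length (`2 * stem + loop`), with `Total` column sums and `Mean`
#' (total / 22, rounded half-up to 1 decimal).
#'
#' @param x either a data frame with columns `trna`, `t_stem`, `t_loop`,
#'   or a named list of `trna_structure` objects (names are tRNA symbols).
#' @return data frame with rows for each tRNA plus `Total` and `Mean`,
#'   columns `trna`, `t_stem`, `t_loop`, `t_arm`.
#' @export
tarm_table <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- data.frame(
      trna = names(x),
      t_stem = vapply(x, function(s) s$t_arm$stem_pairs, 0L),
      t_loop = vapply(x, function(s) s$t_arm$loop_nt, 0L),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(x$trna))
    stop("duplicate tRNA name: ", x$trna[duplicated(x$trna)][1])
  x$t_arm <- 2L * x$t_stem + x$t_loop
  n <- nrow(x)
  tot <- data.frame(trna = "Total", t_stem = sum(x$t_stem),
                    t_loop = sum(x$t_loop), t_arm = sum(x$t_arm))
  mn <- data.frame(trna = "Mean",
                   t_stem = round_half_up(sum(x$t_stem) / n, 1),
                   t_loop = round_half_up(sum(x$t_loop) / n, 1),
                   t_arm = round_half_up(sum(x$t_arm) / n, 1))
  rbind(x[, c("trna", "t_stem", "t_loop", "t_arm")], tot, mn)
}

# --- pseudogene detection --------------------------------------------------

#' Detect a pseudogene remnant in an intergenic sequence
#'
#' Aligns a functional gene locally against an intergenic region and
#' reports hits whose aligned span reaches `min_len` bases at `min_identity`
#' or better — the signature of a truncated, degenerate gene copy left at
#' an ancestral site after a translocation.
#'
#' @param intergenic intergenic nucleotide sequence (character).
#' @param gene functional gene sequence (character).
#' @param min_len minimum aligned span in bases.
#' @param min_identity minimum alignment identity.
#' @return data frame with columns `start`, `end` (0-based half-open in
#'   the intergenic sequence), `length`, `identity`; zero rows if no hit.
#' @export
detect_pseudogene <- function(intergenic, gene, min_len = 40,
                              min_identity = 0.6) {
  if (!nchar(intergenic) || !nchar(gene))
    stop("both sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(gene), Biostrings::DNAString(intergenic),
    type = "local", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 3)
  rng <- Biostrings::subject(aln)@range
  span <- BiocGenerics::width(rng)
  ident <- Biostrings::pid(aln, type = "PID1") / 100
  if (!length(span) || span < min_len || ident < min_identity ||
      Biostrings::score(aln) <= 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), identity = numeric(0)))
  }
  data.frame(start = BiocGenerics::start(rng) - 1L,
             end = BiocGenerics::end(rng),
             length = span, identity = ident)
}

# --- whole-genome annotation ----------------------------------------------

#' Annotate assembled circular contigs into a fragmented genome
#'
#' Runs the annotation stages on a set of circular contigs: genes are
#' identified by reference similarity on both strands, each contig is
#' flipped to the strand carrying the majority of its genes (the reference
#' strand) and rotated so its first gene starts the coordinate system, and
#' coding/non-coding spans are set from the gene extent.
#'
#' @param contigs list of circular `contig` objects (see [assemble()]) or
#'   character sequences.
#' @param reference named character vector of sense-strand gene sequences.
#' @param species label for the resulting genome.
#' @param min_identity,min_coverage thresholds for
#'   [assign_gene_identity()].
#' @return a [fragmented_genome()] with annotations and spans.
#' @export
annotate_genome <- function(contigs, reference, species = "assembled",
                            min_identity = 0.70, min_coverage = 0.60) {
  seqs <- vapply(contigs, function(x)
    if (is.character(x)) x else x$sequence, "")
  mcs <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    len <- nchar(s)
    ann <- assign_gene_identity(s, reference, min_identity, min_coverage)
    if (!nrow(ann)) {
      mcs[[length(mcs) + 1]] <- minichromosome(sprintf("contig_%d", i), s)
      next
    }
    if (sum(ann$orientation == "-") > sum(ann$orientation == "+")) {
      # flip to the reference strand
      s <- revcomp(s)
      new_start <- (len - ann$end) %% len
      ann <- data.frame(name = ann$name, category = ann$category,
                        start = as.integer(new_start),
                        end = as.integer(new_start + (ann$end - ann$start)),
                        orientation = ifelse(ann$orientation == "+",
                                             "-", "+"),
                        anticodon = ann$anticodon,
                        stringsAsFactors = FALSE)
    }
    ann <- ann[order(ann$start), , drop = FALSE]
    # rotate the circle so the first gene begins at the origin; "first" is
    # the gene following the largest annotation gap (the NCR)
    gaps <- (c(ann$start[-1], ann$start[1] + len) - ann$end)
    first <- (which.max(gaps) %% nrow(ann)) + 1L
    origin <- ann$start[first]
    s <- rotate_seq(s, origin + 1L)
    widths <- ann$end - ann$start
    ann$start <- (ann$start - origin) %% len
    ann$end <- ann$start + widths
    ann <- ann[order(ann$start), , drop = FALSE]
    coding_end <- max(ann$end)
    genes <- gene_annotation(ann$name, ann$start, ann$end,
                             ann$orientation, seq_length = len)
    mcs[[length(mcs) + 1]] <- minichromosome(
      sprintf("contig_%d", i), s, genes,
      coding_span = c(0L, as.integer(coding_end)),
      noncoding_span = c(as.integer(coding_end), len))
  }
  fragmented_genome(species, mcs)
}

#' Write genome annotations as GFF3
#'
#' Emits one `##sequence-region` directive per minichromosome with
#' `Is_circular=true`, followed by gene features (1-based GFF
#' coordinates).
#'
#' @param genome annotated [fragmented_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  lines <- c("##gff-version 3")
  for (m in genome$minichromosomes) {
    len <- nchar(m$sequence)
    lines <- c(lines,
               sprintf("##sequence-region %s 1 %d", m$id, len),
               sprintf("# %s Is_circular=true", m$id))
    if (nrow(m$genes)) {
      g <- m$genes
      type <- c(PCG = "gene", rRNA = "rRNA", tRNA = "tRNA",
                pseudogene = "pseudogene")[g$category]
      lines <- c(lines, sprintf(
        "%s\tminichrom\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s%s",
        m$id, type, g$start + 1L, g$end, g$orientation, g$name, g$name,
        ifelse(g$anticodon != "",
               paste0(";anticodon=", g$anticodon), "")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
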