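# Synthetic fragmented mitochondrial genomes with known ground truth.
#
# The generator emulates the minichromosome architecture of louse mt
# genomes: 11 circular minichromosomes, each carrying a distinct coding
# region (2-7 of the 37 canonical genes) followed by a non-coding region
# (NCR) that is one shared template per genome, diverged at a small rate per
# minichromosome. The NCR carries an AT-rich motif (140 bp, 64% AT)
# immediately upstream of the coding region's 5' end, a GC-rich motif
# (76 bp, 71% GC) immediately downstream of its 3' end, and two strictly
# conserved flanking motifs (101 bp upstream, 44 bp downstream). tRNA genes
# are synthesised from a parameterised cloverleaf template so the structure
# folder has a recoverable ground truth.

# Cloverleaf layout constants used by the generator. With D-loop and
# anticodon-stem lengths fixed, the anticodon starts at a constant offset
# within the sense-strand tRNA sequence.
.TRNA_ACC_STEM <- 7L
.TRNA_D_STEM <- 4L
.TRNA_D_LOOP <- 5L
.TRNA_AC_STEM <- 5L
.TRNA_AC_LOOP <- 7L
.TRNA_VAR <- 4L
.TRNA_ANTICODON_OFFSET <- .TRNA_ACC_STEM + 2L * .TRNA_D_STEM +
  .TRNA_D_LOOP + .TRNA_AC_STEM + 2L  # 0-based offset of the anticodon

.DEFAULT_GENE_LENGTHS <- c(
  atp6 = 672, atp8 = 166, cob = 1110, cox1 = 1560, cox2 = 690, cox3 = 790,
  nad1 = 890, nad2 = 1000, nad3 = 354, nad4 = 1340, nad4L = 270,
  nad5 = 1690, nad6 = 480, rrnS = 740, rrnL = 1140)

#' Simulation configuration for synthetic fragmented genomes
#'
#' Defaults reproduce the architecture measured in the rat-louse genomes:
#' 11 minichromosomes partitioned as in the packaged Polyplax asiatica
#' catalog, a 1300-bp NCR with a 140-bp/64% AT-rich motif upstream and a
#' 76-bp/71% GC-rich motif downstream of the coding region, 101-bp and
#' 44-bp strictly conserved flanks, 2% NCR divergence between
#' minichromosomes (matching the observed 96-98% NCR identity), and 90-bp
#' reads.
#'
#' @param n_minichromosomes number of minichromosomes.
#' @param gene_partition an [arrangement_catalog()] assigning all 37 genes
#'   to minichromosomes with orientations.
#' @param ncr_length non-coding region length in bases.
#' @param at_motif list `(length, fraction)` for the upstream AT-rich motif.
#' @param gc_motif list `(length, fraction)` for the downstream GC-rich
#'   motif.
#' @param upstream_conserved_len,downstream_conserved_len lengths of the
#'   strictly conserved NCR flanks.
#' @param ncr_divergence per-base substitution rate applied to the
#'   non-conserved NCR of each minichromosome.
#' @param coding_base_probs per-base probabilities (A, C, G, T) for coding
#'   sequence (AT-rich, as in insect mt genomes).
#' @param gene_lengths named lengths for protein-coding and rRNA genes.
#' @param trna_arms data frame with columns `trna`, `t_stem`, `t_loop`
#'   giving the T-arm architecture per tRNA; defaults to the packaged
#'   Polyplax asiatica measurements.
#' @param read_length,coverage,error_rate read-simulation parameters.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_minichromosomes = 11,
                              gene_partition = NULL,
                              ncr_length = 1300,
                              at_motif = list(length = 140,
                                              fraction = 0.64),
                              gc_motif = list(length = 76,
                                              fraction = 0.71),
                              upstream_conserved_len = 101,
                              downstream_conserved_len = 44,
                              ncr_divergence = 0.02,
                              coding_base_probs = c(A = 0.35, C = 0.15,
                                                    G = 0.15, T = 0.35),
                              gene_lengths = .DEFAULT_GENE_LENGTHS,
                              trna_arms = NULL,
                              read_length = 90,
                              coverage = 30,
                              error_rate = 0,
                              seed = 1L) {
  if (is.null(gene_partition)) gene_partition <- polyplax_catalog("asiatica")
  if (is.null(trna_arms)) {
    arms <- trna_arm_measurements()
    trna_arms <- data.frame(trna = arms$trna, t_stem = arms$pa_t_stem,
                            t_loop = arms$pa_t_loop,
                            stringsAsFactors = FALSE)
  }
  genes <- unlist(lapply(gene_partition$entries, `[[`, "gene"))
  missing <- setdiff(mt_gene_names(), genes)
  dup <- unique(genes[duplicated(genes)])
  if (length(missing) || length(dup)) {
    stop("gene_partition must cover all 37 genes exactly once; missing: ",
         paste(missing, collapse = ", "), "; duplicated: ",
         paste(dup, collapse = ", "))
  }
  stopifnot(ncr_length > at_motif$length + gc_motif$length,
            at_motif$fraction > 0, at_motif$fraction < 1,
            gc_motif$fraction > 0, gc_motif$fraction < 1,
            ncr_divergence >= 0, ncr_divergence < 1,
            read_length > 0, coverage > 0, error_rate >= 0)
  structure(list(
    n_minichromosomes = n_minichromosomes,
    gene_partition = gene_partition, ncr_length = ncr_length,
    at_motif = at_motif, gc_motif = gc_motif,
    upstream_conserved_len = upstream_conserved_len,
    downstream_conserved_len = downstream_conserved_len,
    ncr_divergence = ncr_divergence,
    coding_base_probs = coding_base_probs,
    gene_lengths = gene_lengths, trna_arms = trna_arms,
    read_length = read_length, coverage = coverage,
    error_rate = error_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

# --- sequence synthesis ----------------------------------------------------

# A random motif with an *exact* base composition: `frac` of the bases are
# drawn from `pair1` (split evenly), the rest from `pair2`.
exact_composition_motif <- function(len, frac, pair1, pair2) {
  n1 <- round(len * frac)
  n2 <- len - n1
  bases <- c(rep(pair1, c(ceiling(n1 / 2), floor(n1 / 2))),
             rep(pair2, c(ceiling(n2 / 2), floor(n2 / 2))))
  paste(sample(bases), collapse = "")
}

wc_complement <- function(x) chartr("ACGT", "TGCA", x)

# Synthesise one tRNA gene (sense strand, DNA alphabet) from the cloverleaf
# template. Stems are strict Watson-Crick pairs; loop boundaries are set to
# 'A' so chance stem extensions cannot out-score the planted decomposition.
synth_trna <- function(anticodon_rna, t_stem, t_loop, probs) {
  anticodon <- chartr("U", "T", anticodon_rna)
  stem5 <- function(n) strsplit(random_dna(n, probs), "")[[1]]
  blocked_loop <- function(n) {
    # loop boundaries fixed to 'A' so they cannot pair and extend a stem
    if (n <= 2) return(paste(rep("A", n), collapse = ""))
    paste0("A", random_dna(n - 2, probs), "A")
  }
  acc <- stem5(.TRNA_ACC_STEM)
  d <- stem5(.TRNA_D_STEM)
  ac <- stem5(.TRNA_AC_STEM)
  t5 <- stem5(t_stem)
  ac_loop <- paste0("A", substr(blocked_loop(3), 2, 2), anticodon,
                    substr(blocked_loop(3), 2, 2), "A")
  paste0(
    paste(acc, collapse = ""),
    paste(d, collapse = ""), blocked_loop(.TRNA_D_LOOP),
    paste(rev(wc_complement(d)), collapse = ""),
    paste(ac, collapse = ""), ac_loop,
    paste(rev(wc_complement(ac)), collapse = ""),
    blocked_loop(.TRNA_VAR),
    paste(t5, collapse = ""), blocked_loop(t_loop),
    paste(rev(wc_complement(t5)), collapse = ""),
    paste(rev(wc_complement(acc)), collapse = ""))
}

# Sense-strand sequence for any gene symbol under a config. tRNA templates
# are rejection-sampled until the planted cloverleaf is the decomposition
# the folder recovers, so the generator's structural ground truth is
# unambiguous.
synth_gene <- function(name, config) {
  if (is_trna_gene(name)) {
    arms <- config$trna_arms
    row <- arms[arms$trna == name, ]
    if (!nrow(row)) stop("no T-arm architecture for ", name)
    for (attempt in 1:50) {
      s <- synth_trna(trna_anticodon(name), row$t_stem, row$t_loop,
                      config$coding_base_probs)
      st <- fold_trna(s)
      if (!is.null(st) && st$t_arm$stem_pairs == row$t_stem &&
          st$t_arm$loop_nt == row$t_loop &&
          st$anticodon == trna_anticodon(name)) {
        return(s)
      }
    }
    stop("could not synthesise an unambiguous cloverleaf for ", name)
  } else {
    random_dna(config$gene_lengths[[name]], config$coding_base_probs)
  }
}

# Build one minichromosome from its parts table (name, category,
# orientation, anticodon, sense_seq) plus its NCR. Coordinates restart from
# 0 at the first gene.
layout_minichromosome <- function(id, parts, ncr) {
  segs <- ifelse(parts$orientation == "-",
                 vapply(parts$sense_seq, revcomp, ""), parts$sense_seq)
  lens <- nchar(segs)
  starts <- cumsum(c(0L, head(lens, -1)))
  coding <- paste(segs, collapse = "")
  genes <- data.frame(name = parts$name, category = parts$category,
                      start = as.integer(starts),
                      end = as.integer(starts + lens),
                      orientation = parts$orientation,
                      anticodon = parts$anticodon,
                      stringsAsFactors = FALSE)
  m <- minichromosome(id, paste0(coding, ncr), genes,
                      coding_span = c(0L, nchar(coding)),
                      noncoding_span = c(nchar(coding),
                                         nchar(coding) + nchar(ncr)))
  attr(m, "parts") <- parts
  attr(m, "ncr") <- ncr
  m
}

parts_from_catalog_entry <- function(entry, config) {
  data.frame(
    name = entry$gene,
    category = gene_category(entry$gene),
    orientation = entry$orientation,
    anticodon = ifelse(gene_category(entry$gene) == "tRNA",
                       trna_anticodon(entry$gene), ""),
    sense_seq = vapply(entry$gene, synth_gene, "", config = config),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic fragmented mitochondrial genome
#'
#' @param config a [simulation_config()].
#' @param species label for the emitted genome.
#' @return list with elements `genome` (a [fragmented_genome()] with
#'   sequences, annotations and spans set) and `truth` (the generator's
#'   ground truth: the true catalog, coding/non-coding spans, the reference
#'   sense-strand gene sequences, the NCR template, and empty event/stretch
#'   lists to be filled by [derive_sister()] and [plant_shared_stretch()]).
#' @export
generate_genome <- function(config = simulation_config(),
                            species = "synthetic") {
  with_local_seed(config$seed, {
    ncr_len <- config$ncr_length
    at <- config$at_motif; gc <- config$gc_motif
    filler_len <- ncr_len - at$length - gc$length
    # NCR template: GC-rich motif right after the coding 3' end, AT-rich
    # motif right before the coding 5' end (the NCR precedes position 0 on
    # the circle).
    # A short AT-poor spacer separates the filler from the AT-rich motif so
    # the motif's compositional boundary is sharp on the upstream side.
    spacer_len <- min(30L, filler_len)
    template <- paste0(
      exact_composition_motif(gc$length, gc$fraction, c("G", "C"),
                              c("A", "T")),
      random_dna(filler_len - spacer_len,
                 c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
      random_dna(spacer_len, c(A = 0.05, C = 0.45, G = 0.45, T = 0.05)),
      exact_composition_motif(at$length, at$fraction, c("A", "T"),
                              c("G", "C")))
    up_cons <- config$upstream_conserved_len
    down_cons <- config$downstream_conserved_len
    diverge_ncr <- function() {
      mid <- substr(template, down_cons + 1, ncr_len - up_cons)
      paste0(substr(template, 1, down_cons),
             mutate_seq(mid, config$ncr_divergence),
             substr(template, ncr_len - up_cons + 1, ncr_len))
    }
    entries <- config$gene_partition$entries
    mcs <- lapply(names(entries), function(id) {
      parts <- parts_from_catalog_entry(entries[[id]], config)
      layout_minichromosome(id, parts, diverge_ncr())
    })
    genome <- fragmented_genome(species, mcs, complete = TRUE)
    refs <- unlist(lapply(mcs, function(m) {
      p <- attr(m, "parts")
      setNames(p$sense_seq, p$name)
    }))
    truth <- list(
      catalog = genome_to_catalog(genome),
      spans = lapply(mcs, function(m)
        list(id = m$id, coding = m$coding_span,
             noncoding = m$noncoding_span)),
      reference_genes = refs,
      ncr_template = template,
      events = list(),
      stretches = list())
    list(genome = genome, truth = truth)
  })
}

# --- rearrangement events --------------------------------------------------

#' Event specifications for [derive_sister()]
#'
#' @param gene,geneA,geneB canonical gene symbols.
#' @param after,before destination junction: insert the gene immediately
#'   after (or before) this gene on its host minichromosome. Exactly one of
#'   the two must be given; for a block translocation the whole block of
#'   `genes` moves as one unit.
#' @param genes for `translocation_event`, one gene or a block of adjacent
#'   genes (in their current order).
#' @param leave_pseudogene retain a truncated, mutated copy at the
#'   ancestral site of the (first) moved gene.
#' @param pseudogene_length,pseudogene_divergence remnant length in bases
#'   and its per-base substitution rate.
#' @param orientation orientation of the gene(s) at the destination.
#' @return an event specification list.
#' @export
translocation_event <- function(genes, after = NULL, before = NULL,
                                leave_pseudogene = FALSE,
                                pseudogene_length = 55,
                                pseudogene_divergence = 0.2,
                                orientation = "+") {
  if (is.null(after) == is.null(before))
    stop("give exactly one of `after` or `before`")
  list(type = "translocation", genes = genes, after = after,
       before = before, leave_pseudogene = leave_pseudogene,
       pseudogene_length = pseudogene_length,
       pseudogene_divergence = pseudogene_divergence,
       orientation = orientation)
}

#' @rdname translocation_event
#' @export
identity_swap_event <- function(geneA, geneB) {
  list(type = "identity_swap", genes = c(geneA, geneB))
}

#' @rdname translocation_event
#' @export
pseudogenization_event <- function(gene, divergence = 0.2) {
  list(type = "pseudogenization", genes = gene, divergence = divergence)
}

find_gene_mc <- function(genome, gene) {
  for (id in names(genome$minichromosomes)) {
    p <- attr(genome$minichromosomes[[id]], "parts")
    if (gene %in% p$name) return(id)
  }
  stop("gene not found in genome: ", gene)
}

host_key_of_parts <- function(parts) {
  sort(parts$name[parts$category %in% c("PCG", "rRNA")])
}

#' Derive a sister genome by applying rearrangement events
#'
#' Events are applied in order to a copy of the parent genome. A
#' translocation moves a gene (or block of adjacent genes) to a named
#' junction on another minichromosome, optionally leaving a truncated,
#' mutated pseudogene remnant at the ancestral site. An identity swap
#' exchanges only the anticodon triplets of two same-family tRNA genes in
#' place (the genes trade names without physically moving). A
#' pseudogenization degrades a gene in place.
#'
#' @param parent result of [generate_genome()], or a genome carrying
#'   generator part tables.
#' @param events list of event specifications
#'   ([translocation_event()] etc.).
#' @param seed integer seed for the mutational noise in remnants.
#' @param species label for the derived genome.
#' @return list with `genome` and `truth` (truth records the applied
#'   events).
#' @export
derive_sister <- function(parent, events, seed = 1L,
                          species = "synthetic_sister") {
  genome <- if (!is.null(parent$genome)) parent$genome else parent
  with_local_seed(seed, {
    parts_of <- lapply(genome$minichromosomes, attr, "parts")
    ncr_of <- lapply(genome$minichromosomes, attr, "ncr")
    applied <- list()
    for (ev in events) {
      if (ev$type == "translocation") {
        block <- ev$genes
        src <- find_gene_mc_parts(parts_of, block[1])
        sp <- parts_of[[src]]
        idx <- match(block, sp$name)
        if (anyNA(idx)) stop("block gene missing from source: ",
                             paste(block[is.na(idx)], collapse = ", "))
        if (length(idx) > 1 && any(diff(sort(idx)) != 1))
          stop("translocated block must be adjacent genes")
        idx <- sort(idx)
        moved <- sp[idx, , drop = FALSE]
        src_host <- host_key_of_parts(sp)
        remnant_row <- NULL
        if (isTRUE(ev$leave_pseudogene)) {
          g0 <- moved[1, ]
          rem_len <- min(ev$pseudogene_length, nchar(g0$sense_seq))
          rem <- mutate_seq(substr(g0$sense_seq, 1, rem_len),
                            ev$pseudogene_divergence)
          remnant_row <- data.frame(
            name = paste0("pseudo-", g0$name), category = "pseudogene",
            orientation = g0$orientation, anticodon = "",
            sense_seq = rem, stringsAsFactors = FALSE)
        }
        sp <- sp[-idx, , drop = FALSE]
        if (!is.null(remnant_row)) {
          at <- min(idx) - 1L
          sp <- rbind(sp[seq_len(at), , drop = FALSE], remnant_row,
                      sp[seq(at + 1, length.out = nrow(sp) - at), ,
                         drop = FALSE])
        }
        parts_of[[src]] <- sp
        anchor <- if (!is.null(ev$after)) ev$after else ev$before
        dst <- find_gene_mc_parts(parts_of, anchor)
        dp <- parts_of[[dst]]
        pos <- match(anchor, dp$name)
        if (is.na(pos)) stop("destination junction gene not found: ", anchor)
        at <- if (!is.null(ev$after)) pos else pos - 1L
        moved$orientation <- ev$orientation
        dp <- rbind(dp[seq_len(at), , drop = FALSE], moved,
                    dp[seq(at + 1, length.out = nrow(dp) - at), ,
                       drop = FALSE])
        parts_of[[dst]] <- dp
        applied[[length(applied) + 1]] <- list(
          type = "translocation", genes = block,
          source_host = src_host, dest_host = host_key_of_parts(dp),
          leaves_remnant = isTRUE(ev$leave_pseudogene))
      } else if (ev$type == "identity_swap") {
        ga <- ev$genes[1]; gb <- ev$genes[2]
        fa <- trna_family(ga); fb <- trna_family(gb)
        if (is.na(fa) || is.na(fb) || fa != fb)
          stop("identity swap requires two tRNA genes of the same family")
        ma <- find_gene_mc_parts(parts_of, ga)
        mb <- find_gene_mc_parts(parts_of, gb)
        ia <- match(ga, parts_of[[ma]]$name)
        ib <- match(gb, parts_of[[mb]]$name)
        aca <- chartr("U", "T", trna_anticodon(ga))
        acb <- chartr("U", "T", trna_anticodon(gb))
        off <- .TRNA_ANTICODON_OFFSET
        swap_ac <- function(seq, new_ac) {
          paste0(substr(seq, 1, off), new_ac,
                 substr(seq, off + 4, nchar(seq)))
        }
        host_a <- host_key_of_parts(parts_of[[ma]])
        host_b <- host_key_of_parts(parts_of[[mb]])
        # locus of A takes B's anticodon and name, and vice versa
        parts_of[[ma]]$sense_seq[ia] <-
          swap_ac(parts_of[[ma]]$sense_seq[ia], acb)
        parts_of[[ma]]$name[ia] <- gb
        parts_of[[ma]]$anticodon[ia] <- trna_anticodon(gb)
        parts_of[[mb]]$sense_seq[ib] <-
          swap_ac(parts_of[[mb]]$sense_seq[ib], aca)
        parts_of[[mb]]$name[ib] <- ga
        parts_of[[mb]]$anticodon[ib] <- trna_anticodon(ga)
        applied[[length(applied) + 1]] <- list(
          type = "identity_swap", genes = c(ga, gb),
          source_host = host_a, dest_host = host_b,
          leaves_remnant = FALSE)
      } else if (ev$type == "pseudogenization") {
        g <- ev$genes
        mc <- find_gene_mc_parts(parts_of, g)
        i <- match(g, parts_of[[mc]]$name)
        host <- host_key_of_parts(parts_of[[mc]])
        parts_of[[mc]]$sense_seq[i] <-
          mutate_seq(parts_of[[mc]]$sense_seq[i], ev$divergence)
        parts_of[[mc]]$name[i] <- paste0("pseudo-", g)
        parts_of[[mc]]$category[i] <- "pseudogene"
        parts_of[[mc]]$anticodon[i] <- ""
        applied[[length(applied) + 1]] <- list(
          type = "pseudogenization", genes = g, source_host = host,
          dest_host = host, leaves_remnant = TRUE)
      } else {
        stop("unknown event type: ", ev$type)
      }
    }
    mcs <- lapply(names(parts_of), function(id) {
      layout_minichromosome(id, parts_of[[id]], ncr_of[[id]])
    })
    genome2 <- fragmented_genome(species, mcs)
    refs <- unlist(lapply(mcs, function(m) {
      p <- attr(m, "parts")
      setNames(p$sense_seq, p$name)
    }))
    list(genome = genome2,
         truth = list(catalog = genome_to_catalog(genome2),
                      reference_genes = refs,
                      events = applied, stretches = list()))
  })
}

find_gene_mc_parts <- function(parts_of, gene) {
  for (id in names(parts_of)) {
    if (gene %in% parts_of[[id]]$name) return(id)
  }
  stop("gene not found in genome: ", gene)
}

#' Plant an identical stretch between two genes
#'
#' Copies a random window of `geneA`'s sense sequence over a random window
#' of `geneB`, creating a shared identical stretch of the requested length,
#' as left behind by gene-to-gene recombination.
#'
#' @param parent result of [generate_genome()] (or a genome with part
#'   tables).
#' @param geneA,geneB canonical gene symbols.
#' @param length stretch length in bases (0 leaves the genome unchanged).
#' @param seed integer seed for window placement.
#' @return list with `genome` and `truth`; truth records the planted
#'   length and the 0-based window positions within each gene.
#' @export
plant_shared_stretch <- function(parent, geneA, geneB, length, seed = 1L) {
  genome <- if (!is.null(parent$genome)) parent$genome else parent
  truth <- if (!is.null(parent$truth)) parent$truth else
    list(events = list(), stretches = list())
  stretch_len <- length
  rm(length)  # unshadow base::length
  if (stretch_len == 0) {
    return(list(genome = genome, truth = truth))
  }
  with_local_seed(seed, {
    parts_of <- lapply(genome$minichromosomes, attr, "parts")
    ncr_of <- lapply(genome$minichromosomes, attr, "ncr")
    ma <- find_gene_mc_parts(parts_of, geneA)
    mb <- find_gene_mc_parts(parts_of, geneB)
    ia <- match(geneA, parts_of[[ma]]$name)
    ib <- match(geneB, parts_of[[mb]]$name)
    sa <- parts_of[[ma]]$sense_seq[ia]
    sb <- parts_of[[mb]]$sense_seq[ib]
    if (stretch_len >= nchar(sa) || stretch_len >= nchar(sb))
      stop("stretch length must be shorter than both genes")
    pos_a <- sample.int(nchar(sa) - stretch_len + 1L, 1L) - 1L
    pos_b <- sample.int(nchar(sb) - stretch_len + 1L, 1L) - 1L
    window <- substr(sa, pos_a + 1L, pos_a + stretch_len)
    sb_new <- paste0(substr(sb, 1, pos_b),
                     window,
                     substr(sb, pos_b + stretch_len + 1L, nchar(sb)))
    parts_of[[mb]]$sense_seq[ib] <- sb_new
    mcs <- lapply(names(parts_of), function(id) {
      layout_minichromosome(id, parts_of[[id]], ncr_of[[id]])
    })
    genome2 <- fragmented_genome(genome$species, mcs)
    truth$stretches[[length(truth$stretches) + 1]] <- list(
      geneA = geneA, geneB = geneB, length = stretch_len,
      posA = pos_a, posB = pos_b)
    truth$reference_genes <- unlist(lapply(mcs, function(m) {
      p <- attr(m, "parts")
      setNames(p$sense_seq, p$name)
    }))
    truth$catalog <- genome_to_catalog(genome2)
    list(genome = genome2, truth = truth)
  })
}

# --- read simulation -------------------------------------------------------

#' Simulate short reads from a fragmented genome
#'
#' Reads are sampled uniformly from each circle (start positions wrap the
#' origin) on a random strand, with the number of reads per minichromosome
#' drawn from a Poisson law around `coverage * length / read_length`.
#' Substitution errors are applied at `error_rate` per base. No indels and
#' no quality model.
#'
#' @param genome a [fragmented_genome()] with sequences, or the result of
#'   [generate_genome()].
#' @param read_length read length in bases.
#' @param coverage expected fold coverage per circle.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param region `"circle"` samples reads uniformly around each whole
#'   circle; `"amplicon"` samples only from the coding region plus a short
#'   conserved flank on each side, emulating the PCR strategy used to
#'   sequence real minichromosomes (outward primers in the conserved NCR
#'   flanks). Amplicon mode keeps reads of different minichromosomes from
#'   sharing long identical (conserved-NCR) overlaps, which would defeat
#'   any overlap assembler.
#' @param amplicon_flank bases of NCR retained on each side of the coding
#'   region in amplicon mode (kept below the assembler's minimum overlap).
#' @return data frame with columns `read_id`, `minichrom_id`, `sequence`.
#' @export
simulate_reads <- function(genome, read_length = 90, coverage = 30,
                           error_rate = 0, seed = 1L,
                           region = c("circle", "amplicon"),
                           amplicon_flank = 20) {
  if (!is.null(genome$genome)) genome <- genome$genome
  region <- match.arg(region)
  stopifnot(coverage > 0)
  with_local_seed(seed, {
    out <- lapply(names(genome$minichromosomes), function(id) {
      m <- genome$minichromosomes[[id]]
      if (is.na(m$sequence)) stop("minichromosome without sequence: ", id)
      len <- nchar(m$sequence)
      if (read_length > len)
        stop("read_length exceeds minichromosome length for ", id)
      if (region == "amplicon") {
        if (is.null(m$coding_span))
          stop("amplicon mode needs coding spans: ", id)
        d <- paste0(m$sequence, m$sequence)
        start0 <- (m$coding_span[1] - amplicon_flank) %% len
        tlen <- min(len,
                    (m$coding_span[2] - m$coding_span[1]) +
                      2L * amplicon_flank)
        template <- substr(d, start0 + 1L, start0 + tlen)
        if (read_length > tlen)
          stop("read_length exceeds amplicon length for ", id)
        n <- stats::rpois(1, coverage * tlen / read_length)
        if (n == 0) return(NULL)
        starts <- sample.int(tlen - read_length + 1L, n, replace = TRUE)
        seqs <- substring(template, starts, starts + read_length - 1L)
      } else {
        doubled <- paste0(m$sequence, m$sequence)
        n <- stats::rpois(1, coverage * len / read_length)
        if (n == 0) return(NULL)
        starts <- sample.int(len, n, replace = TRUE)
        seqs <- substring(doubled, starts, starts + read_length - 1L)
      }
      minus <- runif(n) < 0.5
      seqs[minus] <- vapply(seqs[minus], revcomp, "")
      if (error_rate > 0)
        seqs <- vapply(seqs, mutate_seq, "", rate = error_rate)
      data.frame(read_id = sprintf("%s_read%05d", id, seq_len(n)),
                 minichrom_id = id, sequence = unname(seqs),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Write simulated reads to FASTQ
#'
#' Fixed quality (`I`) per base, matching the simulator's
#' substitution-only error model.
#'
#' @param reads data frame from [simulate_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence),
                 function(n) paste(rep("I", n), collapse = ""), "")
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    qual), path)
  invisible(path)
}

#' Write a fragmented genome to FASTA
#'
#' Headers follow `species|minichrom_id|circular=true|length=N`.
#'
#' @param genome a [fragmented_genome()] (or `generate_genome()` result).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!is.null(genome$genome)) genome <- genome$genome
  seqs <- Biostrings::DNAStringSet(
    vapply(genome$minichromosomes, `[[`, "", "sequence"))
  names(seqs) <- sprintf("%s|%s|circular=true|length=%d", genome$species,
                         names(genome$minichromosomes),
                         BiocGenerics::width(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read minichromosome sequences from FASTA
#'
#' Inverse of [write_genome_fasta()]: parses the
#' `species|minichrom_id|circular=true|length=N` headers.
#'
#' @param path FASTA path.
#' @return a [fragmented_genome()] with sequences but no annotations.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  species <- unique(vapply(fields, `[[`, "", 1))
  if (length(species) != 1) stop("FASTA mixes species")
  mcs <- lapply(seq_along(seqs), function(i) {
    minichromosome(fields[[i]][2], as.character(seqs[[i]]))
  })
  fragmented_genome(species, mcs)
}
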