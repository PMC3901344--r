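---
title: "Models and methods behind minichrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind minichrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minichrom)
```

## The biological setting

Most bilaterian animals carry their 37 mitochondrial genes — 13
protein-coding genes (PCGs), 2 rRNAs and 22 tRNAs — on a single circular
chromosome of 13–20 kb. Blood-sucking lice (Anoplura) are a striking
exception: their mitochondrial genome is fragmented into many small
circular **minichromosomes**, each 2–4 kb, each carrying a distinct
**coding region** (a handful of the 37 genes) and a **non-coding region**
(NCR) that is well conserved across the minichromosomes of one species.
The extent of fragmentation varies across lineages: the pig lice
(*Haematopinus*) carry 37 genes on 9 minichromosomes (4.1 genes per
minichromosome), the rat lice (*Polyplax*) 37 on 11 (3.4), the human
pubic louse 34 on 14 (2.4) and the human head/body lice 37 on 20 (their
metric is treated as the catalog constant 2.1 throughout, never
recomputed).

`minichrom` models this system end to end: it ships the arrangement
catalogs of the two *Polyplax* rat lice (plus a synthetic reconstruction
of their common ancestor's arrangement), simulates minichromosome-
structured genomes and short reads with known ground truth, assembles and
annotates them, quantifies recombination-length signals between genes,
infers ancestral gene arrangements on the fixed louse phylogeny,
classifies rearrangement events, and relates fragmentation extent to
life-history traits.

## Coordinate conventions and catalog equality

Coordinates are 0-based and half-open on the circle. The origin of an
annotated minichromosome is the first base of the first gene of its
coding region on the **reference strand** — the strand on which the
majority of genes are transcribed (in the rat lice all genes except
*trnT*/*nad1*, respectively *nad1* alone, share that orientation). This
makes the coding span contiguous from position 0 and puts the NCR after
it; `end` may exceed the sequence length to encode origin-spanning
features.

An arrangement catalog is the sequence-free record of gene order and
orientation per minichromosome. Two catalog entries are equal when one is
a **rotation** of the other with identical orientations; a reflection is
*not* equal, because transcription orientation is meaningful. When two
species are compared, "the same minichromosome" is identified by its
**host key** — the set of PCG/rRNA genes it carries — and a tRNA counts
as differently distributed when its host key changes. Under this
definition (and only under it) the packaged *Po. asiatica* and
*Po. spinulosa* catalogs differ in exactly 8 of 22 tRNAs, with both
members of the leucine identity swap counted, and tRNAs that merely moved
within an unchanged host (e.g. *trnG*) not counted.

## The synthetic genome generator

The generator's defaults are the measured study conditions, not tuning
knobs:

* 11 minichromosomes partitioned as in the *Po. asiatica* catalog;
* an NCR of 1300 bp shared as one template per genome, diverged at 2% per
  minichromosome outside two strictly conserved flanks (101 bp upstream,
  44 bp downstream) — matching the observed 96–98% NCR identity;
* an AT-rich motif (140 bp, 64% AT, built with exact base counts)
  immediately upstream of the coding 5′ end and a GC-rich motif (76 bp,
  71% GC) immediately downstream of the 3′ end. A 30-bp AT-poor spacer
  separates filler from the AT motif so the motif's compositional
  boundary is sharp; without it, the maximal-window detection rule would
  drift into AT-rich filler and report arbitrarily long windows;
* PCG/rRNA lengths chosen so each coding region falls in the observed
  802–1,756 bp range (total circle lengths 2.1–3.1 kb);
* tRNAs synthesised from a parameterised cloverleaf (acceptor stem 7 bp,
  D-arm 4+5, anticodon arm 5 bp with a 7-nt loop carrying the canonical
  anticodon, 4-nt variable region, T-arm per the packaged per-tRNA
  measurements). Stems are strict Watson–Crick pairs; loop boundary bases
  are fixed to `A` so chance pairings cannot extend a stem; and each
  template is rejection-sampled until the folder recovers the planted
  decomposition, making the structural ground truth unambiguous;
* 90-bp reads, 30× coverage, substitution-only errors, fixed FASTQ
  quality.

All randomness flows from a single integer seed through a local RNG
scope, so every artifact is reproducible byte for byte.

Derived sister genomes are produced by applying an ordered event list:
**translocations** (single genes or blocks of adjacent genes, optionally
leaving a truncated remnant — default 55 bp at 20% substitution, between
the two observed remnants of 54 and 57 bp), **identity swaps** (two
same-family tRNAs exchange only their anticodon triplets in place,
mimicking third-anticodon-position point mutations), and
**pseudogenizations**. Planted shared stretches copy a random window of
one gene over a window of another; all events and plants are recorded as
verifiable ground truth.

What the generator does *not* emulate: real coding sequence (PCGs are
random AT-rich strings, not codon-structured), indels, read-quality
structure, tRNA post-transcriptional edits, and inter-gene homology
other than what it plants. Passing recovery tests therefore demonstrates
the pipeline's internal consistency at realistic sizes and noise levels,
not its performance on real sequencing data.

## Assembly

`assemble()` is a deliberately small greedy overlap-layout-consensus
assembler run at the parameters used for the original minichromosome
reads: minimum overlap 50 bp at minimum overlap identity 98%. Reads are
deduplicated onto a canonical strand and sorted, after which the pair of
contigs with the longest qualifying ungapped suffix–prefix overlap
(either strand of either partner) is merged, with per-position
majority-vote consensus, until a fixpoint. Ties are broken by the
lexicographically smaller merged sequence, which together with the
canonical start order makes assembly independent of read order. Overlap
candidates are found through seed k-mers indexed at the first 33
positions of each contig, so a read error in a contig's very first bases
cannot hide every overlap. In well-covered assemblies, single-read contig
tips are trimmed before the circularity check, because a coverage-1
consensus can carry read errors that mask the terminal redundancy.
`circularize()` is the in-silico analogue of outbound-primer
verification: a contig whose prefix and suffix overlap by at least the
minimum overlap is trimmed and flagged circular.

Two scope limitations are inherited from the data this models. Overlap
identity is computed without indels (the simulator produces none), and
whole-circle reads from *different* minichromosomes share the strictly
conserved NCR flanks at 100% identity, which no ≥50-bp-overlap assembler
can disentangle — that is precisely why the original study amplified and
sequenced coding regions. `simulate_reads(region = "amplicon")`
reproduces that design (coding region ± 20 bp of conserved flank, kept
below the minimum overlap), and the end-to-end pipeline uses it.

## Annotation

The coding/non-coding partition uses exact 15-mer anchoring: a position
is conserved when its k-mer occurs in at least half of the
minichromosomes (at least two), conserved positions are merged across
gaps of up to 60 bp (a 2% substitution rate breaks exact 15-mers roughly
every 30 bp, and clustered breaks produce longer gaps), and the largest
conserved block system on each circle is its NCR. Partitions recover the
generator's spans with Jaccard ≥ 0.95; a genome whose circles are
conserved throughout (no distinct coding region) or share no ≥200-bp
block fails with a clear error.

Compositional motifs are reported as the maximal window touching each
coding boundary with AT ≥ 0.60 (5′ side) or GC ≥ 0.55 (3′ side), at
least 50 bp. The thresholds admit all four motifs reported for the rat
lice, including the weakest (57% GC over 65 bp); the detection rule
itself is this package's reconstruction, since no published rule exists.

Gene identity is assigned by best-hit similarity against a reference
gene set (for synthetic data, the generator's own sense-strand genes): a
call requires a local alignment at ≥70% identity covering ≥60% of the
reference, searched on both strands of the doubled circle with an exact
string fast path; overlapping calls are resolved by score. tRNA genes
are folded by exhaustive cloverleaf search with bounds wide enough for
the aberrant louse tRNAs (T-stem 3–8 pairs, T-loop 3–11 nt, spanning the
full range of the packaged measurements); Watson–Crick and G·U pairs are
allowed, every stem position must pair, and the decomposition with the
most pairs wins (ties: more Watson–Crick pairs, then the smallest
T-stem). The T-arm table reports `arm = 2·stem + loop` per tRNA with
column totals and means rounded half-up to one decimal. Pseudogene
remnants are found by local alignment of the functional gene against
intergenic sequence at ≥40 bp and ≥60% identity — thresholds at which
the two observed 54–57-bp remnants are comfortably detected while random
sequence stays clean.

## Shared stretches and the chance baseline

The recombination-length signal is the exact longest common substring
between two genes, computed by dynamic programming (Rcpp) with ties
broken at the smallest position pair; reverse-complement search and
masked re-search for secondary stretches are options. Because no
published procedure defines "longer than expected by chance", the chance
baseline is Monte-Carlo: the longest-stretch distribution between
independent random sequences of matched lengths and pooled base
composition (composition, not shuffling, controls the dominant effect).
A pair is flagged when its observed stretch is at least twice the null
mean or exceeds the null 95th percentile — a rule under which the
weakest case the field calls real (16–17 bp in short tRNAs, "2–3 times
longer than expected by chance") is flagged. By construction the
q95 arm of the rule fires for a few percent of the 666 gene pairs by
chance; the scan is calibrated (chance flag rate ≤ 5% within binomial
tolerance) rather than sparse, and the per-pair null distributions are
cached across pairs with matching lengths and composition. The
Monte-Carlo sampler runs on a self-contained mt19937 stream, so a seed
fixes the distribution across platforms.

## Ancestral states and event classification

Arrangement characters (gene adjacencies or whole-minichromosome gene
lists) are placed on the fixed louse phylogeny — rat lice sister to
human lice, pig lice as the deepest split — under a Dollo assumption:
the state arises once and can only be lost. A state is inferred
`present` at the most recent common ancestor of its carriers when at
least two lineages corroborate it, and along every path from that
ancestor to a carrier; `absent` below the ancestor where no descendant
carries it; `ambiguous` above the ancestor and everywhere when only a
single species carries the state (one carrier cannot distinguish an old
state from a recent gain). For corroborated characters this coincides
with exhaustive minimum-event single-gain reconstruction; the ambiguous
convention is deliberately more cautious than strict parsimony where
evidence is one-sided.

Event classification compares an ancestral catalog with a derived one by
host key. Two same-family tRNAs that exactly exchange host contexts are
one `identity_swap` — corroborated, when sequences are available, by each
derived gene resembling the ancestral occupant of its position more than
its own ancestral copy; blocks of adjacent co-moving genes are reported
as one `translocation`; a detectable remnant at the ancestral site
attaches `pseudogene_remnant` evidence. On the packaged catalogs this
reproduces the published scenario: five tRNA translocations (one of them
the two-gene serine block) and the leucine identity swap separating the
two rat-louse lineages from their reconstructed ancestor.

## Fragmentation and life history

Fragmentation extent is genes per minichromosome rounded half-up to one
decimal (half-up, not banker's rounding, is what reproduces every
printed value: 37/11 → 3.4, 37/9 → 4.1, 34/14 → 2.4). Life-history
ranges are reduced to midpoints — the source compares ranges only
verbally — and association is summarised by a Spearman rank correlation
with average ranks for ties plus a weak-monotonicity indicator. With
five species and tied metrics no p-value is attached; the output is
descriptive: fragmentation tracks life-cycle length (ρ ≈ 0.97,
concordant) but not body length (the *Pediculus* lice are larger than
*Polyplax* yet more fragmented).

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full recovery
pipeline at the study's own scale: 11 circles of 2.1–3.1 kb, 30×
coverage of coding-region amplicons, 5 generator seeds for end-to-end
recovery and 20 for event recovery; the Monte-Carlo null uses 100–2000
replicates depending on context, and the 4-mer null is checked against
exact enumeration of all 4⁴ × 4⁴ sequence pairs. Degenerate inputs fail
loudly rather than silently: empty read sets, single-minichromosome
partitions, single-base null compositions, zero-variance associations
and over-long stretch plants are all errors. Known limitations worth
repeating: the assembler is not general-purpose (no repeat resolution,
no indels, no quality-aware consensus), annotation has no
covariance-model tRNA scoring or ORF validation, and the
fragmentation–life-history link is descriptive, not a hypothesis test.
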