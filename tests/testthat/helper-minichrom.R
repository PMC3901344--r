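# Shared test helpers: independent oracles and small constructors.

# Brute-force longest-common-substring oracle: grow k until no substring of
# that length is shared. Independent of the package's dynamic-programming
# implementation.
oracle_lcs <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  for (k in seq_len(min(na, nb))) {
    sa <- unique(substring(a, 1:(na - k + 1), k:na))
    sb <- unique(substring(b, 1:(nb - k + 1), k:nb))
    if (!length(intersect(sa, sb))) return(k - 1L)
  }
  min(na, nb)
}

random_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = probs),
        collapse = "")
}

rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                               collapse = ""))

# Is `contig_seq` a rotation (or reverse-complement rotation) of the
# circular `truth` sequence? Checked by substring search in truth+truth.
is_rotation_of <- function(contig_seq, truth) {
  if (nchar(contig_seq) != nchar(truth)) return(FALSE)
  d <- paste0(truth, truth)
  grepl(contig_seq, d, fixed = TRUE) || grepl(rc(contig_seq), d,
                                              fixed = TRUE)
}

# Tiny two-minichromosome catalog for invariant tests.
toy_catalog <- function(species = "toy") {
  arrangement_catalog(species, list(
    mcA = data.frame(gene = c("atp8", "atp6", "trnE"),
                     orientation = c("+", "+", "-"),
                     stringsAsFactors = FALSE),
    mcB = data.frame(gene = c("cox1", "trnL2"),
                     orientation = c("+", "+"),
                     stringsAsFactors = FALSE)))
}

# The five tRNA translocations plus the leucine identity swap that separate
# the two rat-louse lineages from their common ancestor.
ps_lineage_events <- function() {
  list(
    translocation_event("trnT", before = "trnD", leave_pseudogene = TRUE),
    translocation_event("trnA", after = "nad6"),
    translocation_event(c("trnS1", "trnS2"), before = "rrnS"),
    identity_swap_event("trnL1", "trnL2"))
}

pa_lineage_events <- function() {
  list(
    translocation_event("trnP", after = "trnN", leave_pseudogene = TRUE),
    translocation_event("trnF", after = "nad4"))
}
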