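test_that("the default genome has 11 minichromosomes of 2-4 kb carrying all
          37 genes, deterministically under a seed", {
  sim <- generate_genome(simulation_config(seed = 1))
  g <- sim$genome
  expect_equal(length(g$minichromosomes), 11)
  expect_equal(minichrom:::n_genes(g), 37)
  lens <- vapply(g$minichromosomes, function(m) nchar(m$sequence), 0L)
  expect_true(all(lens >= 2000 & lens <= 4000))
  # coding + non-coding spans partition each circle
  for (m in g$minichromosomes) {
    expect_equal((m$coding_span[2] - m$coding_span[1]) +
                   (m$noncoding_span[2] - m$noncoding_span[1]),
                 nchar(m$sequence))
  }
  # same config + seed -> byte-identical FASTA
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(sim, f1)
  write_genome_fasta(generate_genome(simulation_config(seed = 1)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the sequences
  sim2 <- generate_genome(simulation_config(seed = 2))
  expect_false(identical(sim$genome$minichromosomes[[1]]$sequence,
                         sim2$genome$minichromosomes[[1]]$sequence))
})

test_that("the emitted AT-rich motif matches its configured composition", {
  sim <- generate_genome(simulation_config(seed = 5))
  m <- sim$genome$minichromosomes[[1]]
  len <- nchar(m$sequence)
  d <- paste0(m$sequence, m$sequence)
  # motif occupies the 140 bases immediately upstream of the coding start
  ne <- m$noncoding_span[2]
  motif <- substr(d, ne - 140 + 1, ne)
  at <- mean(strsplit(motif, "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at - 0.64), 0.03)
})

test_that("gene partitions missing or duplicating genes are rejected", {
  pa <- polyplax_catalog("asiatica")
  broken <- pa$entries
  broken[[1]] <- broken[[1]][-1, ]  # drop atp8
  expect_error(simulation_config(gene_partition =
    structure(list(species = "x", entries = broken),
              class = "arrangement_catalog")), "atp8")
})

test_that("derive_sister applies the rat-louse event sets so the two
          sisters differ in 8 tRNA host assignments", {
  anc <- generate_genome(
    simulation_config(seed = 3,
                      gene_partition = polyplax_catalog("ancestor")),
    species = "ancestor")
  sis_ps <- derive_sister(anc, ps_lineage_events(), seed = 4)
  sis_pa <- derive_sister(anc, pa_lineage_events(), seed = 5)
  cmp <- compare_catalogs(sis_pa$truth$catalog, sis_ps$truth$catalog)
  expect_equal(cmp$n_differing_trnas, 8)
  expect_setequal(cmp$differing_trnas,
                  c("trnT", "trnA", "trnS1", "trnS2", "trnP", "trnF",
                    "trnL1", "trnL2"))
  expect_equal(cmp$n_differing_pcg_rrna, 0)

  # empty event list leaves the catalog unchanged
  same <- derive_sister(anc, list(), seed = 6)
  expect_true(catalogs_equal(same$truth$catalog, anc$truth$catalog))

  # a translocation with remnant leaves a pseudogene at the source site
  ps_pseudo <- attr(sis_ps$truth$catalog, "pseudogenes")
  expect_true("pseudo-trnT" %in%
                unlist(lapply(ps_pseudo, `[[`, "name")))
})

test_that("an identity swap changes only the two anticodon triplets", {
  anc <- generate_genome(simulation_config(seed = 8))
  sw <- derive_sister(anc, list(identity_swap_event("trnL1", "trnL2")),
                      seed = 2)
  # locus content: the sequence at L1's old locus now carries L2's name
  anc_l1 <- anc$truth$reference_genes[["trnL1"]]
  anc_l2 <- anc$truth$reference_genes[["trnL2"]]
  new_l2 <- sw$truth$reference_genes[["trnL2"]]   # at L1's old locus
  new_l1 <- sw$truth$reference_genes[["trnL1"]]   # at L2's old locus
  diffs <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  # anticodons UAG vs UAA differ in one base: each locus changes by <= 1
  expect_lte(diffs(anc_l1, new_l2), 1)
  expect_lte(diffs(anc_l2, new_l1), 1)
  # swapping different families is refused
  expect_error(derive_sister(anc, list(identity_swap_event("trnA",
                                                           "trnC"))),
               "same family")
})

test_that("planted stretches are recoverable and recorded in the truth", {
  sim <- generate_genome(simulation_config(seed = 10))
  pl <- plant_shared_stretch(sim, "trnL1", "trnL2", 28, seed = 3)
  refs <- pl$truth$reference_genes
  obs <- longest_shared_stretch(refs[["trnL1"]], refs[["trnL2"]])
  expect_gte(obs$length, 28)
  rec <- pl$truth$stretches[[1]]
  expect_equal(rec$length, 28)
  # the recorded windows really are identical
  expect_identical(substr(refs[["trnL1"]], rec$posA + 1, rec$posA + 28),
                   substr(refs[["trnL2"]], rec$posB + 1, rec$posB + 28))
  # plant 0 -> unchanged
  same <- plant_shared_stretch(sim, "trnL1", "trnL2", 0, seed = 3)
  expect_identical(same$genome$minichromosomes[[1]]$sequence,
                   sim$genome$minichromosomes[[1]]$sequence)
  # over-long plant is refused
  expect_error(plant_shared_stretch(sim, "trnL1", "trnL2", 1000),
               "shorter than both genes")
})

test_that("read simulation honours coverage, wraps the origin and is
          deterministic", {
  sim <- generate_genome(simulation_config(seed = 12))
  m <- sim$genome$minichromosomes[[3]]
  one <- fragmented_genome("one", list(m))
  len <- nchar(m$sequence)
  reads <- simulate_reads(one, read_length = 90, coverage = 30, seed = 7)
  expect_gt(nrow(reads), 0.8 * 30 * len / 90)
  expect_lt(nrow(reads), 1.2 * 30 * len / 90)
  # error-free reads are exact substrings of the doubled circle (either
  # strand), including origin-spanning ones
  d <- paste0(m$sequence, m$sequence)
  ok <- vapply(reads$sequence, function(r)
    grepl(r, d, fixed = TRUE) || grepl(rc(r), d, fixed = TRUE), TRUE)
  expect_true(all(ok))
  # fixed seed -> identical FASTQ
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(reads, f1)
  write_reads_fastq(simulate_reads(one, read_length = 90, coverage = 30,
                                   seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
  # read longer than the circle is refused
  expect_error(simulate_reads(one, read_length = len + 1), "exceeds")
})
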