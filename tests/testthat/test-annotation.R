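sim_cached <- generate_genome(simulation_config(seed = 31))

test_that("the coding/non-coding partition recovers the generator's spans", {
  part <- partition_coding_noncoding(sim_cached$genome)
  for (i in seq_along(part$minichromosomes)) {
    m <- part$minichromosomes[[i]]
    tr <- sim_cached$genome$minichromosomes[[i]]
    len <- nchar(m$sequence)
    pos <- function(sp) sort(seq(sp[1], sp[2] - 1) %% len)
    a <- pos(m$noncoding_span)
    b <- pos(tr$noncoding_span)
    jac <- length(intersect(a, b)) / length(union(a, b))
    expect_gte(jac, 0.95)
    expect_lt(abs(length(a) - 1300), 50)
  }
})

test_that("degenerate inputs fail the partition with clear errors", {
  s <- random_seq(1500)
  twin <- fragmented_genome("twin", list(minichromosome("a", s),
                                         minichromosome("b", s)))
  expect_error(partition_coding_noncoding(twin), "no distinct coding")
  unrelated <- fragmented_genome("unrel", list(
    minichromosome("a", random_seq(1500)),
    minichromosome("b", random_seq(1500))))
  expect_error(partition_coding_noncoding(unrelated),
               "no shared non-coding")
  expect_error(partition_coding_noncoding(
    fragmented_genome("single", list(minichromosome("a", s)))),
    "at least 2")
})

test_that("compositional motifs are found with the expected geometry", {
  m <- sim_cached$genome$minichromosomes[[2]]
  hits <- find_compositional_motifs(m)
  up <- hits[hits$side == "upstream_AT", ]
  expect_equal(nrow(up), 1)
  expect_lte(abs(up$length - 140), 20)
  expect_gte(up$fraction, 0.60)
  # the motif window must touch the coding 5' boundary (= origin)
  expect_equal(up$end %% nchar(m$sequence), m$coding_span[1])
  down <- hits[hits$side == "downstream_GC", ]
  expect_equal(nrow(down), 1)
  expect_gte(down$fraction, 0.55)
  expect_equal(down$start, m$coding_span[2] %% nchar(m$sequence))
})

test_that("a weak GC motif (57% over 65 bp) is still detected and an
          AT-free NCR gives no upstream hit", {
  # hand-built circle: coding dummy + NCR with a weak GC motif downstream
  set.seed(41)
  coding <- random_seq(600)
  gc_weak <- paste(sample(c(rep(c("G", "C"), 19), rep(c("A", "T"), 14))),
                   collapse = "")  # 65 bp, 38 GC = 58.5%
  ncr <- paste0(gc_weak, paste(rep("G", 300), collapse = ""))
  m <- minichromosome("w", paste0(coding, ncr),
                      coding_span = c(0, 600),
                      noncoding_span = c(600, 600 + nchar(ncr)))
  hits <- find_compositional_motifs(m)
  down <- hits[hits$side == "downstream_GC", ]
  expect_equal(nrow(down), 1)
  expect_gte(down$length, 65)
  # all-G tail: no AT window can reach the 0.60 threshold
  expect_false("upstream_AT" %in% hits$side)
})

test_that("gene identity assignment recovers planted genes, flips with
          strand, and ignores absent genes", {
  g <- sim_cached$genome$minichromosomes[["R-nad4L-cox3-A"]]
  refs <- sim_cached$truth$reference_genes
  ann <- assign_gene_identity(g$sequence, refs)
  truth_ann <- g$genes
  expect_setequal(ann$name, truth_ann$name)
  for (i in seq_len(nrow(truth_ann))) {
    row <- ann[ann$name == truth_ann$name[i], ]
    expect_equal(row$start, truth_ann$start[i])
    expect_equal(row$end, truth_ann$end[i])
    expect_equal(row$orientation, truth_ann$orientation[i])
  }
  # reverse-complemented minichromosome: same genes, orientations flipped
  ann_rc <- assign_gene_identity(rc(g$sequence), refs)
  expect_setequal(ann_rc$name, truth_ann$name)
  ori <- setNames(ann$orientation, ann$name)
  ori_rc <- setNames(ann_rc$orientation, ann_rc$name)
  for (nm in names(ori)) {
    expect_true(ori[[nm]] != ori_rc[[nm]])
  }
  # a reference gene absent from the sequence yields no call
  absent <- refs[c("nad4L", "cox3", "nad5")]
  ann2 <- assign_gene_identity(g$sequence, absent)
  expect_false("nad5" %in% ann2$name)
})

test_that("cloverleaf folding recovers the planted architecture for all 22
          tRNAs of both species' configurations", {
  arms <- trna_arm_measurements()
  for (sp in c("pa", "ps")) {
    cfg <- simulation_config(seed = 33, trna_arms = data.frame(
      trna = arms$trna,
      t_stem = arms[[paste0(sp, "_t_stem")]],
      t_loop = arms[[paste0(sp, "_t_loop")]]))
    sim <- generate_genome(cfg)
    for (i in seq_len(nrow(arms))) {
      st <- fold_trna(sim$truth$reference_genes[[arms$trna[i]]])
      expect_false(is.null(st))
      expect_equal(st$t_arm$stem_pairs, arms[[paste0(sp, "_t_stem")]][i])
      expect_equal(st$t_arm$loop_nt, arms[[paste0(sp, "_t_loop")]][i])
      expect_equal(st$t_arm$arm_nt,
                   2 * st$t_arm$stem_pairs + st$t_arm$loop_nt)
      expect_equal(st$anticodon, arms$anticodon[i])
    }
  }
})

test_that("folding rejects impossible inputs", {
  expect_null(fold_trna(paste(rep("A", 70), collapse = "")))
  expect_error(fold_trna(random_seq(40)), "outside")
  expect_error(fold_trna(random_seq(120)), "outside")
})

test_that("T-arm arithmetic and table totals match the published values
          for both species", {
  arms <- trna_arm_measurements()
  # arm = 2*stem + loop must hold against the reported arm length for
  # every row of both species (44 checks)
  expect_equal(2 * arms$pa_t_stem + arms$pa_t_loop, arms$pa_t_arm)
  expect_equal(2 * arms$ps_t_stem + arms$ps_t_loop, arms$ps_t_arm)
  pa <- tarm_table(data.frame(trna = arms$trna, t_stem = arms$pa_t_stem,
                              t_loop = arms$pa_t_loop))
  ps <- tarm_table(data.frame(trna = arms$trna, t_stem = arms$ps_t_stem,
                              t_loop = arms$ps_t_loop))
  expect_equal(pa$t_arm[pa$trna == "Total"], 332)
  expect_equal(pa$t_arm[pa$trna == "Mean"], 15.1)
  expect_equal(pa$t_stem[pa$trna == "Mean"], 4.6)
  expect_equal(pa$t_loop[pa$trna == "Mean"], 5.9)
  expect_equal(ps$t_arm[ps$trna == "Total"], 285)
  expect_equal(ps$t_arm[ps$trna == "Mean"], 13.0)
  expect_equal(ps$t_stem[ps$trna == "Mean"], 4.2)
  expect_equal(ps$t_loop[ps$trna == "Mean"], 4.6)
  # per-row arm values
  expect_equal(pa$t_arm[pa$trna == "trnA"], 17)
  expect_equal(ps$t_arm[ps$trna == "trnA"], 25)
  # degenerate all-zero input
  zero <- tarm_table(data.frame(trna = c("trnA", "trnC"),
                                t_stem = c(0L, 0L), t_loop = c(0L, 0L)))
  expect_equal(zero$t_arm[zero$trna == "Total"], 0)
  # duplicate tRNA rejected
  expect_error(tarm_table(data.frame(trna = c("trnA", "trnA"),
                                     t_stem = 1:2, t_loop = 1:2)),
               "duplicate")
})

test_that("pseudogene remnants are detected at the planted length and
          random intergenic sequence stays clean", {
  set.seed(51)
  gene <- random_seq(65)
  remnant <- local({
    r <- strsplit(substr(gene, 1, 55), "")[[1]]
    hit <- seq(3, 53, by = 5)  # 11 of 55 positions: 80% identity
    r[hit] <- vapply(r[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(r, collapse = "")
  })
  intergenic <- paste0(random_seq(80), remnant, random_seq(90))
  hits <- detect_pseudogene(intergenic, gene)
  expect_equal(nrow(hits), 1)
  expect_lte(abs(hits$length - 55), 5)
  # identical remnant: full-length, identity 1
  exact <- paste0(random_seq(60), gene, random_seq(60))
  h2 <- detect_pseudogene(exact, gene)
  expect_equal(h2$length, 65)
  expect_equal(h2$identity, 1)
  # unrelated sequences: no hit in the clear majority of draws
  clean <- 0
  for (i in 1:40) {
    h <- detect_pseudogene(random_seq(200), random_seq(65))
    if (nrow(h) == 0) clean <- clean + 1
  }
  expect_gte(clean, 38)
})
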