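test_that("the canonical vocabulary has 37 genes with correct categories", {
  tab <- mt_gene_table()
  expect_equal(nrow(tab), 37)
  expect_equal(sum(tab$category == "PCG"), 13)
  expect_equal(sum(tab$category == "rRNA"), 2)
  expect_equal(sum(tab$category == "tRNA"), 22)
  expect_true(all(tab$anticodon[tab$category == "tRNA"] != ""))
  expect_true(all(tab$anticodon[tab$category != "tRNA"] == ""))
})

test_that("gene_annotation enforces its invariants", {
  ann <- gene_annotation(c("cox1", "trnA"), c(0, 1540), c(1540, 1605),
                         seq_length = 2500)
  expect_equal(ann$category, c("PCG", "tRNA"))
  expect_equal(ann$anticodon, c("", "UGC"))
  expect_error(gene_annotation("notagene", 0, 10), "unknown gene")
  expect_error(gene_annotation("cox1", 10, 10), "end must exceed")
  expect_error(gene_annotation("cox1", 0, 120, seq_length = 100),
               "longer than the circular")
  expect_error(gene_annotation("trnA", 0, 65, anticodon = ""),
               "without anticodon")
  # origin-spanning feature: end beyond length is legal when the width fits
  ok <- gene_annotation("trnA", 2450, 2515, seq_length = 2500)
  expect_equal(ok$end - ok$start, 65)
})

test_that("a gene may not occur on two minichromosomes of one genome", {
  m1 <- minichromosome("a", genes = gene_annotation("cox1", 0, 100))
  m2 <- minichromosome("b", genes = gene_annotation("cox1", 0, 100))
  expect_error(fragmented_genome("sp", list(m1, m2)), "cox1")
})

test_that("catalog TSV round-trips losslessly and rejects bad input", {
  cat0 <- toy_catalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat0, path)
  cat1 <- load_catalog(path)
  expect_true(catalogs_equal(cat0, cat1))
  expect_identical(lapply(cat0$entries, `[[`, "gene"),
                   lapply(cat1$entries, `[[`, "gene"))
  # byte-for-byte stability after a write/load/write cycle
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat1, path2)
  expect_identical(readLines(path), readLines(path2))

  # empty file -> empty catalog
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing here", empty)
  expect_equal(length(load_catalog(empty)$entries), 0)

  # duplicate canonical gene -> hard error naming the gene
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sp\tm1\t1\tcox1\t+", "sp\tm2\t1\tcox1\t+"), dup)
  expect_error(load_catalog(dup), "cox1")

  # malformed row -> error with line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sp\tm1\t1\tcox1\t+", "sp\tm1\tnot-a-number"), bad)
  expect_error(load_catalog(bad), "line 2")

  # unknown gene symbols rejected
  unk <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sp\tm1\t1\tfoo\t+", unk)
  expect_error(load_catalog(unk), "unknown gene")
})

test_that("catalog equality is rotation-invariant but orientation- and
          reflection-sensitive", {
  e <- data.frame(gene = c("trnM", "trnL1", "rrnL", "trnV"),
                  orientation = c("+", "+", "+", "+"),
                  stringsAsFactors = FALSE)
  rot <- e[c(3, 4, 1, 2), ]
  rownames(rot) <- NULL
  a <- arrangement_catalog("s", list(m = e))
  b <- arrangement_catalog("s", list(m = rot))
  expect_true(catalogs_equal(a, b))
  # reflection is NOT equality
  refl <- e[rev(seq_len(nrow(e))), ]
  rownames(refl) <- NULL
  expect_false(catalogs_equal(a, arrangement_catalog("s", list(m = refl))))
  # orientation flips break equality
  flip <- e
  flip$orientation[2] <- "-"
  expect_false(catalogs_equal(a, arrangement_catalog("s", list(m = flip))))
})

test_that("packaged catalogs carry the published gene and
          minichromosome counts", {
  for (sp in c("asiatica", "spinulosa")) {
    cat_ <- polyplax_catalog(sp)
    expect_equal(length(cat_$entries), 11)
    genes <- unlist(lapply(cat_$entries, `[[`, "gene"))
    expect_equal(length(unique(genes)), 37)
    expect_setequal(genes, mt_gene_names())
  }
})

test_that("genome_to_catalog orders genes by start and survives rotation", {
  sim <- generate_genome(simulation_config(seed = 42))
  cat_truth <- sim$truth$catalog
  derived <- genome_to_catalog(sim$genome)
  expect_true(catalogs_equal(derived, cat_truth))

  # rotating a minichromosome's sequence+annotation leaves its catalog
  # entry equal (rotation invariance)
  m <- sim$genome$minichromosomes[[4]]
  len <- nchar(m$sequence)
  shift <- 731L
  g <- m$genes
  g$start <- (g$start + shift) %% len
  g$end <- g$start + (m$genes$end - m$genes$start)
  rot <- minichromosome(m$id, minichrom:::rotate_seq(m$sequence,
                                                     len - shift + 1L), g)
  one <- fragmented_genome(sim$genome$species, list(rot))
  entry_rot <- genome_to_catalog(one)$entries[[m$id]]
  expect_true(minichrom:::entries_equal(
    entry_rot, derived$entries[[m$id]]))
})
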