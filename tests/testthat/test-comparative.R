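test_that("the two rat-louse catalogs share exactly 2 identical
          minichromosomes and differ in 8 tRNA placements", {
  pa <- polyplax_catalog("asiatica")
  ps <- polyplax_catalog("spinulosa")
  cmp <- compare_catalogs(pa, ps)
  expect_equal(cmp$n_identical, 2)
  expect_setequal(cmp$identical_minichromosomes,
                  c("atp8-atp6", "E-cob-I"))
  expect_equal(cmp$n_differing_trnas, 8)
  expect_setequal(cmp$differing_trnas,
                  c("trnL1", "trnL2", "trnT", "trnA", "trnP", "trnF",
                    "trnS1", "trnS2"))
  expect_equal(cmp$n_differing_pcg_rrna, 0)
  # symmetry of the counts
  rev_cmp <- compare_catalogs(ps, pa)
  expect_equal(rev_cmp$n_identical, cmp$n_identical)
  expect_equal(rev_cmp$n_differing_trnas, cmp$n_differing_trnas)
})

test_that("a catalog equals itself everywhere and incomplete catalogs are
          refused", {
  pa <- polyplax_catalog("asiatica")
  self <- compare_catalogs(pa, pa)
  expect_equal(self$n_identical, 11)
  expect_equal(self$n_differing_trnas, 0)
  expect_error(compare_catalogs(toy_catalog(), pa), "incomplete")
})

test_that("Dollo inference places shared arrangements at the correct
          ancestors", {
  st <- infer_ancestral_states(junction_characters())
  at <- function(ch, nd) st$state[st$character == ch & st$node == nd]
  # rrnS-trnC present in Pa + both pigs -> ancestral at the root
  expect_equal(at("rrnS-trnC_minichromosome", "root"), "present")
  expect_equal(at("rrnS-trnC_minichromosome", "human_lice"), "absent")
  # cox3-trnA present in rat, pig and human lice -> present everywhere
  expect_true(all(st$state[st$character == "cox3-trnA"] == "present"))
  # single-species state: ambiguous at every internal node
  solo <- infer_ancestral_states(list(x = "Polyplax_spinulosa"))
  expect_true(all(solo$state == "ambiguous"))
  # unknown label rejected
  expect_error(infer_ancestral_states(list(x = "no_such_louse")),
               "unknown species")
})

test_that("Dollo inference matches an exhaustive single-gain parsimony
          oracle on the quoted junction characters", {
  tree <- louse_phylogeny()
  chars <- junction_characters()
  st <- infer_ancestral_states(chars, tree)
  n_tip <- length(tree$tip.label)
  node_ids <- n_tip + seq_len(tree$Nnode)
  # oracle: enumerate single-gain scenarios (gain at any node covering all
  # present leaves, losses on maximal absent subtrees), keep the
  # minimum-event ones, and read off each internal node's state
  tips_below <- function(nd) {
    if (nd <= n_tip) return(nd)
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    unlist(lapply(kids, tips_below))
  }
  ancestors <- function(nd) {
    out <- integer(0)
    repeat {
      p <- tree$edge[tree$edge[, 2] == nd, 1]
      if (!length(p)) break
      out <- c(out, p); nd <- p
    }
    out
  }
  for (ch in names(chars)) {
    pres <- match(chars[[ch]], tree$tip.label)
    covering <- node_ids[vapply(node_ids, function(nd)
      all(pres %in% tips_below(nd)), TRUE)]
    scenarios <- lapply(covering, function(gain) {
      # minimal losses: prune maximal subtrees under gain with no carrier
      present_nodes <- covering_states <- vapply(node_ids, function(nd) {
        in_gain <- nd == gain || gain %in% ancestors(nd)
        in_gain && length(intersect(tips_below(nd), pres)) > 0
      }, TRUE)
      losses <- 0
      walk <- function(nd, state) {
        kids <- tree$edge[tree$edge[, 1] == nd, 2]
        for (kid in kids) {
          kid_has <- length(intersect(tips_below(kid), pres)) > 0
          if (state && !kid_has) losses <<- losses + 1
          if (kid > n_tip) walk(kid, state && kid_has)
        }
      }
      walk(gain, TRUE)
      list(states = present_nodes, cost = 1 + losses)
    })
    costs <- vapply(scenarios, `[[`, 0, "cost")
    minimal <- scenarios[costs == min(costs)]
    for (i in seq_along(node_ids)) {
      in_all <- all(vapply(minimal, function(s) s$states[i], TRUE))
      in_none <- !any(vapply(minimal, function(s) s$states[i], TRUE))
      oracle <- if (in_all) "present" else if (in_none) "absent" else
        "ambiguous"
      nd_name <- tree$node.label[i]
      got <- st$state[st$character == ch & st$node == nd_name]
      expect_equal(got, oracle,
                   info = paste(ch, nd_name))
    }
  }
})

test_that("event classification recovers the lineage-specific
          translocations and the leucine identity swap", {
  anc <- polyplax_catalog("ancestor")
  ps <- polyplax_catalog("spinulosa")
  pa <- polyplax_catalog("asiatica")
  ev_ps <- classify_events(anc, ps)
  expect_setequal(ev_ps$type,
                  c("identity_swap", "translocation"))
  expect_equal(sum(ev_ps$type == "identity_swap"), 1)
  expect_equal(ev_ps$genes[ev_ps$type == "identity_swap"],
               "trnL1,trnL2")
  tr <- ev_ps$genes[ev_ps$type == "translocation"]
  expect_setequal(tr, c("trnT", "trnA", "trnS1,trnS2"))
  ev_pa <- classify_events(anc, pa)
  expect_true(all(ev_pa$type == "translocation"))
  expect_setequal(ev_pa$genes, c("trnP", "trnF"))
})

test_that("event recovery on synthetic sister genomes is exact, with
          remnant and sequence evidence attached", {
  anc <- generate_genome(
    simulation_config(seed = 81,
                      gene_partition = polyplax_catalog("ancestor")),
    species = "anc")
  sis <- derive_sister(anc, ps_lineage_events(), seed = 82)
  ev <- classify_events(anc$truth$catalog, sis$truth$catalog,
                        sequences = list(
                          ancestral = as.list(anc$truth$reference_genes),
                          derived = as.list(sis$truth$reference_genes),
                          derived_genome = sis$genome))
  expect_equal(nrow(ev), 4)
  expect_equal(ev$evidence[ev$genes == "trnL1,trnL2"],
               "sequence_similarity")
  expect_equal(ev$evidence[ev$genes == "trnT"], "pseudogene_remnant")
  # truth event set and classified set agree exactly
  truth_key <- sort(vapply(sis$truth$events, function(e)
    paste(e$type, paste(sort(e$genes), collapse = ","), sep = ":"), ""))
  got_key <- sort(paste(ev$type, vapply(strsplit(ev$genes, ","),
                                        function(g)
                                          paste(sort(g), collapse = ","),
                                        ""), sep = ":"))
  expect_identical(got_key, truth_key)
})
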