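# Cross-species comparison of arrangement catalogs, Dollo-style
# ancestral-state inference of gene-arrangement characters on the fixed
# louse phylogeny, and classification of rearrangement events
# (translocation, identity swap, pseudogenization).

#' Compare two arrangement catalogs
#'
#' Identifies (i) minichromosomes with identical gene content, circular
#' order and orientation between the two species; (ii) tRNA genes whose
#' host minichromosome differs, where a tRNA's host is keyed by the set of
#' protein-coding and rRNA genes on its minichromosome (a tRNA that merely
#' changes position within an unchanged host does not count); and (iii)
#' the same for protein-coding/rRNA genes, keyed by the other
#' protein-coding/rRNA genes they share a minichromosome with.
#'
#' @param cat_a,cat_b complete [arrangement_catalog()] objects (all 37
#'   genes).
#' @return list with `identical_minichromosomes` (character vector of ids
#'   in `cat_a`), `n_identical`, `differing_trnas`, `n_differing_trnas`,
#'   `differing_pcg_rrna`, `n_differing_pcg_rrna`.
#' @export
compare_catalogs <- function(cat_a, cat_b) {
  for (cat_ in list(cat_a, cat_b)) {
    genes <- unlist(lapply(cat_$entries, `[[`, "gene"))
    genes <- genes[is_canonical_gene(genes)]
    if (!setequal(genes, mt_gene_names()))
      stop("catalog for ", cat_$species,
           " is incomplete (needs all 37 genes)")
  }
  ids <- character(0)
  used <- rep(FALSE, length(cat_b$entries))
  for (i in seq_along(cat_a$entries)) {
    for (j in seq_along(cat_b$entries)) {
      if (!used[j] && entries_equal(cat_a$entries[[i]],
                                    cat_b$entries[[j]])) {
        ids <- c(ids, names(cat_a$entries)[i])
        used[j] <- TRUE
        break
      }
    }
  }
  host_a <- gene_hosts(cat_a)
  host_b <- gene_hosts(cat_b)
  tab <- mt_gene_table()
  trnas <- tab$name[tab$category == "tRNA"]
  big <- tab$name[tab$category %in% c("PCG", "rRNA")]
  diff_t <- trnas[vapply(trnas, function(g)
    !identical(host_a[[g]], host_b[[g]]), TRUE)]
  # a PCG/rRNA's host context excludes the gene itself
  diff_big <- big[vapply(big, function(g)
    !identical(setdiff(host_a[[g]], g), setdiff(host_b[[g]], g)), TRUE)]
  list(identical_minichromosomes = ids, n_identical = length(ids),
       differing_trnas = sort(diff_t),
       n_differing_trnas = length(diff_t),
       differing_pcg_rrna = sort(diff_big),
       n_differing_pcg_rrna = length(diff_big))
}

# Map each canonical gene to its host key (sorted PCG/rRNA content of its
# minichromosome).
gene_hosts <- function(catalog) {
  out <- list()
  for (id in names(catalog$entries)) {
    e <- catalog$entries[[id]]
    key <- catalog$host_key[[id]]
    for (g in e$gene) {
      if (is_canonical_gene(g)) out[[g]] <- key
    }
  }
  out
}

#' Infer ancestral presence of arrangement characters (Dollo)
#'
#' Each character is the presence/absence of an arrangement state (a gene
#' adjacency or a whole-minichromosome gene list) across species. Under
#' the Dollo assumption the state arises once and can only be lost: the
#' state is inferred `present` at the most recent common ancestor (MRCA)
#' of the species carrying it — provided at least two lineages corroborate
#' it — and at every node between that MRCA and a carrier; `absent` below
#' the MRCA where no descendant carries it; and `ambiguous` above the MRCA
#' (presence confined to one child subtree) or everywhere when only a
#' single species carries the state.
#'
#' @param characters named list; each element is a character vector of the
#'   species (tree tips) carrying that state.
#' @param tree rooted `phylo` tree with named internal nodes (default: the
#'   packaged louse phylogeny).
#' @return data frame with one row per (character, internal node) and
#'   columns `character`, `node`, `state`
#'   (`"present"`/`"absent"`/`"ambiguous"`).
#' @export
infer_ancestral_states <- function(characters, tree = louse_phylogeny()) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  node_ids <- n_tip + seq_len(tree$Nnode)
  node_names <- tree$node.label
  if (is.null(node_names)) node_names <- paste0("node", node_ids)
  rows <- list()
  for (ch in names(characters)) {
    present <- characters[[ch]]
    unknown <- setdiff(present, tips)
    if (length(unknown))
      stop("unknown species label(s): ", paste(unknown, collapse = ", "))
    pres_tips <- match(present, tips)
    states <- rep("absent", tree$Nnode)
    names(states) <- node_names
    if (length(pres_tips) == 1) {
      states[] <- "ambiguous"
    } else if (length(pres_tips) >= 2) {
      mrca <- ape::getMRCA(tree, pres_tips)
      desc <- descendant_tips(tree)
      for (i in seq_along(node_ids)) {
        nd <- node_ids[i]
        has_present <- length(intersect(desc[[nd]], pres_tips)) > 0
        if (nd == mrca || (is_descendant(tree, nd, mrca) && has_present)) {
          states[i] <- "present"
        } else if (nd %in% ancestor_chain(tree, mrca)) {
          states[i] <- "ambiguous"
        } else {
          states[i] <- "absent"
        }
      }
    }
    rows[[ch]] <- data.frame(character = ch, node = node_names,
                             state = unname(states),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# tips below each node (list indexed by node id; tips map to themselves)
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  desc <- vector("list", n_all)
  for (t in seq_len(n_tip)) desc[[t]] <- t
  # edges in pruningwise-ish order: iterate until stable
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      if (!is.null(desc[[chl]])) {
        new <- union(desc[[par]], desc[[chl]])
        if (!identical(sort(new), sort(desc[[par]] %||% integer(0)))) {
          desc[[par]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  desc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chain of strict ancestors of `node` up to the root (node ids)
ancestor_chain <- function(tree, node) {
  out <- integer(0)
  repeat {
    par <- tree$edge[tree$edge[, 2] == node, 1]
    if (!length(par)) break
    out <- c(out, par)
    node <- par
  }
  out
}

is_descendant <- function(tree, node, anc) {
  anc %in% ancestor_chain(tree, node)
}

#' Classify rearrangement events between an ancestral and a derived catalog
#'
#' For each gene whose host minichromosome (keyed by PCG/rRNA content)
#' changed between ancestor and descendant: if two tRNA genes of the same
#' isoacceptor family exactly exchanged host contexts — and, when
#' sequences are available, each derived gene is more similar to the
#' ancestral occupant of its position than to its own ancestral copy — the
#' pair is classified as one `identity_swap`; otherwise each moved gene
#' (or block of adjacent co-moving genes) is a `translocation`. When
#' sequences are given, a remnant of the moved gene detected at its
#' ancestral site (via [detect_pseudogene()]) attaches
#' `pseudogene_remnant` evidence; and catalogs that list pseudo-genes
#' attach the same evidence without sequences.
#'
#' @param ancestral,derived complete [arrangement_catalog()] objects.
#' @param sequences optional list with named gene sequence vectors
#'   `ancestral` and `derived`, plus optionally `derived_genome` (a
#'   [fragmented_genome()] for remnant search).
#' @return data frame with columns `type`, `genes`, `source_host`,
#'   `dest_host`, `evidence`.
#' @export
classify_events <- function(ancestral, derived, sequences = NULL) {
  host_a <- gene_hosts(ancestral)
  host_d <- gene_hosts(derived)
  tab <- mt_gene_table()
  moved <- names(host_a)[vapply(names(host_a), function(g)
    !identical(host_a[[g]], host_d[[g]]), TRUE)]
  events <- list()
  handled <- character(0)
  key_str <- function(k) paste(k, collapse = "+")
  # identity swaps: same-family tRNA pairs that exactly exchanged contexts
  trn_moved <- moved[is_trna_gene(moved)]
  fams <- split(trn_moved, trna_family(trn_moved))
  for (fam in fams) {
    if (length(fam) != 2) next
    g1 <- fam[1]; g2 <- fam[2]
    if (identical(host_d[[g1]], host_a[[g2]]) &&
        identical(host_d[[g2]], host_a[[g1]])) {
      evid <- "arrangement_only"
      if (!is.null(sequences)) {
        sim <- function(x, y) {
          longest_shared_stretch(x, y)$length / max(nchar(x), nchar(y))
        }
        anc <- sequences$ancestral; der <- sequences$derived
        ok <- !is.null(anc[[g1]]) && !is.null(anc[[g2]]) &&
          !is.null(der[[g1]]) && !is.null(der[[g2]])
        if (ok) {
          # derived gene at g2's old locus carries g1's name iff swapped:
          # each derived gene should resemble the *other* ancestral gene's
          # locus sequence more than its own ancestral copy
          s_keep <- sim(der[[g1]], anc[[g1]]) + sim(der[[g2]], anc[[g2]])
          s_swap <- sim(der[[g1]], anc[[g2]]) + sim(der[[g2]], anc[[g1]])
          if (s_swap >= s_keep) evid <- "sequence_similarity"
        }
      }
      events[[length(events) + 1]] <- data.frame(
        type = "identity_swap", genes = paste(sort(fam), collapse = ","),
        source_host = key_str(host_a[[g1]]),
        dest_host = key_str(host_a[[g2]]),
        evidence = evid, stringsAsFactors = FALSE)
      handled <- c(handled, fam)
    }
  }
  # translocations: group adjacent co-moving genes into blocks
  rest <- setdiff(moved, handled)
  if (length(rest)) {
    blocks <- comoving_blocks(rest, ancestral, derived, host_a, host_d)
    # pseudogene remnants listed in the derived catalog (either as rows or
    # in the side list produced by genome_to_catalog())
    derived_pseudo <- c(
      unlist(lapply(derived$entries, function(e)
        e$gene[startsWith(e$gene, "pseudo-")])),
      unlist(lapply(attr(derived, "pseudogenes"), `[[`, "name")))
    for (blk in blocks) {
      evid <- "arrangement_only"
      if (paste0("pseudo-", blk[1]) %in% derived_pseudo) {
        evid <- "pseudogene_remnant"
      } else if (!is.null(sequences) &&
                 !is.null(sequences$derived_genome)) {
        rem <- remnant_at_ancestral_site(
          sequences$derived_genome, blk[1],
          sequences$ancestral[[blk[1]]], host_a[[blk[1]]])
        if (rem) evid <- "pseudogene_remnant"
      }
      events[[length(events) + 1]] <- data.frame(
        type = "translocation", genes = paste(blk, collapse = ","),
        source_host = key_str(host_a[[blk[1]]]),
        dest_host = key_str(host_d[[blk[1]]]),
        evidence = evid, stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) {
    return(data.frame(type = character(0), genes = character(0),
                      source_host = character(0),
                      dest_host = character(0),
                      evidence = character(0)))
  }
  out <- do.call(rbind, events)
  out[order(out$type, out$genes), ]
}

# Group moved genes into blocks that are adjacent (consecutive) in both the
# ancestral and the derived arrangement, moving between the same hosts.
comoving_blocks <- function(moved, ancestral, derived, host_a, host_d) {
  adjacency_rank <- function(catalog) {
    rank <- list()
    for (id in names(catalog$entries)) {
      e <- catalog$entries[[id]]
      for (i in seq_len(nrow(e)))
        rank[[e$gene[i]]] <- c(mc = id, pos = i)
    }
    rank
  }
  ra <- adjacency_rank(ancestral)
  rd <- adjacency_rank(derived)
  ord <- moved[order(vapply(moved, function(g) ra[[g]]["mc"], ""),
                     as.integer(vapply(moved, function(g)
                       ra[[g]]["pos"], "")))]
  blocks <- list()
  cur <- ord[1]
  for (g in ord[-1]) {
    prev <- tail(cur, 1)
    same_src <- identical(host_a[[g]], host_a[[prev]])
    same_dst <- identical(host_d[[g]], host_d[[prev]])
    adj_a <- identical(ra[[g]]["mc"], ra[[prev]]["mc"]) &&
      as.integer(ra[[g]]["pos"]) == as.integer(ra[[prev]]["pos"]) + 1L
    adj_d <- identical(rd[[g]]["mc"], rd[[prev]]["mc"]) &&
      abs(as.integer(rd[[g]]["pos"]) -
            as.integer(rd[[prev]]["pos"])) == 1L
    if (same_src && same_dst && adj_a && adj_d) {
      cur <- c(cur, g)
    } else {
      blocks[[length(blocks) + 1]] <- cur
      cur <- g
    }
  }
  blocks[[length(blocks) + 1]] <- cur
  blocks
}

# Does the derived genome retain a detectable remnant of `gene` on the
# minichromosome whose PCG/rRNA content matches the ancestral host key?
remnant_at_ancestral_site <- function(genome, gene, gene_seq, host_key) {
  if (is.null(gene_seq)) return(FALSE)
  for (m in genome$minichromosomes) {
    key <- sort(m$genes$name[m$genes$category %in% c("PCG", "rRNA")])
    if (!identical(key, host_key)) next
    if (is.na(m$sequence)) return(FALSE)
    hits <- detect_pseudogene(m$sequence, gene_seq)
    return(nrow(hits) > 0)
  }
  FALSE
}
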