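# Arrangement catalogs: the sequence-free representation of gene order and
# orientation per minichromosome for one species. Equality of minichromosome
# entries is rotation-invariant on the circular order (reflection is not
# equality: orientation is meaningful).

#' Construct an arrangement catalog
#'
#' @param species species label.
#' @param entries named list; each element is a data frame with columns
#'   `gene` and `orientation` (`"+"`/`"-"`), giving the circular gene order
#'   of one minichromosome read from the reference strand.
#' @return object of class `arrangement_catalog` with a `host_key` per entry
#'   (the set of protein-coding and rRNA genes it carries, used to identify
#'   "the same" minichromosome across species).
#' @export
arrangement_catalog <- function(species, entries) {
  all_genes <- unlist(lapply(entries, `[[`, "gene"))
  canon <- all_genes[is_canonical_gene(all_genes)]
  unknown <- setdiff(all_genes,
                     c(mt_gene_names(),
                       paste0("pseudo-", mt_gene_names())))
  if (length(unknown))
    stop("unknown gene symbol(s): ", paste(unknown, collapse = ", "))
  dup <- unique(canon[duplicated(canon)])
  if (length(dup))
    stop("duplicate gene(s) across minichromosomes: ",
         paste(dup, collapse = ", "))
  host_key <- lapply(entries, function(e) {
    cat_ <- gene_category(e$gene)
    sort(e$gene[cat_ %in% c("PCG", "rRNA")])
  })
  structure(list(species = species, entries = entries, host_key = host_key),
            class = "arrangement_catalog")
}

#' @export
print.arrangement_catalog <- function(x, ...) {
  cat("<arrangement_catalog> ", x$species, ": ", length(x$entries),
      " minichromosomes, ",
      sum(vapply(x$entries, nrow, 0L)), " genes\n", sep = "")
  for (id in names(x$entries)) {
    e <- x$entries[[id]]
    cat("  ", id, ": ",
        paste0(ifelse(e$orientation == "-", "-", ""), e$gene,
               collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# Canonical rotation of one entry: rotate the circular order so that the
# string rendering is lexicographically smallest. Used for rotation-invariant
# equality.
canonical_entry <- function(entry) {
  n <- nrow(entry)
  if (n == 0) return(entry)
  render <- function(e) paste(e$gene, e$orientation, collapse = "|")
  rots <- lapply(seq_len(n), function(k) {
    idx <- c(seq(k, n), if (k > 1) seq_len(k - 1))
    entry[idx, , drop = FALSE]
  })
  keys <- vapply(rots, render, "")
  best <- rots[[which.min(rank(keys, ties.method = "first"))]]
  rownames(best) <- NULL
  best
}

# Rotation-invariant equality of two entries (orientation-sensitive).
entries_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  ca <- canonical_entry(a); cb <- canonical_entry(b)
  identical(ca$gene, cb$gene) && identical(ca$orientation, cb$orientation)
}

#' Test two catalogs for rotation-invariant equality
#'
#' Minichromosome entries are matched by id when ids coincide, otherwise by
#' canonical form; each entry is compared up to rotation of its circular
#' gene order.
#'
#' @param a,b [arrangement_catalog()] objects.
#' @return logical.
#' @export
catalogs_equal <- function(a, b) {
  if (length(a$entries) != length(b$entries)) return(FALSE)
  used <- rep(FALSE, length(b$entries))
  for (ea in a$entries) {
    hit <- FALSE
    for (j in seq_along(b$entries)) {
      if (!used[j] && entries_equal(ea, b$entries[[j]])) {
        used[j] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Read an arrangement catalog from TSV
#'
#' Expected columns: `species`, `minichrom_id`, `ordinal`, `gene`,
#' `orientation` (`+`/`-`). Lines starting with `#` are comments. The file
#' must describe a single species.
#'
#' @param path path to the TSV file.
#' @return [arrangement_catalog()].
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (!length(body)) return(arrangement_catalog("<empty>", list()))
  lineno <- which(keep)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5)
  if (length(bad))
    stop("malformed catalog row at line ", lineno[bad[1]],
         ": expected 5 tab-separated fields")
  df <- data.frame(
    species = vapply(parts, `[[`, "", 1),
    minichrom_id = vapply(parts, `[[`, "", 2),
    ordinal = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3))),
    gene = vapply(parts, `[[`, "", 4),
    orientation = vapply(parts, `[[`, "", 5),
    stringsAsFactors = FALSE)
  if (anyNA(df$ordinal))
    stop("malformed catalog row at line ",
         lineno[which(is.na(df$ordinal))[1]], ": non-integer ordinal")
  if (any(!df$orientation %in% c("+", "-")))
    stop("malformed catalog row at line ",
         lineno[which(!df$orientation %in% c("+", "-"))[1]],
         ": orientation must be + or -")
  sp <- unique(df$species)
  if (length(sp) > 1)
    stop("catalog file mixes species: ", paste(sp, collapse = ", "))
  entries <- lapply(split(df, df$minichrom_id), function(d) {
    d <- d[order(d$ordinal), ]
    data.frame(gene = d$gene, orientation = d$orientation,
               stringsAsFactors = FALSE)
  })
  # preserve first-appearance order of minichromosomes
  entries <- entries[unique(df$minichrom_id)]
  arrangement_catalog(sp, entries)
}

#' Write an arrangement catalog to TSV
#'
#' Canonical ordering: minichromosomes in their catalog order, genes by
#' ordinal. `load_catalog(write_catalog(x))` round-trips losslessly.
#'
#' @param catalog [arrangement_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  rows <- character(0)
  for (id in names(catalog$entries)) {
    e <- catalog$entries[[id]]
    if (!nrow(e)) next
    rows <- c(rows, paste(catalog$species, id, seq_len(nrow(e)),
                          e$gene, e$orientation, sep = "\t"))
  }
  writeLines(c("# species\tminichrom_id\tordinal\tgene\torientation", rows),
             path)
  invisible(path)
}

#' Derive the arrangement catalog of an annotated genome
#'
#' Gene order follows increasing start position along the coding region read
#' from the reference strand. Pseudogenes are excluded from the canonical
#' order and returned in the `pseudogenes` attribute.
#'
#' @param genome annotated [fragmented_genome()].
#' @return [arrangement_catalog()]; attribute `pseudogenes` holds a data
#'   frame of pseudogene annotations per minichromosome.
#' @export
genome_to_catalog <- function(genome) {
  if (!length(genome$minichromosomes)) stop("empty genome")
  annotated <- vapply(genome$minichromosomes,
                      function(m) is.data.frame(m$genes), TRUE)
  if (!all(annotated)) stop("genome is not annotated")
  pseudo <- list()
  entries <- lapply(genome$minichromosomes, function(m) {
    g <- m$genes[order(m$genes$start), , drop = FALSE]
    p <- g[g$category == "pseudogene", , drop = FALSE]
    g <- g[g$category != "pseudogene", , drop = FALSE]
    if (nrow(p)) pseudo[[m$id]] <<- p
    data.frame(gene = g$name, orientation = g$orientation,
               stringsAsFactors = FALSE)
  })
  out <- arrangement_catalog(genome$species, entries)
  attr(out, "pseudogenes") <- pseudo
  out
}
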