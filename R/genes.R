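# The canonical 37-gene vocabulary of bilaterian mitochondrial genomes:
# 13 protein-coding genes, 2 rRNA genes, 22 tRNA genes. tRNA symbols use
# single amino-acid letters, with the two leucine and two serine isoacceptors
# disambiguated by their anticodons (L1 = UAG-type, L2 = UAA-type,
# S1 = UCU-type, S2 = UGA-type).

.PCG_NAMES <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
                "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
.RRNA_NAMES <- c("rrnS", "rrnL")
.TRNA_ANTICODONS <- c(
  A = "UGC", C = "GCA", D = "GUC", E = "UUC", F = "GAA", G = "UCC",
  H = "GUG", I = "GAU", K = "UUU", L1 = "UAG", L2 = "UAA", M = "CAU",
  N = "GUU", P = "UGG", Q = "UUG", R = "UCG", S1 = "UCU", S2 = "UGA",
  T = "UGU", V = "UAC", W = "UCA", Y = "GUA")

#' Canonical mitochondrial gene vocabulary
#'
#' The 37 genes of a typical animal mitochondrial genome: 13 protein-coding
#' genes (PCGs), 2 ribosomal RNA genes and 22 transfer RNA genes. tRNAs are
#' named by amino-acid letter; the leucine and serine isoacceptor pairs are
#' distinguished as L1/L2 and S1/S2 by anticodon.
#'
#' @return A data frame with columns `name`, `category` (`"PCG"`, `"rRNA"`,
#'   `"tRNA"`), `anticodon` (RNA alphabet, empty for non-tRNAs) and `family`
#'   (amino-acid letter for tRNAs, used to recognise isoacceptor pairs).
#' @export
#' @examples
#' nrow(mt_gene_table())  # 37
mt_gene_table <- function() {
  trna <- names(.TRNA_ANTICODONS)
  data.frame(
    name = c(.PCG_NAMES, .RRNA_NAMES, paste0("trn", trna)),
    category = c(rep("PCG", 13), rep("rRNA", 2), rep("tRNA", 22)),
    anticodon = c(rep("", 15), unname(.TRNA_ANTICODONS)),
    family = c(rep("", 15), sub("[12]$", "", trna)),
    stringsAsFactors = FALSE
  )
}

#' @rdname mt_gene_table
#' @export
mt_gene_names <- function() mt_gene_table()$name

# Category lookup for one gene symbol; pseudogenes carry a "pseudo-" prefix.
gene_category <- function(name) {
  tab <- mt_gene_table()
  ifelse(startsWith(name, "pseudo-"), "pseudogene",
         tab$category[match(name, tab$name)])
}

is_canonical_gene <- function(name) name %in% mt_gene_names()

is_trna_gene <- function(name) startsWith(name, "trn") &
  name %in% mt_gene_names()

# Amino-acid family of a tRNA symbol ("trnL1" -> "L"); NA for non-tRNAs.
trna_family <- function(name) {
  tab <- mt_gene_table()
  fam <- tab$family[match(name, tab$name)]
  fam[fam == ""] <- NA_character_
  fam
}

# Anticodon (RNA alphabet) for a tRNA symbol.
trna_anticodon <- function(name) {
  key <- sub("^trn", "", name)
  unname(.TRNA_ANTICODONS[key])
}
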