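# Internal helpers shared across modules.

#' Round half away from zero to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; published gene-per-minichromosome
#' ratios use conventional half-up rounding (e.g. 37/11 = 3.3636 -> 3.4,
#' 332/22 = 15.09 -> 15.1), so that rule is applied throughout.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.25, 1)  # 2.3, where round() gives 2.2
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package funnel
# through this so a single user-facing seed determines every draw.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive the k-th child seed from a parent seed. Simple LCG split: keeps all
# derived seeds inside the 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * k) %% 2147483562) + 1L
}

# Reverse complement for plain character strings (Biostrings does the work).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Rotate a circular sequence so it starts at (1-based) position `start`.
rotate_seq <- function(x, start) {
  n <- nchar(x)
  start <- ((start - 1L) %% n) + 1L
  if (start == 1L) return(x)
  paste0(substr(x, start, n), substr(x, 1L, start - 1L))
}

# Random DNA of length n with per-base probabilities (A, C, G, T).
random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Apply substitutions to a sequence at a given per-base rate; always mutates
# to a *different* base.
mutate_seq <- function(x, rate) {
  if (rate <= 0 || nchar(x) == 0) return(x)
  bases <- strsplit(x, "")[[1]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    bases[hit] <- mapply(function(b, i) alt[[b]][i], bases[hit], pick)
  }
  paste(bases, collapse = "")
}
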