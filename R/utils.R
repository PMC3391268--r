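#' @importFrom methods is
#' @importFrom stats rnorm runif setNames prcomp cor
#' @importFrom utils head tail write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 31-bit hash of a string, for deriving per-label sub-seeds.
str_seed <- function(x, base = 0L) {
  h <- as.numeric(base)
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Hamming mismatches between two equal-length strings (vectorised over pairs).
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  va <- strsplit(a, "")
  vb <- strsplit(b, "")
  mapply(function(x, y) sum(x != y), va, vb, USE.NAMES = FALSE)
}

# Vectorised mismatch counts for many equal-width string pairs (fast path for
# read extension); positions where either string has a non-ACGT letter can be
# excluded from both numerator and denominator.
mismatch_profile <- function(a, b, exclude_ambiguous = FALSE) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(data.frame(mismatches = integer(), compared = integer()))
  w <- nchar(a)
  stopifnot(all(nchar(b) == w))
  out_m <- integer(length(a))
  out_n <- integer(length(a))
  for (wd in unique(w)) {
    i <- which(w == wd)
    ma <- matrix(unlist(strsplit(a[i], ""), use.names = FALSE), nrow = wd)
    mb <- matrix(unlist(strsplit(b[i], ""), use.names = FALSE), nrow = wd)
    if (exclude_ambiguous) {
      ok <- (ma %in% DNA_BASES) & (mb %in% DNA_BASES)
      dim(ok) <- dim(ma)
      out_m[i] <- as.integer(colSums((ma != mb) & ok))
      out_n[i] <- as.integer(colSums(ok))
    } else {
      out_m[i] <- as.integer(colSums(ma != mb))
      out_n[i] <- wd
    }
  }
  data.frame(mismatches = out_m, compared = out_n)
}

# Substitute each site independently with probability p, drawing uniformly
# among the three alternative bases. Operates on a plain character string.
mutate_dna <- function(x, p) {
  if (p <= 0) return(x)
  v <- strsplit(x, "")[[1]]
  hit <- which(runif(length(v)) < p & v %in% DNA_BASES)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  paste(v, collapse = "")
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutate_peptide <- function(x, rate, seed = NULL) {
  with_seed(seed, {
    v <- strsplit(x, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    if (length(hit)) {
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(AA_ALPHABET20, b), 1L), "")
    }
    paste(v, collapse = "")
  })
}

# Most-used codon per amino acid: fixed reverse-translation table so planted
# peptides round-trip exactly through translation.
CODON_OF <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT", H = "CAT",
  I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT", P = "CCT", Q = "CAA",
  R = "CGT", S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT", `*` = "TAA"
)

reverse_translate <- function(pep) {
  paste(CODON_OF[strsplit(pep, "")[[1]]], collapse = "")
}

frac_at <- function(x) {
  v <- strsplit(toupper(x), "")[[1]]
  mean(v %in% c("A", "T"))
}

frac_purine <- function(x) {
  v <- strsplit(toupper(x), "")[[1]]
  mean(v %in% c("A", "G"))
}

as_dna_set <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  Biostrings::DNAStringSet(x)
}

stop_config <- function(...) stop(paste0(...), call. = FALSE)
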