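# Thin wrappers around Biostrings::pairwiseAlignment used across modules, plus
# a k-mer prescreen that avoids all-vs-all alignment of unrelated sequences.

.NUC_MAT <- NULL

nuc_mat <- function() {
  if (is.null(.NUC_MAT))
    utils::assignInMyNamespace(".NUC_MAT", Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3))
  .NUC_MAT
}

# Pairwise nucleotide alignment summary. identity = matched / aligned columns
# (gap columns included in the denominator); coverage = fraction of the
# shorter sequence inside the aligned region.
align_nt <- function(a, b, type = "local", gap_open = 5, gap_ext = 2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = nuc_mat(), gapOpening = gap_open, gapExtension = gap_ext)
  alen <- Biostrings::nchar(aln)
  p <- aln@pattern@range
  s <- aln@subject@range
  shorter <- min(nchar(a), nchar(b))
  aligned_shorter <- if (nchar(a) <= nchar(b)) BiocGenerics::width(p) else BiocGenerics::width(s)
  list(score = Biostrings::score(aln),
       identity = if (alen > 0) Biostrings::nmatch(aln) / alen else 0,
       aligned_len = alen,
       p_start = BiocGenerics::start(p), p_end = BiocGenerics::end(p),
       s_start = BiocGenerics::start(s), s_end = BiocGenerics::end(s),
       coverage_shorter = aligned_shorter / shorter,
       pattern_aln = as.character(Biostrings::alignedPattern(aln)),
       subject_aln = as.character(Biostrings::alignedSubject(aln)))
}

align_aa <- function(a, b, type = "local", gap_open = 10, gap_ext = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = type,
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open, gapExtension = gap_ext)
  alen <- Biostrings::nchar(aln)
  p <- aln@pattern@range
  s <- aln@subject@range
  list(score = Biostrings::score(aln),
       identity = if (alen > 0) Biostrings::nmatch(aln) / alen else 0,
       aligned_len = alen,
       p_start = BiocGenerics::start(p), p_end = BiocGenerics::end(p),
       s_start = BiocGenerics::start(s), s_end = BiocGenerics::end(s),
       pattern_aln = as.character(Biostrings::alignedPattern(aln)),
       subject_aln = as.character(Biostrings::alignedSubject(aln)))
}

# TRUE when the two sequences share at least one exact k-mer; cheap screen
# before committing to a full dynamic-programming alignment.
share_kmer <- function(a, b, k = 16) {
  if (nchar(a) < k || nchar(b) < k) return(a == b)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1), k:nchar(b)))
  length(intersect(ka, kb)) > 0
}

# Positions (1-based) of every k-mer of a sequence, capped per k-mer.
kmer_map <- function(s, k = 12, cap = 4L) {
  n <- nchar(s)
  if (n < k) return(list())
  km <- substring(s, 1:(n - k + 1), k:n)
  mp <- split(seq_len(n - k + 1L), km)
  lapply(mp, function(p) head(p, cap))
}

# Ungapped identity of two sequences along diagonal d (posA = posB + d):
# returns c(matches, overlap). Overlap below 1 yields c(0, 0).
diagonal_identity <- function(a, b, d) {
  la <- nchar(a); lb <- nchar(b)
  a0 <- max(1L, 1L + d); a1 <- min(la, lb + d)
  if (a1 < a0) return(c(0, 0))
  sa <- substr(a, a0, a1)
  sb <- substr(b, a0 - d, a1 - d)
  ov <- a1 - a0 + 1L
  c(ov - hamming(sa, sb), ov)
}

# Fast 80/80-style pair decision with a DP fallback. Shared-k-mer diagonals
# give an ungapped identity estimate: a pair passing the thresholds on a
# diagonal is accepted outright; a pair far below them is rejected; only the
# ambiguous band pays for a full local alignment.
pair_similarity_8080 <- function(a, b, map_a, map_b, min_identity = 0.80,
                                 min_coverage = 0.80, reject_below = 0.60) {
  common <- intersect(names(map_a), names(map_b))
  if (!length(common)) return(FALSE)
  diags <- integer(0)
  for (kk in common)
    diags <- c(diags, as.vector(outer(map_a[[kk]], map_b[[kk]], "-")))
  bucket <- round(diags / 10)
  top <- names(sort(table(bucket), decreasing = TRUE))
  shorter <- min(nchar(a), nchar(b))
  best_id <- 0
  for (bk in head(top, 3)) {
    d <- as.integer(round(stats::median(diags[bucket == as.numeric(bk)])))
    di <- diagonal_identity(a, b, d)
    if (di[2] < 1) next
    idf <- di[1] / di[2]
    if (idf >= min_identity && di[2] >= min_coverage * shorter) return(TRUE)
    if (di[2] >= min_coverage * shorter) best_id <- max(best_id, idf)
  }
  if (best_id > 0 && best_id < reject_below) return(FALSE)
  aln <- align_nt(a, b, type = "local")
  aln$identity >= min_identity && aln$coverage_shorter >= min_coverage
}
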