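# Expression profiling of retroelements: read QC, a seed-and-extend mapper
# against element consensuses, RPKM computation with expression bins, and
# sample-level PCA of the expression matrix.

#' Quality-filter reads
#'
#' Removes reads in which more than one third of bases are ambiguous
#' (strictly greater: a read at exactly 1/3 is retained) and reads shorter
#' than `min_len`.
#'
#' @param reads `DNAStringSet` or FASTQ path.
#' @param min_len minimum read length.
#' @return The retained `DNAStringSet`.
#' @export
qc_filter_reads <- function(reads, min_len = 30) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  w <- Biostrings::width(reads)
  acgt <- Biostrings::letterFrequency(reads, DNA_BASES)
  ambig <- w - rowSums(acgt)
  reads[w >= min_len & ambig / w <= 1 / 3]
}

#' Map reads to element consensuses (seed-and-extend)
#'
#' Exact seeds of `seed_len` nt at three positions along the read locate
#' candidate placements on each consensus (both strands); each candidate is
#' scored by ungapped full-read mismatch count, and the read is assigned to
#' its best-matching element when that count is at most `max_mismatch`.
#' Reads tied between elements are split fractionally among the tied best
#' hits (default) or assigned to one seeded-random winner.
#'
#' @param reads `DNAStringSet` or FASTQ path.
#' @param consensuses named `DNAStringSet` of element consensuses.
#' @param max_mismatch maximum mismatches for an assignment.
#' @param seed_len exact seed length in nt.
#' @param policy `fractional` or `best_random` multi-mapping policy.
#' @param seed RNG seed (required for `best_random`).
#' @param seed_offsets explicit seed start offsets within the read (0-based);
#'   default three spread positions. Denser offsets reduce the seeding bias
#'   against high-mismatch reads (used by divergence scanning).
#' @return list with `counts` (named per-element totals of assignment
#'   weights), `mapped_total`, `unmapped`, and `assignments` (data.frame:
#'   `read_id`, `element`, `pos` 0-based, `strand`, `mismatches`, `weight`).
#' @export
map_reads <- function(reads, consensuses, max_mismatch = 3, seed_len = 12,
                      policy = c("fractional", "best_random"), seed = NULL,
                      seed_offsets = NULL) {
  policy <- match.arg(policy)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  consensuses <- as_dna_set(consensuses)
  if (length(consensuses) == 0) stop_config("no consensuses to map against")
  n <- length(reads)
  counts <- setNames(numeric(length(consensuses)), names(consensuses))
  empty <- data.frame(read_id = character(), element = character(),
                      pos = integer(), strand = character(),
                      mismatches = integer(), aln_len = integer(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (n == 0)
    return(list(counts = counts, mapped_total = 0L, unmapped = 0L,
                assignments = empty))
  rl <- Biostrings::width(reads)
  fwd <- as.character(reads)
  rev <- as.character(Biostrings::reverseComplement(reads))
  ctxt <- as.character(consensuses)
  clen <- nchar(ctxt)
  # hashed k-mer index of the consensuses: k-mer -> (consensus, position)
  idx_ci <- rep.int(seq_along(ctxt), pmax(clen - seed_len + 1L, 0L))
  idx_pos <- unlist(lapply(clen, function(L)
    if (L >= seed_len) seq_len(L - seed_len + 1L) else integer(0)))
  idx_kmer <- unlist(lapply(seq_along(ctxt), function(ci) {
    L <- clen[ci]
    if (L < seed_len) return(character(0))
    substring(ctxt[ci], 1:(L - seed_len + 1L), seed_len:L)
  }))
  kmer_index <- split(seq_along(idx_kmer), idx_kmer)
  c_ri <- list(); c_ci <- list(); c_sd <- list(); c_pos <- list()
  for (sdi in 1:2) {
    rtxt <- if (sdi == 1L) fwd else rev
    offs <- if (is.null(seed_offsets))
      unique(pmax(0L, c(0L, (min(rl) - seed_len) %/% 2L,
                        min(rl) - seed_len))) else seed_offsets
    for (off in offs) {
      ok <- which(rl >= off + seed_len)
      if (!length(ok)) next
      seeds <- substr(rtxt[ok], off + 1L, off + seed_len)
      loc <- kmer_index[seeds]
      nh <- lengths(loc)
      hit <- nh > 0L
      if (!any(hit)) next
      ii <- unlist(loc[hit], use.names = FALSE)
      ri <- rep(ok[hit], nh[hit])
      ci <- idx_ci[ii]
      pos <- idx_pos[ii] - off          # read start, 1-based
      keep <- pos >= 1L & pos + rl[ri] - 1L <= clen[ci]
      if (!any(keep)) next
      k <- length(c_ri) + 1L
      c_ri[[k]] <- ri[keep]; c_ci[[k]] <- ci[keep]
      c_sd[[k]] <- rep(sdi, sum(keep)); c_pos[[k]] <- pos[keep]
    }
  }
  if (!length(c_ri))
    return(list(counts = counts, mapped_total = 0L, unmapped = n,
                assignments = empty))
  ri <- unlist(c_ri); ci <- unlist(c_ci)
  sd <- unlist(c_sd); pos <- unlist(c_pos)
  key <- ((as.numeric(ri) * (length(consensuses) + 1) + ci) * 3 + sd) *
    (max(clen) + 1) + pos
  dup <- duplicated(key)
  ri <- ri[!dup]; ci <- ci[!dup]; sd <- sd[!dup]; pos <- pos[!dup]
  rstr <- ifelse(sd == 1L, fwd[ri], rev[ri])
  tstr <- substring(ctxt[ci], pos, pos + rl[ri] - 1L)
  prof <- mismatch_profile(rstr, tstr, exclude_ambiguous = TRUE)
  mism <- prof$mismatches
  alen <- prof$compared
  keep <- mism <= max_mismatch
  if (!any(keep))
    return(list(counts = counts, mapped_total = 0L, unmapped = n,
                assignments = empty))
  ri <- ri[keep]; ci <- ci[keep]; sd <- sd[keep]; pos <- pos[keep]
  mism <- mism[keep]; alen <- alen[keep]
  # best placement per read, then one (leftmost) placement per (read, element)
  o <- order(ri, mism, ci, pos)
  ri <- ri[o]; ci <- ci[o]; sd <- sd[o]; pos <- pos[o]
  mism <- mism[o]; alen <- alen[o]
  first <- !duplicated(ri)
  bestm <- mism[first][match(ri, ri[first])]
  at_best <- mism == bestm
  ri <- ri[at_best]; ci <- ci[at_best]; sd <- sd[at_best]
  pos <- pos[at_best]; mism <- mism[at_best]; alen <- alen[at_best]
  pair_dup <- duplicated(as.numeric(ri) * (length(consensuses) + 1) + ci)
  ri <- ri[!pair_dup]; ci <- ci[!pair_dup]; sd <- sd[!pair_dup]
  pos <- pos[!pair_dup]; mism <- mism[!pair_dup]; alen <- alen[!pair_dup]
  nties <- tabulate(ri, nbins = n)
  if (policy == "fractional") {
    weight <- 1 / nties[ri]
  } else {
    if (is.null(seed)) stop_config("policy 'best_random' requires a seed")
    pickord <- with_seed(seed, order(ri, runif(length(ri))))
    win <- logical(length(ri))
    win[pickord[!duplicated(ri[pickord])]] <- TRUE
    ri <- ri[win]; ci <- ci[win]; sd <- sd[win]; pos <- pos[win]
    mism <- mism[win]; alen <- alen[win]
    weight <- rep(1, length(ri))
  }
  assignments <- data.frame(
    read_id = names(reads)[ri],
    element = names(consensuses)[ci],
    pos = as.integer(pos - 1L), strand = c("+", "-")[sd],
    mismatches = mism, aln_len = alen, weight = weight,
    stringsAsFactors = FALSE)
  agg <- tapply(assignments$weight, assignments$element, sum)
  counts[names(agg)] <- as.numeric(agg)
  mapped <- length(unique(ri))
  list(counts = counts, mapped_total = mapped, unmapped = n - mapped,
       assignments = assignments)
}

#' Compute RPKM and expression bins
#'
#' RPKM = count / (element length in kb x mapped reads in millions), per
#' element and sample. Bins follow the printed edges with lower-inclusive
#' half-open intervals: below < 0.5 <= low < 10 <= moderate < 50 <= high.
#'
#' @param counts numeric matrix (elements x samples) or vector (one sample).
#' @param lengths element lengths in nt (recycled along rows).
#' @param library_sizes mapped reads per sample.
#' @param scale_factors optional per-sample scaling applied to the library
#'   sizes (TMM-style normalization hook); default none.
#' @return An `ExpressionMatrix` list: `rpkm`, `counts`, `library_sizes`,
#'   `bins` (same dimensions, labels below/low/moderate/high).
#' @export
compute_rpkm <- function(counts, lengths, library_sizes, scale_factors = NULL) {
  if (is.null(dim(counts))) counts <- cbind(sample1 = counts)
  if (any(lengths <= 0)) stop_config("element lengths must be positive")
  if (any(library_sizes <= 0)) stop_config("library sizes must be positive")
  if (length(library_sizes) != ncol(counts))
    stop_config("one library size per sample is required")
  eff_lib <- library_sizes
  if (!is.null(scale_factors)) eff_lib <- library_sizes * scale_factors
  rpkm <- sweep(counts, 1, lengths / 1000, "/")
  rpkm <- sweep(rpkm, 2, eff_lib / 1e6, "/")
  bins <- rpkm_bin(rpkm)
  structure(list(rpkm = rpkm, counts = counts, library_sizes = library_sizes,
                 bins = bins), class = "ExpressionMatrix")
}

#' Bin RPKM values at the printed edges
#'
#' @param x numeric RPKM values (any shape).
#' @return character labels `below` (< 0.5), `low` (0.5-10), `moderate`
#'   (10-50), `high` (>= 50), preserving dimensions.
#' @export
rpkm_bin <- function(x) {
  lab <- c("below", "low", "moderate", "high")
  out <- lab[findInterval(x, c(0.5, 10, 50)) + 1L]
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Principal component analysis of stage expression profiles
#'
#' Samples are observations; RPKM values are log2(x + 1)-transformed and
#' centered (not scaled) before `prcomp`.
#'
#' @param x an `ExpressionMatrix` or an elements x samples RPKM matrix with
#'   at least 3 samples.
#' @param log_transform apply log2(x + 1) first.
#' @return list with `scores` (samples x components), `var_explained`
#'   (fractions summing to 1) and `rotation`.
#' @export
stage_pca <- function(x, log_transform = TRUE) {
  rpkm <- if (is(x, "ExpressionMatrix") || (is.list(x) && !is.null(x$rpkm)))
    x$rpkm else x
  if (ncol(rpkm) < 3) stop_config("PCA needs at least 3 samples")
  m <- t(if (log_transform) log2(rpkm + 1) else rpkm)
  if (all(abs(sweep(m, 2, colMeans(m))) < 1e-12)) {
    warning("constant expression matrix; PCA is degenerate")
    return(list(scores = matrix(0, nrow(m), nrow(m),
                                dimnames = list(rownames(m), NULL)),
                var_explained = rep(0, nrow(m)), rotation = NULL))
  }
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  list(scores = p$x, var_explained = p$sdev^2 / sum(p$sdev^2),
       rotation = p$rotation)
}
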