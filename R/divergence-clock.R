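# Divergence landscape and burst dating: read-versus-consensus divergence
# scans, abundance normalization of alignment counts, per-clade divergence
# histograms, and Jukes-Cantor dating of proliferation bursts.

#' Scan read-versus-consensus divergence
#'
#' Each (QC-filtered) read is placed on the consensus by exact seeds and
#' scored by ungapped mismatch fraction; only alignments strictly longer than
#' `min_aln_len` nt are reported. Ambiguous bases are excluded from both the
#' numerator and the denominator. Reads are used directly (rather than
#' assembled transcripts) to avoid artifacts of retroelement assembly.
#'
#' @param reads `DNAStringSet` or FASTQ path.
#' @param consensus consensus sequence (string or `DNAString`).
#' @param min_aln_len alignments of at most this length are discarded
#'   (strictly-longer rule; default 70 nt).
#' @param seed_len exact seed length used to place reads.
#' @param max_divergence placements above this mismatch fraction are treated
#'   as unaligned.
#' @return data.frame with `read_id`, `aln_len`, `mismatches`, `divergence`.
#' @export
scan_read_divergence <- function(reads, consensus, min_aln_len = 70,
                                 seed_len = 12, max_divergence = 0.35) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  cons <- toupper(as.character(consensus))
  ctarget <- Biostrings::DNAStringSet(c(cons = cons))
  maxmm <- ceiling(max_divergence *
                     max(Biostrings::width(reads), min_aln_len + 1))
  rlmin <- min(Biostrings::width(reads))
  offs <- unique(pmax(0L, seq(0L, rlmin - seed_len, by = max(seed_len %/% 2, 1))))
  m <- map_reads(reads, ctarget, max_mismatch = maxmm, seed_len = seed_len,
                 seed_offsets = offs)
  a <- m$assignments
  if (!nrow(a))
    return(data.frame(read_id = character(), aln_len = integer(),
                      mismatches = integer(), divergence = numeric(),
                      stringsAsFactors = FALSE))
  rl <- setNames(Biostrings::width(reads), names(reads))
  w <- rl[a$read_id]
  rtxt <- setNames(as.character(reads), names(reads))
  rrc <- setNames(as.character(Biostrings::reverseComplement(reads)),
                  names(reads))
  rstr <- ifelse(a$strand == "+", rtxt[a$read_id], rrc[a$read_id])
  tstr <- substring(cons, a$pos + 1L, a$pos + w)
  prof <- mismatch_profile(rstr, tstr, exclude_ambiguous = TRUE)
  out <- data.frame(read_id = a$read_id, aln_len = prof$compared,
                    mismatches = prof$mismatches,
                    divergence = ifelse(prof$compared > 0,
                                        prof$mismatches / prof$compared, NA),
                    stringsAsFactors = FALSE)
  out <- out[out$aln_len > min_aln_len & !is.na(out$divergence) &
               out$divergence <= max_divergence, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Abundance of a retroelement from observed read alignments
#'
#' Normalizes the observed number of qualifying pairwise alignments by the
#' sampling probability of observing one: `A = o * T / (N * (L + l - 2m))`,
#' where `T` is the transcriptome size, `l` the read length, `N` the total
#' read count, `L` the element length and `m` the minimal alignment length.
#' `L + l - 2m` counts the read placements that overlap the element by more
#' than `m` nt, so `A` estimates the effective copy abundance; `A = 0` iff
#' `o = 0`.
#'
#' @param o observed number of qualifying pairwise alignments.
#' @param T_size transcriptome size in nt.
#' @param l read length in nt (75 by convention).
#' @param N total number of sequencing reads.
#' @param L element (consensus) length in nt.
#' @param m minimal alignment length in nt (70 by convention).
#' @return abundance `A` (dimensionless effective copy count).
#' @export
estimate_abundance <- function(o, T_size, l = 75, N, L, m = 70) {
  if (m > l) stop_config("minimal alignment length m must not exceed l")
  if (any(c(T_size, l, N, L, m) <= 0)) stop_config("all parameters must be positive")
  if (o < 0) stop_config("o must be nonnegative")
  denom <- N * (L + l - 2 * m)
  if (denom <= 0) stop_config("degenerate geometry: L + l - 2m must be positive")
  o * T_size / denom
}

#' Per-clade divergence profile with burst dating
#'
#' Builds an abundance-weighted histogram of read divergences per clade
#' (1%-wide bins by default); the peak is the bin with maximal abundance
#' (ties resolve to the lowest-divergence bin, with a message), and the
#' burst age is the Jukes-Cantor date of the peak bin center.
#'
#' @param scans data.frame from [scan_read_divergence()] (possibly several
#'   clades row-bound together).
#' @param clades character vector assigning each scan row to a clade.
#' @param bin_width histogram bin width (fraction, default 0.01).
#' @param abundance_params list with `T_size`, `l`, `N`, `m` and per-clade
#'   `L` (named vector), used to convert bin counts to abundances; when
#'   `NULL` raw counts are used as weights.
#' @param rate substitution rate for dating (substitutions/site/year).
#' @param weights optional per-scan weights (e.g. fractional multi-mapping
#'   weights); default 1 per scan.
#' @return named list of `DivergenceProfile`s: `clade`, `breaks`, `mid`,
#'   `abundance`, `peak_divergence`, `burst_age`.
#' @export
divergence_profile <- function(scans, clades, bin_width = 0.01,
                               abundance_params = NULL, rate = 1.66e-8,
                               weights = NULL) {
  if (!nrow(scans)) stop_config("no divergence scans supplied")
  stopifnot(length(clades) == nrow(scans))
  if (is.null(weights)) weights <- rep(1, nrow(scans))
  out <- list()
  for (cl in unique(clades)) {
    d <- scans$divergence[clades == cl]
    w <- weights[clades == cl]
    if (!length(d)) {
      warning("clade ", cl, " has no scans; omitted")
      next
    }
    # bins centered on multiples of bin_width: [c - bw/2, c + bw/2)
    idx <- as.integer(round(d / bin_width)) + 1L
    nb <- max(idx)
    breaks <- seq(-bin_width / 2, (nb - 0.5) * bin_width, by = bin_width)
    cnt <- as.numeric(tapply(w, factor(idx, levels = seq_len(nb)), sum,
                             default = 0))
    ab <- cnt
    if (!is.null(abundance_params)) {
      p <- abundance_params
      ab <- vapply(cnt, function(o)
        estimate_abundance(o, T_size = p$T_size, l = p$l, N = p$N,
                           L = p$L[[cl]], m = p$m), 0)
    }
    peak_i <- which(ab == max(ab))
    if (length(peak_i) > 1)
      message("divergence peak tie in clade ", cl,
              "; keeping the lowest-divergence bin")
    peak_i <- peak_i[1]
    mid <- (seq_len(nb) - 1L) * bin_width
    jc <- jc_date(mid[peak_i], rate)
    out[[cl]] <- structure(list(
      clade = cl, breaks = breaks, mid = mid, abundance = ab,
      peak_divergence = mid[peak_i], burst_age = jc$age_years),
      class = "DivergenceProfile")
  }
  out
}

#' Jukes-Cantor dating of a divergence level
#'
#' Corrects an observed divergence fraction `P` for multiple hits under the
#' one-parameter model, `K = -(3/4) ln(1 - 4P/3)`, and converts it to an age.
#' By default divergence is assumed to accumulate along the two lineages
#' separating a copy from the consensus ancestor, `age = K / (2 mu)`; set
#' `single_lineage = TRUE` for `K / mu`.
#'
#' @param P observed divergence fraction, `0 <= P < 0.75`.
#' @param rate substitution rate mu in substitutions/site/year
#'   (default 1.66e-8, a nuclear pseudogene rate for insects).
#' @param single_lineage divide by `mu` instead of `2 mu`.
#' @return list with `K` (substitutions per site) and `age_years`.
#' @export
jc_date <- function(P, rate = 1.66e-8, single_lineage = FALSE) {
  if (any(P < 0 | P >= 0.75))
    stop_config("saturation: Jukes-Cantor correction requires 0 <= P < 0.75")
  if (rate <= 0) stop_config("substitution rate must be positive")
  K <- -0.75 * log(1 - 4 * P / 3)
  list(K = K, age_years = K / (if (single_lineage) rate else 2 * rate))
}

#' @export
print.DivergenceProfile <- function(x, ...) {
  cat(sprintf("<DivergenceProfile %s: peak %.1f%%, burst %.2f Myr, %d bins>\n",
              x$clade, 100 * x$peak_divergence, x$burst_age / 1e6,
              length(x$abundance)))
  invisible(x)
}
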