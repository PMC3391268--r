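# Structural annotation of retroelement sequences: ORFs, protein domains and
# their order, primer binding sites (PBS), polypurine tracts (PPT), CCHC zinc
# fingers, poly-A tails and AT-rich 3' UTRs.
#
# All nucleotide coordinates returned by this module are 0-based half-open
# intervals on the forward strand of the query sequence; amino-acid spans are
# 0-based half-open within the translated ORF peptide.

#' Find open reading frames in all six frames
#'
#' Reports every maximal ATG-to-stop ORF of at least `min_aa` codons
#' (excluding the stop) in the three forward and three reverse frames.
#' Maximal means the ORF starts at the first ATG following the previous
#' in-frame stop, so nested ATGs do not generate separate calls.
#'
#' @param sequence a DNA sequence (string, [Biostrings::DNAString], or
#'   length-1 `DNAStringSet`).
#' @param min_aa minimum peptide length in amino acids (>= 50 by default
#'   contract; smaller values are allowed for diagnostics).
#' @return A data.frame with columns `start`, `end` (0-based half-open
#'   nucleotide span on the forward strand, including the stop codon),
#'   `frame` (+1..+3, -1..-3), `aa_len` and `peptide`.
#' @export
find_orfs <- function(sequence, min_aa = 50) {
  seq <- toupper(as.character(as_dna_set(sequence)[[1]]))
  L <- nchar(seq)
  rc <- revcomp(seq)
  rows <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else rc
    for (f in 1:3) {
      n_cod <- (nchar(s) - f + 1L) %/% 3L
      if (n_cod < min_aa + 1L) next
      codons <- substring(s, f + 3L * (seq_len(n_cod) - 1L), f + 3L * seq_len(n_cod) - 1L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      bounds <- c(0L, which(is_stop))
      for (b in seq_len(length(bounds) - 1L)) {
        lo <- bounds[b] + 1L
        hi <- bounds[b + 1L]            # index of the stop codon
        atg <- which(is_atg[lo:(hi - 1L)])
        if (hi - lo < 1L || !length(atg)) next
        a <- lo + atg[1L] - 1L          # codon index of the start ATG
        aa_len <- hi - a                # codons before the stop
        if (aa_len < min_aa) next
        nt_start <- f + 3L * (a - 1L) - 1L       # 0-based
        nt_end <- f + 3L * hi - 1L               # 0-based half-open, incl stop
        pep <- paste(vapply(codons[a:(hi - 1L)], codon_aa, ""), collapse = "")
        if (strand == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = nt_start, end = nt_end, frame = f, aa_len = aa_len,
            peptide = pep, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            start = L - nt_end, end = L - nt_start, frame = -f, aa_len = aa_len,
            peptide = pep, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      aa_len = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$frame), , drop = FALSE]
}

.CODON_TABLE <- local({
  tab <- Biostrings::GENETIC_CODE
  tab
})

codon_aa <- function(codon) {
  aa <- .CODON_TABLE[[codon]]
  if (is.null(aa)) "X" else aa
}

#' Locate protein domains in an ORF peptide
#'
#' Local alignment of the peptide against each bundled (or supplied) domain
#' reference; the best-scoring non-overlapping placements above threshold are
#' reported in N-to-C order. This replaces profile-HMM scoring with direct
#' alignment to reference peptides.
#'
#' @param orf_peptide peptide string or `AAString`.
#' @param domain_refs named `AAStringSet` of domain references
#'   (default [retro_domain_refs()]).
#' @param min_score minimum local alignment score (BLOSUM62, gap open 10,
#'   extension 0.5).
#' @param min_aa minimum aligned length in amino acids.
#' @return data.frame with `domain`, `start_aa`, `end_aa` (0-based half-open
#'   within the peptide), `score`, `ref_id`.
#' @export
locate_domains <- function(orf_peptide, domain_refs = retro_domain_refs(),
                           min_score = 80, min_aa = 30) {
  pep <- as.character(orf_peptide)
  if (!nzchar(pep)) stop_config("empty peptide")
  hits <- list()
  for (i in seq_along(domain_refs)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pep), domain_refs[[i]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    rng <- aln@pattern@range
    alen <- Biostrings::nchar(aln)
    if (Biostrings::score(aln) >= min_score && alen >= min_aa) {
      hits[[length(hits) + 1L]] <- data.frame(
        domain = names(domain_refs)[i],
        start_aa = BiocGenerics::start(rng) - 1L,
        end_aa = BiocGenerics::end(rng),
        score = Biostrings::score(aln),
        ref_id = names(domain_refs)[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(domain = character(), start_aa = integer(),
                      end_aa = integer(), score = numeric(),
                      ref_id = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, hits)
  df <- df[order(-df$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) for (j in (i + 1L):nrow(df)) {
      if (keep[j] && df$start_aa[j] < df$end_aa[i] && df$end_aa[j] > df$start_aa[i])
        keep[j] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start_aa), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Resolve (sequence, ltr spans) from a template, a full-length model, or an
# explicit list(sequence=, ltr5_span=, ltr3_span=).
.element_parts <- function(element) {
  if (is.character(element) && length(element) == 1 && !file.exists(element))
    return(list(seq = toupper(element), ltr5 = NULL, ltr3 = NULL))
  if (is.list(element)) {
    seq <- toupper(as.character(element$sequence))
    ltr5 <- element$ltr5_span
    ltr3 <- element$ltr3_span
    if (is.null(ltr5) && !is.null(element$features)) {
      f <- element$features
      r5 <- f[f$kind == "LTR5", , drop = FALSE]
      r3 <- f[f$kind == "LTR3", , drop = FALSE]
      if (nrow(r5)) ltr5 <- c(r5$start[1], r5$end[1])
      if (nrow(r3)) ltr3 <- c(r3$start[1], r3$end[1])
    }
    return(list(seq = seq, ltr5 = ltr5, ltr3 = ltr3))
  }
  list(seq = toupper(as.character(element)), ltr5 = NULL, ltr3 = NULL)
}

#' Detect the primer binding site (PBS)
#'
#' Searches the window immediately downstream of the 5' LTR for the best
#' reverse-complement match to the 3'-terminal 18 nt of any tRNA in the set.
#' A call requires a match of at least `min_match` nt with at most
#' `max_mismatch` mismatches. Ties are broken by longer match, then fewer
#' mismatches, then lexicographic tRNA id (logged via `message`).
#'
#' @param element a template/model carrying a 5' LTR span, or a list with
#'   `sequence` and `ltr5_span`.
#' @param trna_set `DNAStringSet` of tRNAs (default the bundled set).
#' @param window search window in nt downstream of the 5' LTR.
#' @param min_match,max_mismatch match acceptance rule.
#' @return A list of class `PbsCall` with `trna_id`, `start`, `end`
#'   (0-based half-open element coordinates), `match_len`, `mismatches`;
#'   or `NULL` when no qualifying match exists.
#' @export
detect_pbs <- function(element, trna_set = retro_trna_set(), window = 30,
                       min_match = 12, max_mismatch = 1) {
  parts <- .element_parts(element)
  if (is.null(parts$ltr5))
    stop_config("element has no 5' LTR annotation; cannot anchor PBS search")
  seq <- parts$seq
  from0 <- parts$ltr5[2]
  region <- substr(seq, from0 + 1, min(nchar(seq), from0 + window))
  if (nchar(region) < min_match) return(NULL)
  best <- NULL
  ids <- sort(names(trna_set))
  for (id in ids) {
    t <- toupper(as.character(trna_set[[id]]))
    probe <- revcomp(substr(t, nchar(t) - 17, nchar(t)))
    for (s in 0:(nchar(region) - min_match)) {
      kmax <- min(18, nchar(region) - s)
      if (kmax < min_match) next
      sub <- substr(region, s + 1, s + kmax)
      mm_prefix <- cumsum(strsplit(sub, "")[[1]] != strsplit(substr(probe, 1, kmax), "")[[1]])
      for (k in kmax:min_match) {
        mm <- mm_prefix[k]
        if (mm <= max_mismatch) {
          cand <- list(trna_id = id, start = from0 + s, end = from0 + s + k,
                       match_len = k, mismatches = as.integer(mm))
          if (is.null(best) ||
              cand$match_len > best$match_len ||
              (cand$match_len == best$match_len && cand$mismatches < best$mismatches)) {
            if (!is.null(best) && cand$match_len == best$match_len &&
                cand$mismatches == best$mismatches && cand$trna_id != best$trna_id)
              message("PBS tie between ", best$trna_id, " and ", cand$trna_id,
                      "; keeping ", best$trna_id)
            else best <- cand
          } else if (cand$match_len == best$match_len &&
                     cand$mismatches == best$mismatches && cand$trna_id != best$trna_id) {
            message("PBS tie between ", best$trna_id, " and ", cand$trna_id,
                    "; keeping ", best$trna_id)
          }
          break
        }
      }
    }
  }
  if (!is.null(best)) class(best) <- "PbsCall"
  best
}

#' Detect the polypurine tract (PPT)
#'
#' Finds the longest run of at least `min_len` nt with purine fraction
#' >= `min_purine` inside the window immediately upstream of the 3' LTR.
#' Absence is a valid, reportable outcome (`NULL`).
#'
#' @param element a template/model carrying a 3' LTR span, or a list with
#'   `sequence` and `ltr3_span`.
#' @param window search window in nt upstream of the 3' LTR.
#' @param min_len,min_purine acceptance rule.
#' @return list with `start`, `end` (0-based half-open element coordinates)
#'   and `purine_fraction`, or `NULL`.
#' @export
detect_ppt <- function(element, window = 30, min_len = 10, min_purine = 0.8) {
  parts <- .element_parts(element)
  if (is.null(parts$ltr3))
    stop_config("element has no 3' LTR annotation; cannot anchor PPT search")
  seq <- parts$seq
  to0 <- parts$ltr3[1]
  w0 <- max(0, to0 - window)
  region <- substr(seq, w0 + 1, to0)
  n <- nchar(region)
  if (n < min_len) return(NULL)
  v <- strsplit(region, "")[[1]] %in% c("A", "G")
  cs <- c(0L, cumsum(v))
  best <- NULL
  for (len in n:min_len) {
    for (s in 0:(n - len)) {
      if ((cs[s + len + 1] - cs[s + 1]) / len >= min_purine) {
        best <- list(start = w0 + s, end = w0 + s + len,
                     purine_fraction = (cs[s + len + 1] - cs[s + 1]) / len)
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

#' Scan a peptide for CCHC zinc-finger motifs
#'
#' Matches the pattern C-X(2)-C-X(3,4)-H-X(3,6)-C. Overlapping matches are
#' allowed but each start position is reported once. The spacer ranges jointly
#' accommodate the CCHC variants observed in retroelement gag/ORF1 proteins.
#'
#' @param peptide peptide string or `AAString`.
#' @return data.frame with `start_aa` (1-based start position) and `match`.
#' @export
scan_cchc <- function(peptide) {
  pep <- as.character(peptide)
  if (!nzchar(pep)) stop_config("empty peptide")
  m <- gregexpr("(?=(C.{2}C.{3,4}H.{3,6}C))", pep, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start_aa = integer(), match = character(),
                      stringsAsFactors = FALSE))
  cap_start <- attr(m, "capture.start")[, 1]
  cap_len <- attr(m, "capture.length")[, 1]
  data.frame(start_aa = as.integer(cap_start),
             match = substring(pep, cap_start, cap_start + cap_len - 1),
             stringsAsFactors = FALSE)
}

#' Detect 3'-end features: poly-A tail and AT-rich UTR
#'
#' The poly-A tail is the longest terminal suffix with at most one non-A per
#' ten bases, required to be at least `min_polya` nt. The AT-rich flag is set
#' when the region between the last ORF and the poly-A start has AT fraction
#' >= `min_at`.
#'
#' @param element sequence (string/`DNAString`) or a list with `sequence`.
#' @param min_polya minimum tail length.
#' @param min_at AT-fraction threshold for the 3' UTR.
#' @param min_orf_aa ORF size used when locating the last ORF.
#' @return list with `polyA` (0-based half-open span or `NULL`),
#'   `at_rich_utr` (logical, `NA` when no ORF anchors the UTR) and
#'   `utr_span`.
#' @export
detect_3prime_features <- function(element, min_polya = 10, min_at = 0.6,
                                   min_orf_aa = 100) {
  parts <- .element_parts(element)
  seq <- parts$seq
  L <- nchar(seq)
  v <- rev(strsplit(seq, "")[[1]])
  best_len <- 0L
  nonA <- 0L
  for (i in seq_along(v)) {
    if (v[i] != "A") nonA <- nonA + 1L
    # the tail must begin on an A: a non-A at the inner edge never extends it
    if (v[i] == "A" && nonA <= i / 10) best_len <- i
    if (nonA > i / 10 && i - best_len > 10) break
  }
  polyA <- if (best_len >= min_polya) list(start = L - best_len, end = L) else NULL
  utr_end0 <- if (is.null(polyA)) L else polyA$start
  orfs <- find_orfs(seq, min_aa = min_orf_aa)
  orfs <- orfs[orfs$frame > 0 & orfs$end <= utr_end0, , drop = FALSE]
  at_rich <- NA
  utr_span <- NULL
  if (nrow(orfs)) {
    utr_start0 <- max(orfs$end)
    if (utr_end0 - utr_start0 >= 5) {
      utr_span <- c(utr_start0, utr_end0)
      at_rich <- frac_at(substr(seq, utr_start0 + 1, utr_end0)) >= min_at
    }
  }
  list(polyA = polyA, at_rich_utr = at_rich, utr_span = utr_span)
}
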