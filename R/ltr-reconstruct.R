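# Full-length LTR retroelement reconstruction. Near-identical terminal
# repeats make short-read assemblers collapse the two LTR copies or stitch
# the element in the wrong orientation; this module recovers full-length
# models from (a) terminal direct repeats found by self-alignment, and
# (b) separate LTR contigs that align to both termini of a domain-bearing
# internal contig, corroborated by paired-end junction support, followed by
# domain-order orientation correction and structural validation.

#' Detect collapsed or fragmented LTR structures
#'
#' Two signatures are searched: `self_repeat` - the two terminal windows of a
#' sequence align to each other at >= `ltr_min_identity` over >=
#' `min_ltr_len` nt (a full-length or misoriented element carrying both
#' LTRs); and `ltr_pair` - a short contig aligns to both termini of a
#' domain-bearing contig (a collapsed assembly that separated the LTR from
#' the internal region).
#'
#' @param seqs `DNAStringSet` (consensuses and/or contigs), each >= 300 nt to
#'   be considered.
#' @param domain_bearing optional character vector of sequence ids known to
#'   carry protein domains (used for the `ltr_pair` signature); when `NULL`
#'   it is computed from the sequences.
#' @param ltr_min_identity minimum identity between the two LTR copies.
#' @param min_ltr_len minimum LTR length in nt.
#' @param terminal_window how far from each terminus to search.
#' @return list of `LTRCandidate`s: `type` (`self_repeat`/`ltr_pair`),
#'   `internal_id`, `ltr_id` (for `ltr_pair`), `ltr_len`, `identity`,
#'   `evidence`.
#' @export
detect_collapsed_ltr <- function(seqs, domain_bearing = NULL,
                                 ltr_min_identity = 0.85, min_ltr_len = 80,
                                 terminal_window = 600) {
  seqs <- as_dna_set(seqs)
  out <- list()
  txt <- as.character(seqs)
  lens <- Biostrings::width(seqs)
  for (i in seq_along(seqs)) {
    if (lens[i] < 300) next
    L <- lens[i]
    w <- min(terminal_window, L %/% 2)
    head_w <- substr(txt[i], 1, w)
    tail_w <- substr(txt[i], L - w + 1, L)
    a <- align_nt(head_w, tail_w, type = "local")
    if (a$aligned_len >= min_ltr_len && a$identity >= ltr_min_identity) {
      delta <- (L - w + a$s_start) - a$p_start   # offset of the repeat
      K <- L - delta
      if (K >= min_ltr_len && K <= L %/% 2) {
        id5 <- substr(txt[i], 1, K)
        id3 <- substr(txt[i], delta + 1, L)
        ident <- ltr_pair_identity(id5, id3) / 100
        if (ident >= ltr_min_identity) {
          out[[length(out) + 1L]] <- structure(list(
            type = "self_repeat", internal_id = names(seqs)[i], ltr_id = NA,
            ltr_len = as.integer(K), identity = ident,
            evidence = "self_repeat"), class = "LTRCandidate")
          next
        }
      }
    }
  }
  # ltr_pair signature: short contig matching both termini of an internal
  if (is.null(domain_bearing)) {
    domain_bearing <- names(seqs)[vapply(seq_along(seqs), function(i) {
      orfs <- find_orfs(txt[i], min_aa = 150)
      nrow(orfs) > 0 && any(vapply(orfs$peptide, function(p)
        nrow(locate_domains(p)) > 0, TRUE))
    }, TRUE)]
  }
  found_self <- vapply(out, function(x) x$internal_id, "")
  for (di in which(names(seqs) %in% domain_bearing)) {
    if (names(seqs)[di] %in% found_self) next
    L <- lens[di]
    w <- min(150L, L %/% 4)
    head_w <- substr(txt[di], 1, w)
    tail_w <- substr(txt[di], L - w + 1, L)
    for (si in seq_along(seqs)) {
      if (si == di) next
      if (lens[si] < min_ltr_len || lens[si] > 2000 ||
          names(seqs)[si] %in% domain_bearing) next
      a5 <- align_nt(head_w, txt[si], type = "local")
      a3 <- align_nt(tail_w, txt[si], type = "local")
      if (a5$aligned_len >= 25 && a5$identity >= ltr_min_identity &&
          a3$aligned_len >= 25 && a3$identity >= ltr_min_identity) {
        out[[length(out) + 1L]] <- structure(list(
          type = "ltr_pair", internal_id = names(seqs)[di],
          ltr_id = names(seqs)[si], ltr_len = lens[si],
          identity = min(a5$identity, a3$identity),
          evidence = "terminal_alignment"), class = "LTRCandidate")
      }
    }
  }
  out
}

#' Scaffold an LTR candidate using paired-end junction support
#'
#' For an `ltr_pair` candidate, counts read pairs with one mate in the LTR
#' contig and the other within insert range of each internal terminus. When
#' both junctions reach `min_junction_pairs`, one LTR copy is placed at each
#' end of the internal contig (terminal overlaps between the contigs are
#' merged). For a `self_repeat` candidate the sequence is already full
#' length; junction support is still counted as corroborating evidence.
#'
#' @param candidate an `LTRCandidate`.
#' @param seqs the `DNAStringSet` the candidate indexes into.
#' @param read1,read2 paired reads (`DNAStringSet`).
#' @param insert_mean,insert_sd insert size model; mates within
#'   `insert_mean + 3 * insert_sd` of a terminus support its junction.
#' @param min_junction_pairs required support per junction.
#' @param seed_len mapper seed length.
#' @return list with `sequence`, `ltr5_span`, `ltr3_span` (0-based
#'   half-open), `junction_support` (left/right counts) and `candidate`; or
#'   `NULL` (with the reason reported via `message`) when support is
#'   insufficient.
#' @export
scaffold_with_pairs <- function(candidate, seqs, read1, read2,
                                insert_mean = 250, insert_sd = 25,
                                min_junction_pairs = 3, seed_len = 12) {
  seqs <- as_dna_set(seqs)
  reach <- insert_mean + 3 * insert_sd
  if (candidate$type == "self_repeat") {
    s <- as.character(seqs[[candidate$internal_id]])
    K <- candidate$ltr_len
    L <- nchar(s)
    sup <- .junction_support(s, c(K, L - K), read1, read2, reach, seed_len)
    return(list(sequence = s, ltr5_span = c(0L, K),
                ltr3_span = c(L - K, L), junction_support = sup,
                candidate = candidate))
  }
  internal <- as.character(seqs[[candidate$internal_id]])
  ltr <- as.character(seqs[[candidate$ltr_id]])
  targets <- Biostrings::DNAStringSet(c(internal = internal, ltr = ltr))
  m1 <- map_reads(read1, targets, max_mismatch = 12, seed_len = seed_len)
  m2 <- map_reads(read2, targets, max_mismatch = 12, seed_len = seed_len)
  a1 <- m1$assignments; a2 <- m2$assignments
  a1$frag <- sub("/[12]$", "", a1$read_id)
  a2$frag <- sub("/[12]$", "", a2$read_id)
  j <- merge(a1, a2, by = "frag", suffixes = c(".1", ".2"))
  Lint <- nchar(internal)
  left <- 0L; right <- 0L
  for (r in seq_len(nrow(j))) {
    e1 <- j$element.1[r]; e2 <- j$element.2[r]
    if (e1 == e2) next
    ipos <- if (e1 == "internal") j$pos.1[r] else j$pos.2[r]
    if (ipos <= reach) left <- left + 1L
    if (ipos + 75 >= Lint - reach) right <- right + 1L
  }
  sup <- c(left = left, right = right)
  if (any(sup < min_junction_pairs)) {
    message(sprintf("candidate %s rejected: junction support %d/%d below %d",
                    candidate$internal_id, left, right, min_junction_pairs))
    return(invisible(NULL))
  }
  o5 <- .terminal_overlap(ltr, internal, head_of_internal = TRUE)
  o3 <- .terminal_overlap(ltr, internal, head_of_internal = FALSE)
  core <- substr(internal, o5 + 1, nchar(internal) - o3)
  s <- paste0(ltr, core, ltr)
  K <- nchar(ltr)
  list(sequence = s, ltr5_span = c(0L, K),
       ltr3_span = c(nchar(s) - K, nchar(s)), junction_support = sup,
       candidate = candidate)
}

# Count read pairs whose mates straddle a junction position on a full
# sequence (one mate left of it, mate two right of it, within reach).
.junction_support <- function(s, junctions, read1, read2, reach, seed_len) {
  targets <- Biostrings::DNAStringSet(c(elem = s))
  m1 <- map_reads(read1, targets, max_mismatch = 12, seed_len = seed_len)
  m2 <- map_reads(read2, targets, max_mismatch = 12, seed_len = seed_len)
  a1 <- m1$assignments; a2 <- m2$assignments
  if (!nrow(a1) || !nrow(a2)) return(setNames(rep(0L, length(junctions)),
                                              paste0("j", seq_along(junctions))))
  a1$frag <- sub("/[12]$", "", a1$read_id)
  a2$frag <- sub("/[12]$", "", a2$read_id)
  j <- merge(a1[, c("frag", "pos")], a2[, c("frag", "pos")], by = "frag")
  lo <- pmin(j$pos.x, j$pos.y)
  hi <- pmax(j$pos.x, j$pos.y) + 75
  vapply(junctions, function(jp)
    sum(lo < jp & hi > jp & hi - lo <= reach + 150), 0L) |>
    setNames(paste0("j", seq_along(junctions)))
}

# Longest terminal overlap (<= 120 nt, <= 10% mismatches) between an LTR and
# the head or tail of the internal contig.
.terminal_overlap <- function(ltr, internal, head_of_internal = TRUE,
                              max_over = 120L) {
  best <- 0L
  for (k in seq_len(min(max_over, nchar(ltr), nchar(internal)))) {
    a <- if (head_of_internal) substr(internal, 1, k)
         else substr(internal, nchar(internal) - k + 1, nchar(internal))
    b <- if (head_of_internal) substr(ltr, nchar(ltr) - k + 1, nchar(ltr))
         else substr(ltr, 1, k)
    if (hamming(a, b) <= 0.1 * k) best <- k
  }
  best
}

#' Finalize a full-length LTR retroelement model
#'
#' Validates and annotates a scaffold: protein domains orient the internal
#' region (when domain evidence sits on the reverse strand the internal
#' region is reverse-complemented - the orientation correction is an
#' involution), at least one ORF of `min_orf_aa` amino acids is required, the
#' LTR pair identity must reach `ltr_min_identity`, and PBS/PPT calls are
#' attached when present.
#'
#' @param scaffold result of [scaffold_with_pairs()] (or any list with
#'   `sequence`, `ltr5_span`, `ltr3_span`).
#' @param domain_refs domain reference peptides.
#' @param trna_set tRNA set for the PBS search.
#' @param min_orf_aa minimum ORF length (amino acids).
#' @param ltr_min_identity minimum LTR pair identity (percent).
#' @return A `FullLengthLTRModel` list (`element_id`, `sequence`,
#'   `ltr5_span`, `ltr3_span`, `ltr_identity` (percent), `pbs`, `ppt`,
#'   `orfs`, `domain_order`, `oriented`); or `NULL` (reason reported via
#'   `message`) when validation fails.
#' @export
finalize_element <- function(scaffold, domain_refs = retro_domain_refs(),
                             trna_set = retro_trna_set(), min_orf_aa = 200,
                             ltr_min_identity = 85) {
  if (is.null(scaffold)) return(NULL)
  s <- scaffold$sequence
  l5 <- scaffold$ltr5_span
  l3 <- scaffold$ltr3_span
  internal <- substr(s, l5[2] + 1, l3[1])
  orient <- .domain_strand(internal, domain_refs)
  oriented <- FALSE
  if (!is.na(orient) && orient < 0) {
    internal <- revcomp(internal)
    s <- paste0(substr(s, 1, l5[2]), internal,
                substr(s, l3[1] + 1, nchar(s)))
    oriented <- TRUE
  }
  orfs <- find_orfs(s, min_aa = min_orf_aa)
  orfs <- orfs[orfs$frame > 0, , drop = FALSE]
  if (!nrow(orfs)) {
    message("scaffold rejected: no_orf (no ORF of >= ", min_orf_aa, " aa)")
    return(invisible(NULL))
  }
  doms <- list()
  for (oi in seq_len(nrow(orfs))) {
    d <- locate_domains(orfs$peptide[oi], domain_refs)
    if (nrow(d)) {
      d$nt_start <- orfs$start[oi] + 3L * d$start_aa
      doms[[length(doms) + 1L]] <- d
    }
  }
  doms <- if (length(doms)) do.call(rbind, doms) else NULL
  domain_order <- if (!is.null(doms)) doms$domain[order(doms$nt_start)] else character()
  ident <- ltr_pair_identity(substr(s, l5[1] + 1, l5[2]),
                             substr(s, l3[1] + 1, l3[2]))
  if (ident < ltr_min_identity) {
    message(sprintf("scaffold rejected: ltr_identity %d below %s", ident,
                    ltr_min_identity))
    return(invisible(NULL))
  }
  model <- structure(list(
    element_id = if (!is.null(scaffold$candidate))
      scaffold$candidate$internal_id else "element",
    sequence = s, ltr5_span = l5, ltr3_span = l3,
    ltr_identity = ident,
    pbs = NULL, ppt = NULL, orfs = orfs[, c("start", "end", "frame", "aa_len")],
    domain_order = domain_order, oriented = oriented,
    junction_support = scaffold$junction_support), class = "FullLengthLTRModel")
  model$pbs <- detect_pbs(model, trna_set = trna_set)
  model$ppt <- detect_ppt(model)
  model
}

# Net strand of domain evidence in a sequence: +1, -1, or NA when none.
.domain_strand <- function(seq, domain_refs = retro_domain_refs()) {
  orfs <- find_orfs(seq, min_aa = 150)
  if (!nrow(orfs)) return(NA_integer_)
  best <- c(`1` = 0, `-1` = 0)
  for (oi in seq_len(nrow(orfs))) {
    d <- locate_domains(orfs$peptide[oi], domain_refs)
    if (nrow(d)) {
      key <- as.character(sign(orfs$frame[oi]))
      best[key] <- best[key] + sum(d$score)
    }
  }
  if (all(best == 0)) return(NA_integer_)
  if (best["1"] >= best["-1"]) 1L else -1L
}

#' LTR pair identity
#'
#' Global alignment identity of the two LTR copies, as matched columns over
#' aligned columns, rounded to integer percent.
#'
#' @param x a `FullLengthLTRModel`, or the 5' LTR sequence.
#' @param y the 3' LTR sequence when `x` is a sequence.
#' @return integer percent in `[0, 100]`.
#' @export
ltr_pair_identity <- function(x, y = NULL) {
  if (is.list(x) && !is.null(x$ltr5_span)) {
    s <- x$sequence
    y <- substr(s, x$ltr3_span[1] + 1, x$ltr3_span[2])
    x <- substr(s, x$ltr5_span[1] + 1, x$ltr5_span[2])
  }
  if (nchar(x) < 50 || nchar(y) < 50)
    warning("LTR shorter than 50 nt; identity estimate is unstable")
  a <- align_nt(x, y, type = "global")
  as.integer(round(100 * a$identity))
}

#' @export
print.FullLengthLTRModel <- function(x, ...) {
  cat(sprintf(
    "<FullLengthLTRModel %s: %d nt, LTRs %d nt at %d%%, domains %s, PBS %s, PPT %s>\n",
    x$element_id, nchar(x$sequence), x$ltr5_span[2] - x$ltr5_span[1],
    x$ltr_identity,
    if (length(x$domain_order)) paste(x$domain_order, collapse = "-") else "none",
    if (is.null(x$pbs)) "absent" else x$pbs$trna_id,
    if (is.null(x$ppt)) "absent" else "present"))
  invisible(x)
}
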