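# Retroelement catalogue construction: contig redundancy removal, translated
# homology search against the retrotransposon protein panel, the stringent
# candidate filters, 80/80 single-linkage clustering into elements, and
# majority-vote consensus building.

#' Remove redundant contigs from pooled assemblies
#'
#' Greedy longest-first clustering: a contig contained in a longer survivor at
#' >= `min_identity` identity over >= `min_coverage` of its own length is
#' dropped, so the longest possible representative of every region is kept.
#' Thresholds emulate common cd-hit-style redundancy removal defaults.
#'
#' @param contig_sets a `DNAStringSet`, FASTA path, or list of either
#'   (multiple k-mer assemblies are pooled before deduplication).
#' @param min_identity,min_coverage containment rule.
#' @return A `DNAStringSet` of surviving contigs.
#' @export
dedupe_contigs <- function(contig_sets, min_identity = 0.95,
                           min_coverage = 0.90) {
  if (!is.list(contig_sets) || is(contig_sets, "DNAStringSet"))
    contig_sets <- list(contig_sets)
  pool <- do.call(c, lapply(contig_sets, as_dna_set))
  if (length(pool) == 0) return(Biostrings::DNAStringSet())
  if (is.null(names(pool)) || anyDuplicated(names(pool)))
    names(pool) <- sprintf("contig%05d", seq_along(pool))
  ord <- order(-Biostrings::width(pool), names(pool))
  pool <- pool[ord]
  txt <- as.character(pool)
  keep <- logical(length(pool))
  for (i in seq_along(pool)) {
    contained <- FALSE
    for (j in which(keep)) {
      if (!share_kmer(txt[i], txt[j], 16)) next
      a <- align_nt(txt[i], txt[j], type = "local")
      if (a$identity >= min_identity &&
          (a$p_end - a$p_start + 1) / nchar(txt[i]) >= min_coverage) {
        contained <- TRUE
        break
      }
    }
    keep[i] <- !contained
  }
  pool[keep]
}

#' Translated homology search against a protein panel
#'
#' Six-frame translation of each contig; every stop-free peptide segment of at
#' least `min_seg_aa` residues is locally aligned (BLOSUM62, affine gaps)
#' against every panel entry. Hits below the reporting stringency are
#' suppressed; homology interrupted by stop codons surfaces as separate hits.
#'
#' @param contigs `DNAStringSet` or FASTA path.
#' @param panel `AAStringSet` with a `class` metadata column (default the
#'   bundled synthetic panel).
#' @param min_score,min_aa reporting stringency (local alignment score and
#'   aligned amino-acid length).
#' @param min_seg_aa shortest stop-free segment worth aligning.
#' @return data.frame of homology hits: `contig_id`, `frame`,
#'   `panel_protein_id`, `superfamily_class`, `aligned_aa_len`, `identity`,
#'   `score`, `contig_start`, `contig_end` (0-based half-open nt span on the
#'   forward strand).
#' @export
translated_search <- function(contigs, panel = retro_protein_panel(),
                              min_score = 60, min_aa = 30, min_seg_aa = 30) {
  contigs <- as_dna_set(contigs)
  if (length(panel) == 0) stop_config("empty protein panel")
  classes <- S4Vectors::mcols(panel)$class
  if (is.null(classes)) stop_config("panel must carry a 'class' metadata column")
  aa_k <- 5L
  panel_kmers <- lapply(seq_along(panel), function(pi) {
    p <- as.character(panel[[pi]])
    unique(substring(p, 1:(nchar(p) - aa_k + 1), aa_k:nchar(p)))
  })
  hits <- list()
  for (ci in seq_along(contigs)) {
    id <- names(contigs)[ci]
    seq <- toupper(as.character(contigs[[ci]]))
    if (grepl("[^ACGTN]", seq)) stop_config("contig ", id,
                                            " contains non-IUPAC characters")
    if (nchar(seq) < 3) next
    segs <- .six_frame_segments(seq, min_seg_aa)
    if (!nrow(segs)) next
    seg_kmers <- lapply(segs$peptide, function(p)
      unique(substring(p, 1:(nchar(p) - aa_k + 1), aa_k:nchar(p))))
    for (pi in seq_along(panel)) {
      shared <- vapply(seg_kmers, function(sk)
        sum(sk %in% panel_kmers[[pi]]), 0L)
      idx <- which(shared >= 2L)
      if (!length(idx)) next
      alns <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(segs$peptide[idx]), panel[[pi]],
        type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
      sc <- Biostrings::score(alns)
      for (sii in which(sc >= min_score)) {
        si <- idx[sii]
        aln <- alns[sii]
        alen <- Biostrings::nchar(aln)
        if (alen < min_aa) next
        pr <- aln@pattern@range
        aa0 <- segs$aa_offset[si] + BiocGenerics::start(pr) - 1L  # 0-based in frame peptide
        aa1 <- segs$aa_offset[si] + BiocGenerics::end(pr)
        fr <- segs$frame[si]
        L <- nchar(seq)
        if (fr > 0) {
          nt0 <- (fr - 1L) + 3L * aa0
          nt1 <- (fr - 1L) + 3L * aa1
        } else {
          rc0 <- (-fr - 1L) + 3L * aa0
          rc1 <- (-fr - 1L) + 3L * aa1
          nt0 <- L - rc1
          nt1 <- L - rc0
        }
        hits[[length(hits) + 1L]] <- data.frame(
          contig_id = id, frame = fr,
          panel_protein_id = names(panel)[pi],
          superfamily_class = classes[pi],
          aligned_aa_len = alen,
          identity = Biostrings::nmatch(aln) / alen,
          score = sc[sii],
          contig_start = as.integer(nt0), contig_end = as.integer(nt1),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(contig_id = character(), frame = integer(),
                      panel_protein_id = character(),
                      superfamily_class = character(),
                      aligned_aa_len = integer(), identity = numeric(),
                      score = numeric(), contig_start = integer(),
                      contig_end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$contig_id, -out$score), , drop = FALSE]
}

# Stop-free peptide segments (>= min_seg_aa) of all six frames, with the
# 0-based amino-acid offset of each segment within its frame translation.
.six_frame_segments <- function(seq, min_seg_aa) {
  L <- nchar(seq)
  rc <- revcomp(seq)
  rows <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0) seq else rc
    f <- abs(fr)
    n_cod <- (L - f + 1L) %/% 3L
    if (n_cod < min_seg_aa) next
    sub <- substr(s, f, f + 3L * n_cod - 1L)
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "X"))
    parts <- strsplit(pep, "*", fixed = TRUE)[[1]]
    off <- 0L
    for (p in parts) {
      if (nchar(p) >= min_seg_aa)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = fr, aa_offset = off, peptide = p, stringsAsFactors = FALSE)
      off <- off + nchar(p) + 1L
    }
  }
  if (!length(rows))
    return(data.frame(frame = integer(), aa_offset = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Candidate filter policy
#'
#' Thresholds for [apply_filters()]: minimum transcript length (300 bp),
#' minimum retroelement homology length (200 aa) at `min_identity`, the
#' DNA-transposon screen, and the host-protein screen applied to
#' non-retroelement ORFs of at least `min_nonTE_orf_len` nt. The
#' length-plus-identity stringency stands in for an E-value cutoff.
#'
#' @param min_transcript_len,min_homology_aa,min_identity,min_nonTE_orf_len
#'   thresholds (see description).
#' @param host_decoy_panel `AAStringSet` of host proteins for the non-TE
#'   screen.
#' @param host_min_score local-alignment score above which a non-TE ORF is
#'   deemed to match a host protein.
#' @return list of class `FilterPolicy`.
#' @export
filter_policy <- function(min_transcript_len = 300, min_homology_aa = 200,
                          min_identity = 0.30, min_nonTE_orf_len = 300,
                          host_decoy_panel = retro_host_decoys(),
                          host_min_score = 100) {
  stopifnot(min_transcript_len > 0, min_homology_aa > 0,
            min_identity > 0, min_nonTE_orf_len > 0)
  structure(list(min_transcript_len = min_transcript_len,
                 min_homology_aa = min_homology_aa,
                 min_identity = min_identity,
                 min_nonTE_orf_len = min_nonTE_orf_len,
                 host_decoy_panel = host_decoy_panel,
                 host_min_score = host_min_score),
            class = "FilterPolicy")
}

#' Apply the stringent candidate filters
#'
#' Retains contigs that (1) are at least `min_transcript_len` nt; (2) carry a
#' retroelement homology of at least `min_homology_aa` aligned amino acids at
#' `min_identity` or better; (3) are not better explained as DNA transposons
#' (best hit in the transposase class); and (4) have no non-retroelement ORF
#' of `min_nonTE_orf_len` nt or more matching the host decoy panel. Every
#' rejection is logged with the rule that fired; rules are evaluated
#' independently so the retained set does not depend on rule order.
#'
#' @param contigs `DNAStringSet` or FASTA path.
#' @param hits data.frame from [translated_search()] covering these contigs.
#' @param policy a [filter_policy()].
#' @return list with `retained` (`DNAStringSet`), `rejections` (data.frame
#'   `contig_id`, `rule`, `detail`) and `classes` (named vector: best
#'   retroelement class per retained contig).
#' @export
apply_filters <- function(contigs, hits, policy = filter_policy()) {
  contigs <- as_dna_set(contigs)
  rej <- list()
  note <- function(id, rule, detail = "") rej[[length(rej) + 1L]] <<-
    data.frame(contig_id = id, rule = rule, detail = detail,
               stringsAsFactors = FALSE)
  classes <- character(0)
  keep <- character(0)
  for (ci in seq_along(contigs)) {
    id <- names(contigs)[ci]
    seq <- as.character(contigs[[ci]])
    h <- hits[hits$contig_id == id, , drop = FALSE]
    retro <- h[h$superfamily_class != "DNA_TE", , drop = FALSE]
    tpase <- h[h$superfamily_class == "DNA_TE", , drop = FALSE]
    drop <- FALSE
    if (nchar(seq) < policy$min_transcript_len) {
      note(id, "min_length", sprintf("%d nt < %d", nchar(seq),
                                     policy$min_transcript_len))
      drop <- TRUE
    }
    best_retro <- if (nrow(retro)) retro[which.max(retro$score), , drop = FALSE] else NULL
    # the homology length criterion applies to the whole masked region: hits
    # to the same panel protein in the same frame, interrupted by stop codons
    # or small gaps, are chained and their union length counts
    chains <- merge_hit_chains(retro)
    qualifying <- nrow(retro) > 0 &&
      any(chains$aa_len >= policy$min_homology_aa &
          chains$identity >= policy$min_identity)
    if (is.null(best_retro)) {
      note(id, "no_retro_homology")
      drop <- TRUE
    } else if (!qualifying) {
      note(id, "weak_homology",
           sprintf("best %d aa at %.2f identity", best_retro$aligned_aa_len,
                   best_retro$identity))
      drop <- TRUE
    }
    if (nrow(tpase) && (is.null(best_retro) ||
                        max(tpase$score) > best_retro$score)) {
      note(id, "dna_te", "best homology is a transposase")
      drop <- TRUE
    }
    # host-protein screen on ORFs outside retroelement homology regions
    if (nrow(retro)) {
      orfs <- find_orfs(seq, min_aa = ceiling(policy$min_nonTE_orf_len / 3))
      if (nrow(orfs)) {
        for (oi in seq_len(nrow(orfs))) {
          o <- orfs[oi, ]
          ov <- pmin(retro$contig_end, o$end) - pmax(retro$contig_start, o$start)
          if (any(ov > 0.2 * (o$end - o$start))) next  # inside the TE region
          sc <- vapply(seq_along(policy$host_decoy_panel), function(hi)
            align_aa(o$peptide,
                     as.character(policy$host_decoy_panel[[hi]]))$score, 0)
          if (any(sc >= policy$host_min_score)) {
            note(id, "non_te_homology",
                 sprintf("ORF %d-%d matches host panel", o$start, o$end))
            drop <- TRUE
            break
          }
        }
      }
    }
    if (!drop) {
      keep <- c(keep, id)
      classes[id] <- best_retro$superfamily_class
    }
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(contig_id = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(retained = contigs[keep], rejections = rejections, classes = classes)
}

# Chain co-linear hits to the same panel protein in the same frame (gaps up
# to max_gap nt allowed, spans unioned) and summarize each chain's amino-acid
# length and score-weighted identity.
merge_hit_chains <- function(hits, max_gap = 150) {
  if (!nrow(hits))
    return(data.frame(panel_protein_id = character(), frame = integer(),
                      aa_len = numeric(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (key in unique(paste(hits$panel_protein_id, hits$frame))) {
    h <- hits[paste(hits$panel_protein_id, hits$frame) == key, , drop = FALSE]
    h <- h[order(h$contig_start), , drop = FALSE]
    cs <- h$contig_start[1]; ce <- h$contig_end[1]
    ids <- h$identity[1] * h$aligned_aa_len[1]
    aas <- h$aligned_aa_len[1]; sc <- h$score[1]
    flush_chain <- function() out[[length(out) + 1L]] <<- data.frame(
      panel_protein_id = h$panel_protein_id[1], frame = h$frame[1],
      aa_len = (ce - cs) / 3, identity = ids / aas, score = sc,
      stringsAsFactors = FALSE)
    if (nrow(h) > 1) for (i in 2:nrow(h)) {
      if (h$contig_start[i] <= ce + max_gap) {
        ce <- max(ce, h$contig_end[i])
        ids <- ids + h$identity[i] * h$aligned_aa_len[i]
        aas <- aas + h$aligned_aa_len[i]
        sc <- sc + h$score[i]
      } else {
        flush_chain()
        cs <- h$contig_start[i]; ce <- h$contig_end[i]
        ids <- h$identity[i] * h$aligned_aa_len[i]
        aas <- h$aligned_aa_len[i]; sc <- h$score[i]
      }
    }
    flush_chain()
  }
  do.call(rbind, out)
}

#' Group candidate transcripts into elements under the 80/80 rule
#'
#' Two transcripts belong to the same retroelement when they share at least
#' `min_identity` sequence identity over at least `min_coverage` of the
#' shorter sequence (local alignment). Clustering is single-linkage on this
#' predicate after a canonical sort, so the result does not depend on input
#' order.
#'
#' @param candidates `DNAStringSet` of retained transcripts.
#' @param classes optional named vector of per-contig superfamily classes
#'   (majority vote labels the cluster).
#' @param min_identity,min_coverage the 80/80 thresholds.
#' @param prescreen_k k-mer length for the alignment prescreen (pairs sharing
#'   no k-mer are never aligned; at the 80/80 boundary shared exact k-mers of
#'   this size are abundant).
#' @return list of `RetroelementCluster` objects: `element_id`,
#'   `member_contig_ids`, `superfamily_class`, `representative`, and after
#'   [consensus_build()] a `consensus`.
#' @export
cluster_elements <- function(candidates, classes = NULL, min_identity = 0.80,
                             min_coverage = 0.80, prescreen_k = 14) {
  if (length(candidates) == 0) stop_config("no candidates to cluster")
  ord <- order(names(candidates))
  candidates <- candidates[ord]
  n <- length(candidates)
  txt <- as.character(candidates)
  maps <- lapply(txt, kmer_map, k = prescreen_k)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (find(i) == find(j)) next
      if (pair_similarity_8080(txt[i], txt[j], maps[[i]], maps[[j]],
                               min_identity, min_coverage))
        parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  groups <- split(names(candidates), comp)
  groups <- groups[order(vapply(groups, function(g) g[1], ""))]
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    members <- sort(groups[[gi]])
    wid <- Biostrings::width(candidates[members])
    rep_id <- members[order(-wid, members)][1]
    cls <- NA_character_
    if (!is.null(classes)) {
      cc <- classes[members]
      cc <- cc[!is.na(cc)]
      if (length(cc)) cls <- names(sort(table(cc), decreasing = TRUE))[1]
    }
    out[[gi]] <- structure(list(
      element_id = sprintf("RE%03d", gi),
      member_contig_ids = members,
      representative = rep_id,
      superfamily_class = cls,
      consensus = NULL), class = "RetroelementCluster")
  }
  out
}

#' Build the majority-vote consensus of a cluster
#'
#' Members are aligned to the cluster representative (the longest member);
#' the most frequent nucleotide at each representative position is retained,
#' independent of how many members cover that position, so single-coverage
#' columns adopt their only base. Ties break toward the representative's
#' base, then alphabetically; columns whose majority vote is a gap are
#' dropped.
#'
#' @param cluster a `RetroelementCluster` from [cluster_elements()].
#' @param candidates the `DNAStringSet` the cluster indexes into.
#' @return The cluster with its `consensus` (character string) filled in.
#' @export
consensus_build <- function(cluster, candidates) {
  members <- cluster$member_contig_ids
  rep_id <- cluster$representative
  rep_seq <- as.character(candidates[[rep_id]])
  L <- nchar(rep_seq)
  rep_v <- strsplit(rep_seq, "")[[1]]
  votes <- matrix(0L, nrow = 5, ncol = L,
                  dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (m in members) {
    if (m == rep_id) {
      idx <- match(rep_v, rownames(votes))
      votes[cbind(idx, seq_len(L))] <- votes[cbind(idx, seq_len(L))] + 1L
      next
    }
    a <- align_nt(as.character(candidates[[m]]), rep_seq, type = "local")
    pv <- strsplit(a$pattern_aln, "")[[1]]
    sv <- strsplit(a$subject_aln, "")[[1]]
    spos <- a$s_start - 1L
    for (k in seq_along(sv)) {
      if (sv[k] == "-") next       # insertion in member: no rep column
      spos <- spos + 1L
      base <- pv[k]
      if (!base %in% rownames(votes)) base <- "-"
      votes[base, spos] <- votes[base, spos] + 1L
    }
  }
  cons <- character(L)
  for (p in seq_len(L)) {
    v <- votes[, p]
    if (sum(v) == 0) { cons[p] <- rep_v[p]; next }
    mx <- max(v)
    top <- rownames(votes)[v == mx]
    pick <- if (rep_v[p] %in% top) rep_v[p] else sort(top)[1]
    cons[p] <- pick
  }
  cluster$consensus <- paste(cons[cons != "-"], collapse = "")
  cluster
}

#' @export
print.RetroelementCluster <- function(x, ...) {
  cat(sprintf("<RetroelementCluster %s: %d member(s), class %s%s>\n",
              x$element_id, length(x$member_contig_ids),
              ifelse(is.na(x$superfamily_class), "?", x$superfamily_class),
              if (!is.null(x$consensus))
                sprintf(", consensus %d nt", nchar(x$consensus)) else ""))
  invisible(x)
}
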