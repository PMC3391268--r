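# Synthetic-data generator: retroelement templates, diverged copy families,
# host transcriptomes and paired-end reads, all with complete ground truth so
# every downstream stage of the pipeline can be tested against known answers.

new_feature_table <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             meta = character(), stringsAsFactors = FALSE)
}

add_feature <- function(tab, kind, start, end, meta = "") {
  rbind(tab, data.frame(kind = kind, start = as.integer(start),
                        end = as.integer(end), meta = meta,
                        stringsAsFactors = FALSE))
}

#' Build an LTR retroelement template
#'
#' Constructs a synthetic full-length LTR retroelement satisfying the
#' structural rules used for full-length identification: a pair of terminal
#' repeats (identical at generation time unless `ltr_divergence` > 0 emulates
#' post-insertion aging), a PBS complementary to the 3' end of the named tRNA
#' within 30 nt downstream of the 5' LTR, a polyprotein ORF carrying the
#' superfamily's canonical domain order (gypsy: PRO-RVT-RNH-INT; copia:
#' PRO-INT-RVT-RNH), and a purine-rich PPT immediately upstream of the 3' LTR.
#'
#' @param superfamily one of `gypsy`, `BEL`, `copia`, `DIRS`.
#' @param ltr_len LTR length in nt (>= 100).
#' @param internal_len internal region length in nt (>= 900 and large enough
#'   to hold the domain cassette).
#' @param trna_id a tRNA id present in `trna_set`.
#' @param seed integer seed; identical seeds give identical templates.
#' @param ltr_divergence fraction of LTR sites substituted in the 3' copy.
#' @param ppt include a PPT (set `FALSE` to emulate elements with no
#'   assignable polypurine tract).
#' @param trna_set tRNA reference set.
#' @return A list of class `retro_template` with `id`, `superfamily`,
#'   `sequence`, `features` (0-based half-open), `trna_id`.
#' @export
make_ltr_template <- function(superfamily, ltr_len = 300, internal_len = 4000,
                              trna_id = "tRNA-Met", seed = 1,
                              ltr_divergence = 0, ppt = TRUE,
                              trna_set = retro_trna_set()) {
  known <- c("gypsy", "BEL", "copia", "DIRS")
  if (!superfamily %in% known)
    stop_config("unknown superfamily: ", superfamily)
  if (!trna_id %in% names(trna_set))
    stop_config("unknown tRNA: ", trna_id)
  if (ltr_len < 100) stop_config("ltr_len must be >= 100")
  if (internal_len < 900) stop_config("internal_len must be >= 900")

  dom_order <- switch(superfamily,
    gypsy = c("PRO", "RVT", "RNH", "INT"),
    BEL   = c("PRO", "RVT", "RNH", "INT"),
    copia = c("PRO", "INT", "RVT", "RNH"),
    DIRS  = c("RVT", "RNH"))
  rvt_pep <- clade_rvt(switch(superfamily, gypsy = "gypsy", BEL = "BEL",
                              copia = "copia", DIRS = "Mag"))
  pep_of <- function(d) if (d == "RVT") rvt_pep else
    clade_domain(d, superfamily)

  with_seed(seed, {
    ltr5 <- random_dna(ltr_len)
    trna <- toupper(as.character(trna_set[[trna_id]]))
    pbs <- revcomp(substr(trna, nchar(trna) - 17, nchar(trna)))
    linker <- "GSAGA"
    pol_pep <- paste0("M", paste(vapply(dom_order, pep_of, ""), collapse = linker))
    orf_nt <- paste0(reverse_translate(pol_pep), "TAA")
    fixed <- 2 + nchar(pbs) + nchar(orf_nt) + 13 + 2
    if (internal_len < fixed + 40)
      stop_config("internal_len too small for the domain cassette (needs >= ",
                  fixed + 40, ")")
    pad <- internal_len - fixed
    pad5 <- pad %/% 2
    pad3 <- pad - pad5
    ppt_seq <- paste(sample(c("A", "G"), 13, replace = TRUE), collapse = "")
    ppt_block <- if (ppt) ppt_seq else random_dna_no_ppt(13)
    pad3_seq <- random_dna(pad3)
    if (!ppt && pad3 > 0) {
      # keep the whole PPT search window purine-poor so absence is unambiguous
      k <- min(pad3, 25L)
      substr(pad3_seq, pad3 - k + 1, pad3) <-
        paste(sample(c("C", "T"), k, replace = TRUE), collapse = "")
    }
    internal <- paste0("GT", pbs, random_dna(pad5), orf_nt, pad3_seq,
                       ppt_block, "CA")
    ltr3 <- if (ltr_divergence > 0) {
      nmut <- max(1L, round(ltr_divergence * ltr_len))
      v <- strsplit(ltr5, "")[[1]]
      pos <- sample(ltr_len, nmut)
      v[pos] <- vapply(v[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      paste(v, collapse = "")
    } else ltr5
    sequence <- paste0(ltr5, internal, ltr3)

    f <- new_feature_table()
    f <- add_feature(f, "LTR5", 0, ltr_len)
    pbs0 <- ltr_len + 2
    f <- add_feature(f, "PBS", pbs0, pbs0 + nchar(pbs),
                     paste0("trna_id=", trna_id))
    orf0 <- ltr_len + 2 + nchar(pbs) + pad5
    f <- add_feature(f, "ORF", orf0, orf0 + nchar(orf_nt), "name=pol")
    off <- 1L  # leading Met
    for (d in dom_order) {
      dlen <- nchar(pep_of(d))
      f <- add_feature(f, "domain", orf0 + 3 * off, orf0 + 3 * (off + dlen),
                       paste0("domain=", d))
      off <- off + dlen + nchar(linker)
    }
    if (ppt) {
      ppt0 <- ltr_len + internal_len - 13 - 2
      f <- add_feature(f, "PPT", ppt0, ppt0 + 13)
    }
    f <- add_feature(f, "LTR3", ltr_len + internal_len,
                     ltr_len + internal_len + ltr_len)

    structure(list(
      id = paste0(superfamily, "_tpl_", seed),
      superfamily = superfamily, sequence = sequence, features = f,
      trna_id = trna_id, ltr_len = ltr_len,
      ltr_identity = 100 * (1 - hamming(ltr5, ltr3) / ltr_len)),
      class = "retro_template")
  })
}

# Purine-poor filler: a 13-nt block guaranteed not to read as a PPT.
random_dna_no_ppt <- function(n) {
  paste(sample(c("C", "T"), n, replace = TRUE), collapse = "")
}

#' Build a non-LTR retroelement template
#'
#' Constructs a synthetic non-LTR (LINE-like) element for one of the
#' supported clades: an optional ORF1 carrying at least one CCHC zinc-finger
#' motif, an ORF2 with APE followed by the clade's RVT (plus RNH in the
#' L2/Nimb/I clades), an AT-rich 3' UTR and a poly-A tail.
#'
#' @param clade one of CR1, L2, I, R1, Jockey, RTE, Vingi, Nimb, Daphne,
#'   Penelope.
#' @param orf1 include a separate ORF1 with a CCHC motif.
#' @param seed integer seed.
#' @param utr5_len,utr3_len UTR lengths in nt.
#' @return A list of class `retro_template` (superfamily `nonLTR_<clade>`).
#' @export
make_nonltr_template <- function(clade, orf1 = TRUE, seed = 1,
                                 utr5_len = 60, utr3_len = 50) {
  if (!clade %in% NONLTR_CLADES) stop_config("unknown clade: ", clade)
  rvt_pep <- clade_rvt(clade)
  with_seed(seed, {
    cchc <- paste0("C", rand_pep_no_ch(2), "C", rand_pep_no_ch(4), "H",
                   rand_pep_no_ch(4), "C")
    seqparts <- character()
    f <- new_feature_table()
    pos <- 0L
    utr5 <- random_dna(utr5_len)
    seqparts <- c(seqparts, utr5); pos <- pos + utr5_len
    if (orf1) {
      orf1_pep <- paste0("M", rand_pep_no_ch(40), cchc, rand_pep_no_ch(60))
      orf1_nt <- paste0(reverse_translate(orf1_pep), "TAA")
      f <- add_feature(f, "ORF", pos, pos + nchar(orf1_nt), "name=orf1")
      seqparts <- c(seqparts, orf1_nt); pos <- pos + nchar(orf1_nt)
      gap <- random_dna(15)
      seqparts <- c(seqparts, gap); pos <- pos + 15L
    }
    with_rnh <- clade %in% c("L2", "Nimb", "I")
    ape_pep <- clade_domain("APE", clade)
    rnh_pep <- clade_domain("RNH", clade)
    orf2_pep <- paste0("M", ape_pep, "GSAGA", rvt_pep,
                       if (with_rnh) paste0("GSAGA", rnh_pep) else "")
    orf2_nt <- paste0(reverse_translate(orf2_pep), "TAA")
    orf2_0 <- pos
    f <- add_feature(f, "ORF", pos, pos + nchar(orf2_nt), "name=orf2")
    ape_len <- nchar(ape_pep)
    f <- add_feature(f, "domain", pos + 3, pos + 3 * (1 + ape_len), "domain=APE")
    rvt_off <- 1 + ape_len + 5
    f <- add_feature(f, "domain", pos + 3 * rvt_off,
                     pos + 3 * (rvt_off + nchar(rvt_pep)), "domain=RVT")
    if (with_rnh) {
      rnh_off <- rvt_off + nchar(rvt_pep) + 5
      f <- add_feature(f, "domain", pos + 3 * rnh_off,
                       pos + 3 * (rnh_off + nchar(rnh_pep)),
                       "domain=RNH")
    }
    seqparts <- c(seqparts, orf2_nt); pos <- pos + nchar(orf2_nt)
    utr3 <- paste(sample(c("A", "T", "G", "C"), utr3_len, replace = TRUE,
                         prob = c(0.38, 0.38, 0.12, 0.12)), collapse = "")
    f <- add_feature(f, "UTR3", pos, pos + utr3_len)
    seqparts <- c(seqparts, utr3); pos <- pos + utr3_len
    polya <- strrep("A", 20)
    f <- add_feature(f, "polyA", pos, pos + 20L)
    seqparts <- c(seqparts, polya); pos <- pos + 20L
    structure(list(
      id = paste0("nonLTR_", clade, "_tpl_", seed),
      superfamily = paste0("nonLTR_", clade),
      sequence = paste(seqparts, collapse = ""), features = f,
      trna_id = NULL), class = "retro_template")
  })
}

# Random peptide avoiding C and H so planted CCHC motifs stay unique,
# and avoiding W (whose codon TGG can seed spurious contexts is untrue; W is
# excluded only to keep the alphabet symmetric with the motif filler).
rand_pep_no_ch <- function(n) {
  paste(sample(setdiff(AA_ALPHABET20, c("C", "H")), n, replace = TRUE),
        collapse = "")
}

#' Evolve a family of diverged copies from a template
#'
#' Each copy substitutes every site independently with probability `P`
#' (uniform choice among the three alternative bases), matching the
#' one-parameter substitution model used for divergence dating. Copies of
#' non-LTR templates may be 5'-truncated (truncation length uniform over
#' 10-80% of the element), emulating the abortive reverse transcription that
#' leaves most new LINE copies without their 5' end.
#'
#' @param template a `retro_template`.
#' @param n_copies number of copies.
#' @param P per-site substitution probability, `0 <= P < 0.75`.
#' @param truncate_prob probability that a non-LTR copy is 5'-truncated.
#' @param seed integer seed.
#' @return list with `copies` (`DNAStringSet`) and `truth` (data.frame with
#'   `template_id`, `copy_id`, `divergence`, `realized_divergence`,
#'   `truncated_5prime`, `trunc_len`).
#' @export
evolve_family <- function(template, n_copies, P, truncate_prob = 0, seed = 1) {
  if (P < 0 || P >= 0.75)
    stop_config("saturation: divergence P must satisfy 0 <= P < 0.75")
  if (truncate_prob < 0 || truncate_prob > 1)
    stop_config("truncate_prob must be in [0, 1]")
  is_nonltr <- startsWith(template$superfamily, "nonLTR")
  with_seed(seed, {
    seqs <- character(n_copies)
    truth <- vector("list", n_copies)
    L <- nchar(template$sequence)
    for (i in seq_len(n_copies)) {
      s <- mutate_dna(template$sequence, P)
      realized <- hamming(s, template$sequence) / L
      trunc <- is_nonltr && runif(1) < truncate_prob
      tlen <- 0L
      if (trunc) {
        tlen <- as.integer(round(runif(1, 0.1, 0.8) * L))
        s <- substr(s, tlen + 1, L)
      }
      seqs[i] <- s
      truth[[i]] <- data.frame(
        template_id = template$id,
        copy_id = sprintf("%s_c%02d", template$id, i),
        divergence = P, realized_divergence = realized,
        truncated_5prime = trunc, trunc_len = tlen,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    list(copies = Biostrings::DNAStringSet(setNames(seqs, truth$copy_id)),
         truth = truth, template = template)
  })
}

#' Assemble a synthetic transcriptome from element families
#'
#' Emits one transcript per element copy, `n_host_genes` host-gene transcripts
#' (each carrying an ORF matching a host decoy peptide), `n_transposase_decoys`
#' transcripts carrying a DDE transposase ORF (which the catalogue must
#' classify as DNA transposons and remove), and optionally `n_embedded`
#' host transcripts with an element copy embedded 3' of the host ORF
#' (emulating co-transcription with adjacent protein-coding genes).
#'
#' @param families list of [evolve_family()] results (may be empty).
#' @param n_host_genes,n_transposase_decoys,n_embedded decoy counts.
#' @param seed integer seed.
#' @return list with `transcripts` (`DNAStringSet`) and `truth` (data.frame
#'   with `transcript_id`, `kind`, `template_id`, `copy_id`, `elem_start`,
#'   `elem_end`; element spans 0-based half-open).
#' @export
build_transcriptome <- function(families, n_host_genes = 5,
                                n_transposase_decoys = 2, n_embedded = 0,
                                seed = 1) {
  with_seed(seed, {
    seqs <- character(); ids <- character(); rows <- list()
    note <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
      ..., stringsAsFactors = FALSE)
    for (fam in families) {
      for (i in seq_along(fam$copies)) {
        cid <- names(fam$copies)[i]
        tid <- paste0("tx_", cid)
        seqs <- c(seqs, as.character(fam$copies[[i]])); ids <- c(ids, tid)
        note(transcript_id = tid, kind = "element",
             template_id = fam$truth$template_id[i], copy_id = cid,
             elem_start = 0L, elem_end = nchar(as.character(fam$copies[[i]])))
      }
    }
    hosts <- retro_host_decoys()
    for (h in seq_len(n_host_genes)) {
      pep <- as.character(hosts[[(h - 1L) %% length(hosts) + 1L]])
      orf <- paste0(reverse_translate(paste0("M", pep)), "TAA")
      s <- paste0(random_dna(80), orf, random_dna(120))
      tid <- sprintf("tx_host_%02d", h)
      seqs <- c(seqs, s); ids <- c(ids, tid)
      note(transcript_id = tid, kind = "host", template_id = NA_character_,
           copy_id = NA_character_, elem_start = NA_integer_,
           elem_end = NA_integer_)
    }
    for (d in seq_len(n_transposase_decoys)) {
      pan <- retro_protein_panel()
      tp <- as.character(pan[["transposase"]])
      orf <- paste0(reverse_translate(paste0("M", tp)), "TAA")
      s <- paste0(random_dna(60), orf, random_dna(90))
      tid <- sprintf("tx_tpase_%02d", d)
      seqs <- c(seqs, s); ids <- c(ids, tid)
      note(transcript_id = tid, kind = "transposase",
           template_id = NA_character_, copy_id = NA_character_,
           elem_start = NA_integer_, elem_end = NA_integer_)
    }
    if (n_embedded > 0 && length(families)) {
      for (e in seq_len(n_embedded)) {
        fam <- families[[(e - 1L) %% length(families) + 1L]]
        extra <- mutate_dna(fam$template$sequence, fam$truth$divergence[1])
        pep <- as.character(hosts[[(e - 1L) %% length(hosts) + 1L]])
        orf <- paste0(reverse_translate(paste0("M", pep)), "TAA")
        head_part <- paste0(random_dna(60), orf, random_dna(30))
        s <- paste0(head_part, extra)
        tid <- sprintf("tx_embed_%02d", e)
        seqs <- c(seqs, s); ids <- c(ids, tid)
        note(transcript_id = tid, kind = "host_embedded",
             template_id = fam$template$id,
             copy_id = sprintf("%s_embed%02d", fam$template$id, e),
             elem_start = nchar(head_part), elem_end = nchar(s))
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(transcript_id = character(), kind = character(),
                 template_id = character(), copy_id = character(),
                 elem_start = integer(), elem_end = integer(),
                 stringsAsFactors = FALSE)
    list(transcripts = Biostrings::DNAStringSet(setNames(seqs, ids)),
         truth = truth)
  })
}

#' Simulate paired-end (or single-end) reads from a transcriptome
#'
#' Fragments are placed uniformly within each transcript; transcripts are
#' chosen with probability proportional to `weights` times the number of
#' admissible fragment placements. Mate orientation is forward-reverse.
#' A fraction `ambig_frac` of reads receives more than one third ambiguous
#' bases (for QC testing). Transcripts shorter than the insert are skipped
#' with a warning.
#'
#' @param transcriptome `DNAStringSet` (or FASTA path).
#' @param n_reads number of reads (pairs count as two reads).
#' @param read_len read length in nt (>= 30).
#' @param paired simulate read pairs.
#' @param insert_mean,insert_sd insert size distribution (nt).
#' @param ambig_frac fraction of reads receiving > 1/3 ambiguous bases.
#' @param weights optional per-transcript expression weights (molar);
#'   default uniform.
#' @param seed integer seed.
#' @return list with `read1`, `read2` (`DNAStringSet`; `read2` is `NULL` for
#'   single-end) and `truth` (data.frame with fragment coordinates, 0-based
#'   half-open on the transcript).
#' @export
simulate_reads <- function(transcriptome, n_reads, read_len = 75,
                           paired = TRUE, insert_mean = 250,
                           insert_sd = insert_mean / 10, ambig_frac = 0,
                           weights = NULL, seed = 1) {
  txs <- as_dna_set(transcriptome)
  if (read_len < 30) stop_config("read_len must be >= 30")
  if (paired && insert_mean <= read_len)
    stop_config("insert_mean must exceed read_len for paired reads")
  lens <- Biostrings::width(txs)
  if (is.null(weights)) weights <- rep(1, length(txs))
  stopifnot(length(weights) == length(txs))
  min_frag <- if (paired) insert_mean else read_len
  ok <- lens >= min_frag
  if (any(!ok & weights > 0))
    warning("skipping ", sum(!ok & weights > 0),
            " transcript(s) shorter than the insert")
  eff <- ifelse(ok, weights * (lens - min_frag + 1), 0)
  if (sum(eff) <= 0) stop_config("no transcript is long enough to sample from")
  n_frag <- if (paired) ceiling(n_reads / 2) else n_reads
  txt <- as.character(txs)
  with_seed(seed, {
    pick <- sample(length(txs), n_frag, replace = TRUE, prob = eff)
    frag <- if (paired) {
      pmin(pmax(round(rnorm(n_frag, insert_mean, insert_sd)), read_len),
           lens[pick])
    } else rep(read_len, n_frag)
    start0 <- floor(runif(n_frag) * (lens[pick] - frag + 1))  # 0-based
    r1 <- substr(txt[pick], start0 + 1, start0 + read_len)
    truth <- data.frame(
      fragment_id = sprintf("frag%06d", seq_len(n_frag)),
      transcript_id = names(txs)[pick],
      frag_start = as.integer(start0), frag_end = as.integer(start0 + frag),
      stringsAsFactors = FALSE)
    r2 <- NULL
    if (paired) {
      mate2 <- substr(txt[pick], start0 + frag - read_len + 1, start0 + frag)
      r2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(mate2)))
    }
    nms1 <- paste0(truth$fragment_id, "/1")
    reads1 <- setNames(r1, nms1)
    reads2 <- if (paired) setNames(r2, paste0(truth$fragment_id, "/2")) else NULL
    if (ambig_frac > 0) {
      all_n <- if (paired) 2L * n_frag else n_frag
      n_amb <- round(ambig_frac * all_n)
      tgt <- sample(all_n, n_amb)
      n_pos <- floor(read_len / 3) + 1L
      garble <- function(s) {
        v <- strsplit(s, "")[[1]]
        v[sample(read_len, n_pos)] <- "N"
        paste(v, collapse = "")
      }
      for (t in tgt) {
        if (t <= n_frag) reads1[t] <- garble(reads1[t])
        else reads2[t - n_frag] <- garble(reads2[t - n_frag])
      }
    }
    list(read1 = Biostrings::DNAStringSet(reads1),
         read2 = if (paired) Biostrings::DNAStringSet(reads2) else NULL,
         truth = truth)
  })
}

#' Write a simulation bundle to disk
#'
#' Emits `transcripts.fasta`, `reads_1.fastq` / `reads_2.fastq` (constant
#' quality), `truth.json` and `features.gff3` (1-based inclusive coordinates).
#'
#' @param transcriptome result of [build_transcriptome()].
#' @param reads result of [simulate_reads()].
#' @param templates optional list of `retro_template`s (for the GFF3).
#' @param dir output directory.
#' @return Invisibly, the output paths.
#' @export
write_simulation <- function(transcriptome, reads, templates = list(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "transcripts.fasta")
  Biostrings::writeXStringSet(transcriptome$transcripts, fa)
  write_fastq(reads$read1, file.path(dir, "reads_1.fastq"))
  if (!is.null(reads$read2))
    write_fastq(reads$read2, file.path(dir, "reads_2.fastq"))
  truth <- list(transcripts = transcriptome$truth, fragments = reads$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (length(templates)) {
    gr <- do.call(c, lapply(templates, template_granges))
    rtracklayer::export.gff3(gr, file.path(dir, "features.gff3"))
  }
  invisible(dir)
}

write_fastq <- function(reads, path) {
  q <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads), function(w) strrep("I", w), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
}

template_granges <- function(template) {
  f <- template$features
  GenomicRanges::GRanges(
    seqnames = template$id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    type = f$kind, meta = f$meta)
}
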