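# A complete simulated retroelement transcriptome study with ground truth:
# the standard benchmark configuration used to validate the whole pipeline.

#' Simulate a multi-family retroelement transcriptome study
#'
#' Builds the package's reference benchmark: three LTR families (a gypsy
#' element with PBS = tRNA-Met and a PPT, planted LTR divergence 3%; a BEL
#' element with the PPT deleted and identical LTRs; a copia element at 6%
#' LTR divergence) and four non-LTR families (a CCHC-bearing Nimb-like
#' element, an RTE-like family at 9% copy divergence - the proliferation
#' burst - plus CR1-like and Daphne-like families), each expanded into
#' `n_copies` diverged copies, mixed with host-gene and transposase decoys,
#' and sequenced as 75 nt read pairs across three developmental samples with
#' an elevated egg stage. Expression weights are log-spread so every element
#' has a distinct planted RPKM.
#'
#' @param seed master seed; all stages derive their streams from it.
#' @param n_copies copies per family.
#' @param reads_per_sample total reads (mates counted) per sample.
#' @param read_len,insert_mean,insert_sd read geometry.
#' @param truncate_prob 5'-truncation probability for non-LTR copies.
#' @return list with `contigs` (all transcripts, the pipeline input),
#'   `samples` (named list of `list(read1, read2)`), `truth` (templates,
#'   family table, clade map, planted LTR identities, expected RPKM matrix,
#'   transcript map) and `params`.
#' @export
simulate_study <- function(seed = 1, n_copies = 10, reads_per_sample = 30000,
                           read_len = 75, insert_mean = 250,
                           insert_sd = 25, truncate_prob = 0.2) {
  spec <- list(
    list(kind = "ltr", superfamily = "gypsy", trna = "tRNA-Met",
         ltr_div = 0.03, ppt = TRUE, P = 0.03, clade = "gypsy"),
    list(kind = "ltr", superfamily = "BEL", trna = "tRNA-Ser",
         ltr_div = 0.00, ppt = FALSE, P = 0.02, clade = "BEL"),
    list(kind = "ltr", superfamily = "copia", trna = "tRNA-Val",
         ltr_div = 0.06, ppt = TRUE, P = 0.05, clade = "copia"),
    list(kind = "nonltr", clade = "Nimb", orf1 = TRUE, P = 0.04),
    list(kind = "nonltr", clade = "RTE", orf1 = FALSE, P = 0.09),
    list(kind = "nonltr", clade = "CR1", orf1 = FALSE, P = 0.05),
    list(kind = "nonltr", clade = "Daphne", orf1 = TRUE, P = 0.06))
  templates <- list()
  families <- list()
  fam_rows <- list()
  for (i in seq_along(spec)) {
    sp <- spec[[i]]
    tpl <- if (sp$kind == "ltr") {
      make_ltr_template(sp$superfamily, ltr_len = 300, internal_len = 4000,
                        trna_id = sp$trna, seed = str_seed("tpl", seed + i),
                        ltr_divergence = sp$ltr_div, ppt = sp$ppt)
    } else {
      make_nonltr_template(sp$clade, orf1 = sp$orf1,
                           seed = str_seed("tpl", seed + i))
    }
    fam <- evolve_family(tpl, n_copies, sp$P,
                         truncate_prob = if (sp$kind == "nonltr")
                           truncate_prob else 0,
                         seed = str_seed("fam", seed + i))
    templates[[tpl$id]] <- tpl
    families[[tpl$id]] <- fam
    fam_rows[[i]] <- data.frame(
      template_id = tpl$id, kind = sp$kind, clade = sp$clade,
      divergence = sp$P,
      ltr_identity = if (sp$kind == "ltr") tpl$ltr_identity else NA,
      ppt_present = if (sp$kind == "ltr") sp$ppt else NA,
      trna_id = if (sp$kind == "ltr") sp$trna else NA_character_,
      length = nchar(tpl$sequence), stringsAsFactors = FALSE)
  }
  fam_tab <- do.call(rbind, fam_rows)

  txome <- build_transcriptome(families, n_host_genes = 4,
                               n_transposase_decoys = 2,
                               seed = str_seed("txome", seed))
  txs <- txome$transcripts
  tx_truth <- txome$truth

  # expression design: log-spread weights, egg stage globally elevated
  sample_names <- c("egg", "instar4", "adult")
  base_w <- 2 ^ seq(0, 6, length.out = nrow(fam_tab))      # 1x .. 64x
  names(base_w) <- fam_tab$template_id
  stage_mult <- c(egg = 2.5, instar4 = 1, adult = 0.7)
  jitter <- outer(seq_len(nrow(fam_tab)), seq_along(sample_names),
                  function(i, j) 2 ^ (((i * 7 + j * 3) %% 5 - 2) / 2))
  rownames(jitter) <- fam_tab$template_id
  w_mat <- sweep(jitter, 2, stage_mult, "*") * base_w
  colnames(w_mat) <- sample_names

  lens <- Biostrings::width(txs)
  names(lens) <- names(txs)
  eff_places <- pmax(lens - insert_mean + 1, 0)
  samples <- list()
  expected_rpkm <- matrix(0, nrow(fam_tab), length(sample_names),
                          dimnames = list(fam_tab$template_id, sample_names))
  for (sj in seq_along(sample_names)) {
    sn <- sample_names[sj]
    w <- setNames(numeric(length(txs)), names(txs))
    for (tid in fam_tab$template_id) {
      member <- tx_truth$transcript_id[!is.na(tx_truth$template_id) &
                                         tx_truth$template_id == tid &
                                         tx_truth$kind == "element"]
      w[member] <- w_mat[tid, sj]
    }
    w[tx_truth$transcript_id[tx_truth$kind %in% c("host", "transposase")]] <- 4
    rd <- simulate_reads(txs, reads_per_sample, read_len = read_len,
                         paired = TRUE, insert_mean = insert_mean,
                         insert_sd = insert_sd, weights = w,
                         seed = str_seed(paste0("reads_", sn), seed))
    samples[[sn]] <- rd
    # planted RPKM: expected fragment counts (x2 mates) per element over
    # expected mapped total, with the template length as element length
    probs <- w * eff_places
    probs <- probs / sum(probs)
    exp_reads <- probs * reads_per_sample
    exp_cnt <- vapply(fam_tab$template_id, function(tid) {
      member <- tx_truth$transcript_id[!is.na(tx_truth$template_id) &
                                         tx_truth$template_id == tid &
                                         tx_truth$kind == "element"]
      sum(exp_reads[member])
    }, 0)
    mapped_exp <- sum(exp_cnt)
    expected_rpkm[, sj] <- exp_cnt / (fam_tab$length / 1000) / (mapped_exp / 1e6)
  }

  list(contigs = txs,
       samples = lapply(samples, function(s) list(read1 = s$read1,
                                                  read2 = s$read2)),
       truth = list(templates = templates, families = fam_tab,
                    transcripts = tx_truth, expected_rpkm = expected_rpkm,
                    clades = setNames(fam_tab$clade, fam_tab$template_id),
                    fragments = lapply(samples, function(s) s$truth)),
       params = list(seed = seed, n_copies = n_copies,
                     reads_per_sample = reads_per_sample,
                     read_len = read_len, insert_mean = insert_mean,
                     insert_sd = insert_sd))
}

#' Emulate assembly artifacts for an LTR element family
#'
#' Produces the contig structures that short-read assemblers generate from
#' LTR retroelements: `inverted` returns the full element with the internal
#' region reverse-complemented (the wrong-direction misassembly caused by
#' the two near-identical LTRs), and `split` returns an internal contig
#' retaining only short LTR stubs plus a single separate LTR contig (the
#' collapsed assembly in which both LTR copies merged into one contig).
#'
#' @param template a `retro_template` from [make_ltr_template()].
#' @param mode `inverted` or `split`.
#' @param stub_len length of LTR stubs retained on the internal contig
#'   (`split` mode).
#' @return `DNAStringSet` of misassembled contigs.
#' @export
misassemble_contigs <- function(template, mode = c("inverted", "split"),
                                stub_len = 40) {
  mode <- match.arg(mode)
  s <- template$sequence
  f <- template$features
  l5 <- f[f$kind == "LTR5", ]
  l3 <- f[f$kind == "LTR3", ]
  internal <- substr(s, l5$end + 1, l3$start)
  if (mode == "inverted") {
    out <- Biostrings::DNAStringSet(setNames(
      paste0(substr(s, 1, l5$end), revcomp(internal),
             substr(s, l3$start + 1, nchar(s))),
      paste0(template$id, "_inverted")))
    return(out)
  }
  ltr <- substr(s, l5$start + 1, l5$end)
  int_contig <- paste0(substr(ltr, nchar(ltr) - stub_len + 1, nchar(ltr)),
                       internal, substr(ltr, 1, stub_len))
  Biostrings::DNAStringSet(setNames(
    c(int_contig, ltr),
    paste0(template$id, c("_internal", "_ltr"))))
}
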