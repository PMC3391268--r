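# End-to-end orchestration: discovery -> reconstruction -> annotation ->
# phylogeny -> expression -> divergence dating, with TSV/FASTA/GFF3/newick
# outputs and a JSON summary report.

#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_full_analysis()]. Sequence inputs
#' may be in-memory `DNAStringSet`s or FASTA/FASTQ paths.
#'
#' @param contigs assembled transcriptome contigs.
#' @param samples named list; each entry a list with `read1` and `read2`
#'   (paired FASTQ paths or `DNAStringSet`s). May be empty: expression and
#'   divergence stages are then skipped.
#' @param panel,trna_set,rvt_refs,host_decoys reference sets (defaults: the
#'   bundled synthetic sets).
#' @param policy candidate [filter_policy()].
#' @param dedupe run contig redundancy removal first (use when pooling
#'   multiple assemblies).
#' @param bootstrap_reps NJ bootstrap replicates.
#' @param read_len nominal read length (nt).
#' @param insert_mean,insert_sd paired-end insert model.
#' @param min_junction_pairs junction support threshold for scaffolding.
#' @param express_max_mismatch_frac mismatch tolerance for expression
#'   mapping, as a fraction of the read length. The default 0.15 follows
#'   from the 80/80 family definition: members may sit ~10% from their
#'   consensus, and the binomial spread of per-read mismatch counts at that
#'   divergence stays within 15% of the read length.
#' @param divergence_sample which sample's reads feed the divergence
#'   landscape (default: the first).
#' @param min_aln_len minimal alignment length for divergence scans
#'   (strictly-longer rule).
#' @param rate substitution rate for burst dating.
#' @param bin_width divergence histogram bin width.
#' @param ltr_min_identity minimum LTR pair identity (fraction) for
#'   detection/validation.
#' @param min_orf_aa minimum ORF length for full-length validation.
#' @param seed master seed (bootstrap and any randomized policies).
#' @param outdir optional output directory; when set, all result files are
#'   written there.
#' @return list of class `PipelineConfig`.
#' @export
retro_config <- function(contigs, samples = list(),
                         panel = retro_protein_panel(),
                         trna_set = retro_trna_set(),
                         rvt_refs = rvt_reference_set(),
                         host_decoys = retro_host_decoys(),
                         policy = filter_policy(host_decoy_panel = host_decoys),
                         dedupe = FALSE, bootstrap_reps = 100,
                         read_len = 75, insert_mean = 250, insert_sd = 25,
                         min_junction_pairs = 3,
                         express_max_mismatch_frac = 0.15,
                         divergence_sample = NULL, min_aln_len = 70,
                         rate = 1.66e-8, bin_width = 0.01,
                         ltr_min_identity = 0.85, min_orf_aa = 200,
                         seed = 1, outdir = NULL) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full retroelement analysis
#'
#' Executes all stages on the configured inputs and returns a report bundle;
#' any stage failure halts with a stage-attributed error. Reruns with the
#' same configuration and seed are deterministic.
#'
#' @param config a [retro_config()].
#' @return list of class `retro_report`: `clusters`, `consensuses`,
#'   `rejections`, `full_length` (models + table), `annotations`,
#'   `phylogeny` (tree, assignments), `expression` (`ExpressionMatrix`,
#'   PCA), `divergence` (profiles, burst table), `summary`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  ## discovery
  res <- list()
  discovery <- stage("discovery", {
    contigs <- as_dna_set(config$contigs)
    if (length(contigs) == 0) stop("empty contig set")
    if (config$dedupe) contigs <- dedupe_contigs(contigs)
    hits <- translated_search(contigs, config$panel)
    filt <- apply_filters(contigs, hits, config$policy)
    if (length(filt$retained) == 0) stop("no candidate retroelement survives the filters")
    clusters <- cluster_elements(filt$retained, filt$classes)
    clusters <- lapply(clusters, consensus_build, candidates = filt$retained)
    cons <- Biostrings::DNAStringSet(
      setNames(vapply(clusters, function(cl) cl$consensus, ""),
               vapply(clusters, function(cl) cl$element_id, "")))
    list(contigs = contigs, hits = hits, filt = filt, clusters = clusters,
         consensuses = cons)
  })
  res$clusters <- discovery$clusters
  res$consensuses <- discovery$consensuses
  res$rejections <- discovery$filt$rejections

  ## pooled reads of the divergence/scaffolding sample
  pool <- NULL
  if (length(config$samples)) {
    dsn <- config$divergence_sample
    if (is.null(dsn)) dsn <- names(config$samples)[1]
    s <- config$samples[[dsn]]
    r1 <- qc_filter_reads(s$read1)
    r2 <- qc_filter_reads(s$read2)
    pool <- list(sample = dsn, read1 = r1, read2 = r2)
  }

  ## full-length LTR reconstruction
  recon <- stage("reconstruction", {
    cands <- detect_collapsed_ltr(res$consensuses,
                                  ltr_min_identity = config$ltr_min_identity)
    models <- list()
    for (cand in cands) {
      # self-repeat candidates are already full length; only fragmented
      # (ltr_pair) candidates need paired-end scaffolding
      scaf <- if (cand$type == "self_repeat") {
        s <- as.character(res$consensuses[[cand$internal_id]])
        list(sequence = s, ltr5_span = c(0L, cand$ltr_len),
             ltr3_span = c(nchar(s) - cand$ltr_len, nchar(s)),
             junction_support = NULL, candidate = cand)
      } else if (!is.null(pool)) {
        scaffold_with_pairs(cand, res$consensuses, pool$read1, pool$read2,
                            insert_mean = config$insert_mean,
                            insert_sd = config$insert_sd,
                            min_junction_pairs = config$min_junction_pairs)
      } else NULL
      m <- finalize_element(scaf, trna_set = config$trna_set,
                            min_orf_aa = config$min_orf_aa,
                            ltr_min_identity = 100 * config$ltr_min_identity)
      if (!is.null(m)) models[[m$element_id]] <- m
    }
    models
  })
  res$full_length <- list(
    models = recon,
    table = if (length(recon)) data.frame(
      element_id = vapply(recon, function(m) m$element_id, ""),
      length = vapply(recon, function(m) nchar(m$sequence), 0L),
      ltr_len = vapply(recon, function(m) m$ltr5_span[2] - m$ltr5_span[1], 0L),
      ltr_identity = vapply(recon, function(m) m$ltr_identity, 0L),
      pbs_trna = vapply(recon, function(m)
        if (is.null(m$pbs)) NA_character_ else m$pbs$trna_id, ""),
      ppt = vapply(recon, function(m) !is.null(m$ppt), TRUE),
      domain_order = vapply(recon, function(m)
        paste(m$domain_order, collapse = "-"), ""),
      stringsAsFactors = FALSE, row.names = NULL)
    else data.frame())

  ## structural annotation of all consensuses
  res$annotations <- stage("annotation", {
    lapply(setNames(nm = names(res$consensuses)), function(id) {
      s <- as.character(res$consensuses[[id]])
      orfs <- find_orfs(s, min_aa = 100)
      orfs_f <- orfs[orfs$frame > 0, , drop = FALSE]
      doms <- list()
      cchc <- 0L
      for (oi in seq_len(nrow(orfs_f))) {
        d <- locate_domains(orfs_f$peptide[oi])
        if (nrow(d)) {
          d$orf_start <- orfs_f$start[oi]
          doms[[length(doms) + 1L]] <- d
        }
        cchc <- cchc + nrow(scan_cchc(orfs_f$peptide[oi]))
      }
      list(orfs = orfs_f,
           domains = if (length(doms)) do.call(rbind, doms) else NULL,
           cchc_motifs = cchc,
           three_prime = detect_3prime_features(s))
    })
  })

  ## RVT phylogeny and clade assignment
  res$phylogeny <- stage("phylogeny", {
    ar <- withCallingHandlers(
      extract_and_align_rvt(res$consensuses, refs = config$rvt_refs),
      warning = function(w) invokeRestart("muffleWarning"))
    d <- poisson_distance(ar$alignment, ar$gappy_cols)
    tr <- nj_tree(d, ar$alignment, bootstrap_reps = config$bootstrap_reps,
                  seed = config$seed, exclude_cols = ar$gappy_cols)
    asn <- assign_clade(tr, ar$ref_clades)
    asn <- asn[asn$element_id %in% names(res$consensuses), , drop = FALSE]
    list(alignment = ar, tree = tr$tree, support = tr$support,
         assignments = asn, excluded = ar$excluded)
  })

  ## expression profiling
  res$expression <- if (length(config$samples)) stage("expression", {
    maxmm <- ceiling(config$express_max_mismatch_frac * config$read_len)
    counts <- NULL
    libs <- numeric(0)
    for (sn in names(config$samples)) {
      s <- config$samples[[sn]]
      rds <- c(qc_filter_reads(s$read1),
               if (!is.null(s$read2)) qc_filter_reads(s$read2))
      m <- map_reads(rds, res$consensuses, max_mismatch = maxmm)
      counts <- cbind(counts, m$counts)
      libs[sn] <- max(m$mapped_total, 1L)
    }
    colnames(counts) <- names(config$samples)
    em <- compute_rpkm(counts, Biostrings::width(res$consensuses), libs)
    pca <- if (ncol(counts) >= 3) stage_pca(em) else NULL
    list(matrix = em, pca = pca)
  }) else NULL

  ## divergence landscape and burst dating
  res$divergence <- if (!is.null(pool)) stage("divergence", {
    clade_of <- setNames(res$phylogeny$assignments$clade,
                         res$phylogeny$assignments$element_id)
    rds <- c(pool$read1, pool$read2)
    maxmm <- ceiling(0.35 * config$read_len)
    offs <- unique(pmax(0L, seq(0L, config$read_len - 12L, by = 6L)))
    m <- map_reads(rds, res$consensuses, max_mismatch = maxmm,
                   seed_offsets = offs)
    a <- m$assignments
    a <- a[a$aln_len > config$min_aln_len & !is.na(clade_of[a$element]), ,
           drop = FALSE]
    if (!nrow(a)) stop("no qualifying divergence alignments")
    scans <- data.frame(read_id = a$read_id, aln_len = a$aln_len,
                        mismatches = a$mismatches,
                        divergence = a$mismatches / a$aln_len,
                        stringsAsFactors = FALSE)
    clades <- unname(clade_of[a$element])
    cons_len <- setNames(Biostrings::width(res$consensuses),
                         names(res$consensuses))
    Ltab <- tapply(cons_len[a$element], clades, mean)
    prof <- divergence_profile(
      scans, clades, bin_width = config$bin_width,
      abundance_params = list(
        T_size = sum(Biostrings::width(as_dna_set(config$contigs))),
        l = config$read_len, N = length(rds), m = config$min_aln_len,
        L = as.list(Ltab)),
      rate = config$rate, weights = a$weight)
    burst <- data.frame(
      clade = vapply(prof, function(p) p$clade, ""),
      peak_divergence = vapply(prof, function(p) p$peak_divergence, 0),
      burst_age_years = vapply(prof, function(p) p$burst_age, 0),
      total_abundance = vapply(prof, function(p) sum(p$abundance), 0),
      stringsAsFactors = FALSE, row.names = NULL)
    list(profiles = prof, burst = burst, sample = pool$sample)
  }) else NULL

  ## summary
  asn <- res$phylogeny$assignments
  res$summary <- list(
    n_contigs = length(discovery$contigs),
    n_retained = length(discovery$filt$retained),
    n_elements = length(res$clusters),
    elements_by_class = as.list(table(vapply(
      res$clusters, function(cl) ifelse(is.na(cl$superfamily_class), "?",
                                        cl$superfamily_class), ""))),
    elements_by_clade = as.list(table(asn$clade[!is.na(asn$clade)])),
    n_full_length_ltr = length(res$full_length$models),
    ltr_identities = if (nrow(res$full_length$table))
      setNames(res$full_length$table$ltr_identity,
               res$full_length$table$element_id) else NULL,
    burst_ages = if (!is.null(res$divergence))
      setNames(res$divergence$burst$burst_age_years,
               res$divergence$burst$clade) else NULL,
    seed = config$seed)
  class(res) <- "retro_report"

  if (!is.null(config$outdir)) write_report_files(res, config)
  res
}

#' @export
print.retro_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<retro_report: %d contigs -> %d retained -> %d elements; ",
    "%d full-length LTR model(s)>\n"),
    s$n_contigs, s$n_retained, s$n_elements, s$n_full_length_ltr))
  invisible(x)
}

# Write the standard output files of a pipeline run.
write_report_files <- function(res, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  tsv <- function(d, f) write.table(d, out(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  Biostrings::writeXStringSet(res$consensuses, out("elements.fasta"))
  tsv(data.frame(
    element_id = rep(vapply(res$clusters, `[[`, "", "element_id"),
                     vapply(res$clusters, function(cl)
                       length(cl$member_contig_ids), 0L)),
    contig_id = unlist(lapply(res$clusters, `[[`, "member_contig_ids")),
    stringsAsFactors = FALSE), "clusters.tsv")
  tsv(res$rejections, "rejections.tsv")
  if (length(res$full_length$models)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      vapply(res$full_length$models, function(m) m$sequence, "")),
      out("full_length.fasta"))
    tsv(res$full_length$table, "report.tsv")
    rtracklayer::export.gff3(do.call(c, unname(lapply(res$full_length$models,
                                                      model_granges))),
                             out("full_length.gff3"))
  }
  ape::write.tree(res$phylogeny$tree, out("tree.nwk"))
  tsv(res$phylogeny$assignments, "assignments.tsv")
  if (!is.null(res$expression)) {
    em <- res$expression$matrix
    tsv(data.frame(element_id = rownames(em$rpkm), em$rpkm,
                   check.names = FALSE), "rpkm.tsv")
    tsv(data.frame(element_id = rownames(em$rpkm), em$bins,
                   check.names = FALSE), "bins.tsv")
    if (!is.null(res$expression$pca))
      tsv(data.frame(sample = rownames(res$expression$pca$scores),
                     res$expression$pca$scores, check.names = FALSE),
          "pca_scores.tsv")
  }
  if (!is.null(res$divergence)) {
    hist_rows <- do.call(rbind, lapply(res$divergence$profiles, function(p)
      data.frame(clade = p$clade, bin_low = p$breaks[-length(p$breaks)],
                 bin_mid = p$mid, abundance = p$abundance,
                 stringsAsFactors = FALSE)))
    tsv(hist_rows, "divergence_hist.tsv")
    tsv(res$divergence$burst, "burst_ages.tsv")
  }
  jsonlite::write_json(res$summary, out("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(config$outdir)
}

# GRanges of a full-length model's features (1-based inclusive for GFF3).
model_granges <- function(m) {
  feats <- data.frame(kind = c("LTR5", "LTR3"),
                      start = c(m$ltr5_span[1], m$ltr3_span[1]),
                      end = c(m$ltr5_span[2], m$ltr3_span[2]),
                      stringsAsFactors = FALSE)
  if (!is.null(m$pbs))
    feats <- rbind(feats, data.frame(kind = "PBS", start = m$pbs$start,
                                     end = m$pbs$end))
  if (!is.null(m$ppt))
    feats <- rbind(feats, data.frame(kind = "PPT", start = m$ppt$start,
                                     end = m$ppt$end))
  if (nrow(m$orfs))
    feats <- rbind(feats, data.frame(kind = "ORF", start = m$orfs$start,
                                     end = m$orfs$end))
  GenomicRanges::GRanges(
    seqnames = m$element_id,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    type = feats$kind)
}
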