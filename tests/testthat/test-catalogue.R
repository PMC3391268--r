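test_that("redundant contigs collapse to the longest representative", {
  x <- rand_dna(500, 41)
  pool <- Biostrings::DNAStringSet(c(full = x, dup = x,
                                     sub = substr(x, 101, 400)))
  kept <- dedupe_contigs(pool)
  expect_length(kept, 1)
  expect_identical(as.character(kept[[1]]), x)

  a <- rand_dna(400, 42)
  b <- rand_dna(400, 43)
  kept2 <- dedupe_contigs(Biostrings::DNAStringSet(c(a = a, b = b)))
  expect_setequal(names(kept2), c("a", "b"))
  expect_length(dedupe_contigs(Biostrings::DNAStringSet()), 0)
})

test_that("dedupe matches an all-pairs containment oracle", {
  set.seed(44)
  base <- rand_dna(600, 44)
  seqs <- c(
    long1 = base,
    long2 = rand_dna(500, 45),
    frag1 = substr(base, 51, 450),              # contained in long1
    frag2 = substr(rand_dna(500, 45), 1, 460),  # contained in long2
    indep = rand_dna(350, 46))
  pool <- Biostrings::DNAStringSet(seqs)
  kept <- names(dedupe_contigs(pool))

  # oracle: quadratic check of the same containment rule, longest-first
  ord <- names(seqs)[order(-nchar(seqs), names(seqs))]
  surv <- character(0)
  for (id in ord) {
    contained <- FALSE
    for (s in surv) {
      a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[id]]), Biostrings::DNAString(seqs[[s]]),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
        gapOpening = 5, gapExtension = 2)
      alen <- Biostrings::nchar(a)
      idf <- Biostrings::nmatch(a) / alen
      cov <- alen / nchar(seqs[[id]])
      if (idf >= 0.95 && cov >= 0.90) { contained <- TRUE; break }
    }
    if (!contained) surv <- c(surv, id)
  }
  expect_setequal(kept, surv)
})

test_that("translated search finds exact reverse-translated homology", {
  panel <- retro_protein_panel()
  gypsy_pol <- as.character(panel[["gypsy_pol"]])
  rvt_part <- substr(gypsy_pol, 100, 330)
  codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  nt <- paste(codons[strsplit(rvt_part, "")[[1]]], collapse = "")
  # stop-codon flanks bound the in-frame segment to exactly the planted
  # peptide, so the hit cannot extend into chance flank similarity
  contig <- Biostrings::DNAStringSet(c(q = paste0(
    rand_dna(90, 51), "TAATAATAA", nt, "TAATAATAA", rand_dna(90, 52))))
  h <- translated_search(contig)
  expect_gt(nrow(h), 0)
  best <- h[which.max(h$score), ]
  expect_identical(best$superfamily_class, "gypsy")
  expect_equal(best$identity, 1.0)
  expect_gte(best$aligned_aa_len, nchar(rvt_part) - 2)
  # nt span consistency: ~3x the aligned amino acids
  expect_lt(abs((best$contig_end - best$contig_start) -
                  3 * best$aligned_aa_len), 9)

  # reverse-complement symmetry: same best hit on a negative frame
  contig_rc <- Biostrings::DNAStringSet(c(q = rc(as.character(contig[[1]]))))
  h2 <- translated_search(contig_rc)
  best2 <- h2[which.max(h2$score), ]
  expect_equal(best2$score, best$score)
  expect_lt(best2$frame, 0)

  # a random sequence produces nothing above stringency
  rnd <- Biostrings::DNAStringSet(c(r = rand_dna(1000, 53)))
  expect_identical(nrow(translated_search(rnd)), 0L)

  expect_error(
    translated_search(Biostrings::DNAStringSet(c(x = strrep("ACGR", 20)))),
    "non-IUPAC")
})

test_that("the stringent filters fire on the printed thresholds", {
  fam <- small_gypsy()$fam
  tpl <- small_gypsy()$tpl
  short_contig <- substr(tpl$sequence, 1, 250)
  # 150 aa of true homology only
  f <- tpl$features
  orf0 <- f[f$kind == "ORF", ]
  frag450 <- substr(tpl$sequence, orf0$start + 4, orf0$start + 3 + 450)
  contigs <- Biostrings::DNAStringSet(c(
    ok = as.character(fam$copies[[1]]),
    too_short = short_contig,
    weak = paste0(rand_dna(200, 61), frag450, rand_dna(200, 62))))
  hits <- translated_search(contigs)
  out <- apply_filters(contigs, hits)
  expect_true("ok" %in% names(out$retained))
  expect_false("too_short" %in% names(out$retained))
  expect_false("weak" %in% names(out$retained))
  expect_true(any(out$rejections$rule[out$rejections$contig_id == "too_short"]
                  == "min_length"))
  expect_true(any(out$rejections$rule[out$rejections$contig_id == "weak"]
                  == "weak_homology"))
})

test_that("transposase transcripts are classified DNA-TE and removed", {
  fam <- small_gypsy()$fam
  tx <- build_transcriptome(list(fam), n_host_genes = 1,
                            n_transposase_decoys = 1, seed = 71)
  hits <- translated_search(tx$transcripts)
  out <- apply_filters(tx$transcripts, hits)
  tp <- tx$truth$transcript_id[tx$truth$kind == "transposase"]
  expect_false(tp %in% names(out$retained))
  expect_true("dna_te" %in%
                out$rejections$rule[out$rejections$contig_id == tp])
})

test_that("an element embedded in a host transcript is caught by the host screen", {
  fam <- small_gypsy()$fam
  tx <- build_transcriptome(list(fam), n_host_genes = 0,
                            n_transposase_decoys = 0, n_embedded = 1,
                            seed = 72)
  hits <- translated_search(tx$transcripts)
  emb <- tx$truth$transcript_id[tx$truth$kind == "host_embedded"]
  # discovery still reports the element region inside the fusion transcript
  eh <- hits[hits$contig_id == emb & hits$superfamily_class == "gypsy", ]
  expect_gt(nrow(eh), 0)
  expect_gt(min(eh$contig_start),
            0.5 * tx$truth$elem_start[tx$truth$transcript_id == emb])
  out <- apply_filters(tx$transcripts, hits)
  expect_false(emb %in% names(out$retained))
  expect_true("non_te_homology" %in%
                out$rejections$rule[out$rejections$contig_id == emb])
})

test_that("filters are order-invariant over contig input order", {
  fam <- small_gypsy()$fam
  tx <- build_transcriptome(list(fam), n_host_genes = 2,
                            n_transposase_decoys = 1, seed = 73)
  hits <- translated_search(tx$transcripts)
  a <- apply_filters(tx$transcripts, hits)
  perm <- rev(seq_along(tx$transcripts))
  b <- apply_filters(tx$transcripts[perm], hits)
  expect_setequal(names(a$retained), names(b$retained))
})

test_that("the 80/80 rule groups and separates as stated", {
  x <- rand_dna(1000, 81)
  y <- mutate_at_rate(x, 0.15, 82)            # ~85% identity, full coverage
  one <- cluster_elements(Biostrings::DNAStringSet(c(a = x, b = y)))
  expect_length(one, 1)

  # ~85% identity but only half the shorter sequence covered
  z <- paste0(substr(y, 1, 500), rand_dna(500, 83))
  two <- cluster_elements(Biostrings::DNAStringSet(c(a = x, b = z)))
  expect_length(two, 2)

  same <- cluster_elements(Biostrings::DNAStringSet(c(a = x, b = x)))
  expect_length(same, 1)
})

test_that("clustering equals brute-force transitive closure of the predicate", {
  set.seed(85)
  seqs <- character(0)
  for (fi in 1:5) {
    base <- rand_dna(400, 850 + fi)
    for (ci in 1:5)
      seqs[sprintf("f%d_c%d", fi, ci)] <-
        mutate_at_rate(base, 0.05, 8500 + 10 * fi + ci)
  }
  for (ri in 1:5) seqs[sprintf("rnd_%d", ri)] <- rand_dna(400, 870 + ri)
  cand <- Biostrings::DNAStringSet(seqs)
  clusters <- cluster_elements(cand)
  got <- lapply(clusters, function(cl) sort(cl$member_contig_ids))

  # oracle: explicit transitive closure over the pairwise 80/80 predicate
  n <- length(seqs)
  adj <- matrix(FALSE, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(seqs[[j]]),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
      gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(a)
    idf <- if (alen) Biostrings::nmatch(a) / alen else 0
    cov <- BiocGenerics::width(a@pattern@range) / min(nchar(seqs[[i]]),
                                                      nchar(seqs[[j]]))
    adj[i, j] <- adj[j, i] <- (idf >= 0.80 && cov >= 0.80)
  }
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in 1:n) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  want <- unname(lapply(split(names(seqs), comp), sort))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
})

test_that("majority consensus follows the stated column rules", {
  # column {A,A,G} -> A
  s <- rand_dna(300, 91)
  v <- strsplit(s, "")[[1]]; v[50] <- "A"
  s1 <- paste(v, collapse = ""); v[50] <- "A"; s2 <- paste(v, collapse = "")
  v[50] <- "G"; s3 <- paste(v, collapse = "")
  cand <- Biostrings::DNAStringSet(c(m1 = s1, m2 = s2, m3 = s3))
  cl <- structure(list(element_id = "E1",
                       member_contig_ids = c("m1", "m2", "m3"),
                       representative = "m3", superfamily_class = NA,
                       consensus = NULL), class = "RetroelementCluster")
  cons <- consensus_build(cl, cand)$consensus
  expect_identical(substr(cons, 50, 50), "A")

  # tie {A,A,G,G} breaks toward the representative's base
  v[50] <- "A"; s4 <- paste(v, collapse = "")
  cand2 <- Biostrings::DNAStringSet(c(m1 = s1, m2 = s4, m3 = s3, m4 = s3))
  cl2 <- structure(list(element_id = "E2",
                        member_contig_ids = c("m1", "m2", "m3", "m4"),
                        representative = "m3", superfamily_class = NA,
                        consensus = NULL), class = "RetroelementCluster")
  expect_identical(substr(consensus_build(cl2, cand2)$consensus, 50, 50), "G")

  # single-coverage columns adopt their only base (longest member rules)
  long <- rand_dna(400, 92)
  short <- substr(long, 1, 200)
  cand3 <- Biostrings::DNAStringSet(c(lng = long, sht = short))
  cl3 <- structure(list(element_id = "E3",
                        member_contig_ids = c("lng", "sht"),
                        representative = "lng", superfamily_class = NA,
                        consensus = NULL), class = "RetroelementCluster")
  expect_identical(consensus_build(cl3, cand3)$consensus, long)
})

test_that("consensus recovers the template from diverged copies", {
  tpl <- small_gypsy()$tpl
  fam <- evolve_family(tpl, 10, 0.05, seed = 93)
  cand <- fam$copies
  cl <- structure(list(element_id = "E", member_contig_ids = names(cand),
                       representative = names(cand)[1],
                       superfamily_class = "gypsy", consensus = NULL),
                  class = "RetroelementCluster")
  cons <- consensus_build(cl, cand)$consensus
  same <- mean(strsplit(cons, "")[[1]] ==
                 strsplit(tpl$sequence, "")[[1]])
  expect_gte(same, 0.99)
})

test_that("planted families at modest divergence are recovered one-to-one", {
  families <- list(small_gypsy()$fam, small_rte()$fam,
                   evolve_family(make_nonltr_template("CR1", seed = 94),
                                 5, 0.08, seed = 95))
  tx <- build_transcriptome(families, n_host_genes = 2,
                            n_transposase_decoys = 1, seed = 96)
  hits <- translated_search(tx$transcripts)
  out <- apply_filters(tx$transcripts, hits)
  clusters <- cluster_elements(out$retained, out$classes)
  expect_length(clusters, 3)
  expect_setequal(cluster_template_map(clusters),
                  vapply(families, function(f) f$template$id, ""))
})
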