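test_that("LTR templates satisfy the structural invariants", {
  tpl <- small_gypsy()$tpl
  f <- tpl$features
  # terminal repeats identical at generation time
  ltr5 <- substr(tpl$sequence, f$start[f$kind == "LTR5"] + 1,
                 f$end[f$kind == "LTR5"])
  ltr3 <- substr(tpl$sequence, f$start[f$kind == "LTR3"] + 1,
                 f$end[f$kind == "LTR3"])
  expect_identical(ltr5, ltr3)
  # PBS within 30 nt downstream of the 5' LTR, complementary to the tRNA
  pbs <- f[f$kind == "PBS", ]
  expect_lte(pbs$start - f$end[f$kind == "LTR5"], 30)
  trna <- as.character(retro_trna_set()[["tRNA-Met"]])
  expect_identical(substr(tpl$sequence, pbs$start + 1, pbs$end),
                   rc(substr(trna, nchar(trna) - 17, nchar(trna))))
  # PPT within 30 nt upstream of the 3' LTR and >= 80% purines
  ppt <- f[f$kind == "PPT", ]
  expect_lte(f$start[f$kind == "LTR3"] - ppt$end, 30)
  ppt_seq <- substr(tpl$sequence, ppt$start + 1, ppt$end)
  expect_gte(mean(strsplit(ppt_seq, "")[[1]] %in% c("A", "G")), 0.8)
  # gypsy domain order
  doms <- f[f$kind == "domain", ]
  expect_identical(sub("domain=", "", doms$meta[order(doms$start)]),
                   c("PRO", "RVT", "RNH", "INT"))
})

test_that("templates are seeded deterministically and reject bad inputs", {
  a <- make_ltr_template("gypsy", 300, 4000, "tRNA-Met", seed = 1)
  b <- make_ltr_template("gypsy", 300, 4000, "tRNA-Met", seed = 1)
  expect_identical(a$sequence, b$sequence)
  expect_error(make_ltr_template("mariner", seed = 1), "superfamily")
  expect_error(make_ltr_template("gypsy", trna_id = "tRNA-Xyz", seed = 1),
               "tRNA")
  expect_error(make_nonltr_template("NotAClade", seed = 1), "clade")
})

test_that("generated structure round-trips through the annotator", {
  tpl <- small_gypsy()$tpl
  pbs <- detect_pbs(tpl)
  expect_identical(pbs$trna_id, tpl$trna_id)
  expect_identical(pbs$mismatches, 0L)
  expect_false(is.null(detect_ppt(tpl)))
  nl <- make_nonltr_template("Nimb", orf1 = TRUE, seed = 2)
  orfs <- find_orfs(nl$sequence, min_aa = 80)
  orf1_pep <- orfs$peptide[orfs$frame > 0][1]
  expect_gte(nrow(scan_cchc(orf1_pep)), 1)
  f3 <- detect_3prime_features(nl$sequence)
  expect_false(is.null(f3$polyA))
  expect_true(f3$at_rich_utr)
  # 3' UTR AT fraction is a generator constraint
  utr <- nl$features[nl$features$kind == "UTR3", ]
  utr_seq <- substr(nl$sequence, utr$start + 1, utr$end)
  expect_gte(mean(strsplit(utr_seq, "")[[1]] %in% c("A", "T")), 0.6)
})

test_that("single-ORF non-LTR clades carry a poly-A tail", {
  rte <- make_nonltr_template("RTE", orf1 = FALSE, seed = 3)
  orfs <- find_orfs(rte$sequence, min_aa = 200)
  expect_identical(sum(orfs$frame > 0), 1L)
  expect_false(is.null(detect_3prime_features(rte$sequence)$polyA))
  pa <- rte$features[rte$features$kind == "polyA", ]
  expect_gte(pa$end - pa$start, 15)
})

test_that("evolve_family realizes the requested divergence", {
  tpl <- small_rte()$tpl
  zero <- evolve_family(tpl, 3, 0, seed = 5)
  expect_true(all(as.character(zero$copies) == tpl$sequence))
  fam <- evolve_family(tpl, 200, 0.09, seed = 6)
  expect_lt(abs(mean(fam$truth$realized_divergence) - 0.09), 0.01)
  # per-copy realized divergence within 3 binomial standard errors
  L <- nchar(tpl$sequence)
  se3 <- 3 * sqrt(0.09 * 0.91 / L)
  expect_gt(mean(abs(fam$truth$realized_divergence - 0.09) <= se3), 0.99)
  expect_error(evolve_family(tpl, 2, 0.8, seed = 1), "saturation")
})

test_that("forced truncation removes the 5' end but keeps the poly-A tail", {
  tpl <- small_rte()$tpl
  fam <- evolve_family(tpl, 10, 0.01, truncate_prob = 1, seed = 7)
  expect_true(all(fam$truth$truncated_5prime))
  expect_true(all(fam$truth$trunc_len >= 0.1 * nchar(tpl$sequence)))
  for (s in as.character(fam$copies)) {
    expect_lt(nchar(s), nchar(tpl$sequence))
    expect_false(is.null(detect_3prime_features(s)$polyA))
  }
})

test_that("build_transcriptome maps every transcript in its truth table", {
  empty <- build_transcriptome(list(), n_host_genes = 5,
                               n_transposase_decoys = 0, seed = 1)
  expect_length(empty$transcripts, 5)
  expect_true(all(empty$truth$kind == "host"))
  expect_false(any(empty$truth$kind == "element"))

  fam <- small_gypsy()$fam
  tx <- build_transcriptome(list(fam), n_host_genes = 2,
                            n_transposase_decoys = 1, n_embedded = 1,
                            seed = 2)
  expect_identical(sort(names(tx$transcripts)),
                   sort(tx$truth$transcript_id))
  emb <- tx$truth[tx$truth$kind == "host_embedded", ]
  expect_identical(nrow(emb), 1L)
  expect_gt(emb$elem_start, 0)
})

test_that("read simulation is deterministic and honours the ambiguity dial", {
  fam <- small_gypsy()$fam
  tx <- build_transcriptome(list(fam), n_host_genes = 0,
                            n_transposase_decoys = 0, seed = 2)
  r1 <- simulate_reads(tx$transcripts, 1000, seed = 11)
  r2 <- simulate_reads(tx$transcripts, 1000, seed = 11)
  expect_identical(as.character(r1$read1), as.character(r2$read1))
  expect_identical(as.character(r1$read2), as.character(r2$read2))
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(tx, r1, dir = d1)
  write_simulation(tx, r2, dir = d2)
  expect_identical(readLines(file.path(d1, "reads_1.fastq")),
                   readLines(file.path(d2, "reads_1.fastq")))

  amb <- simulate_reads(tx$transcripts, 10000, ambig_frac = 0.10, seed = 12)
  reads <- c(amb$read1, amb$read2)
  w <- Biostrings::width(reads)
  nfrac <- 1 - rowSums(Biostrings::letterFrequency(reads, c("A", "C", "G", "T"))) / w
  expect_lt(abs(mean(nfrac > 1 / 3) - 0.10), 0.01)
})

test_that("junction-spanning pairs arise at 20x depth over a 300 nt LTR", {
  tpl <- make_ltr_template("gypsy", ltr_len = 300, internal_len = 4000,
                           seed = 21)
  tx <- Biostrings::DNAStringSet(setNames(tpl$sequence, "tx_elem"))
  depth <- 20
  n_reads <- ceiling(depth * nchar(tpl$sequence) / 75)
  rd <- simulate_reads(tx, n_reads, read_len = 75, paired = TRUE,
                       insert_mean = 250, seed = 22)
  j <- 300  # 5' LTR / internal junction (0-based)
  spanning <- with(rd$truth, frag_start + 75 <= j & frag_end - 75 >= j)
  expect_gt(sum(spanning), 0)
})

test_that("transcripts shorter than the insert are skipped with a warning", {
  tx <- Biostrings::DNAStringSet(c(short = rand_dna(120, 31),
                                   long = rand_dna(2000, 32)))
  expect_warning(rd <- simulate_reads(tx, 200, insert_mean = 250, seed = 13),
                 "shorter than the insert")
  expect_true(all(rd$truth$transcript_id == "long"))
})
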