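test_that("divergence scans count mismatches and honour the length cut", {
  cons <- rand_dna(2000, 601)
  r_exact <- substr(cons, 501, 575)
  sc <- scan_read_divergence(Biostrings::DNAStringSet(c(x = r_exact)), cons)
  expect_identical(nrow(sc), 1L)
  expect_identical(sc$divergence, 0)

  # 3 mismatches in a 75 nt alignment -> 0.04
  r3 <- substitute_n(r_exact, 3, 602)
  sc3 <- scan_read_divergence(Biostrings::DNAStringSet(c(x = r3)), cons)
  expect_equal(sc3$divergence, 0.04)
  expect_identical(sc3$mismatches, 3L)

  # alignment of exactly 70 nt is excluded (strictly longer than 70 required)
  r70 <- substr(cons, 501, 570)
  expect_identical(
    nrow(scan_read_divergence(Biostrings::DNAStringSet(c(x = r70)), cons)), 0L)
  r71 <- substr(cons, 501, 571)
  expect_identical(
    nrow(scan_read_divergence(Biostrings::DNAStringSet(c(x = r71)), cons)), 1L)

  # ambiguous bases shrink the alignment below the cut the same way
  v <- strsplit(r_exact, "")[[1]]; v[40:44] <- "N"       # 70 informative
  expect_identical(nrow(scan_read_divergence(
    Biostrings::DNAStringSet(c(x = paste(v, collapse = ""))), cons)), 0L)
  v4 <- strsplit(r_exact, "")[[1]]; v4[40:43] <- "N"     # 71 informative
  sc4 <- scan_read_divergence(
    Biostrings::DNAStringSet(c(x = paste(v4, collapse = ""))), cons)
  expect_identical(sc4$aln_len, 71L)
})

test_that("abundance normalization has the stated algebra and limits", {
  expect_identical(estimate_abundance(0, T_size = 1e6, N = 1e5, L = 3000), 0)
  a1 <- estimate_abundance(500, T_size = 1e6, N = 1e5, L = 3000)
  expect_equal(a1, 500 * 1e6 / (1e5 * (3000 + 75 - 140)))
  # monotone up in o and T, down in N and in placements (L)
  expect_gt(estimate_abundance(600, 1e6, N = 1e5, L = 3000), a1)
  expect_gt(estimate_abundance(500, 2e6, N = 1e5, L = 3000), a1)
  expect_lt(estimate_abundance(500, 1e6, N = 2e5, L = 3000), a1)
  expect_lt(estimate_abundance(500, 1e6, N = 1e5, L = 6000), a1)
  expect_error(estimate_abundance(5, 1e6, l = 60, N = 1e5, L = 3000, m = 70),
               "m must not exceed")
  expect_error(estimate_abundance(-1, 1e6, N = 1e5, L = 3000), "nonnegative")
})

test_that("a planted copy number is recovered within 15%", {
  tpl <- make_nonltr_template("RTE", orf1 = FALSE, seed = 611)
  n_copies <- 10
  fam <- evolve_family(tpl, n_copies, 0.02, seed = 612)
  tx <- build_transcriptome(list(fam), n_host_genes = 4,
                            n_transposase_decoys = 0, seed = 613)
  N <- 20000
  rd <- simulate_reads(tx$transcripts, N, insert_mean = 250, seed = 614)
  reads <- c(rd$read1, rd$read2)
  sc <- scan_read_divergence(reads, tpl$sequence)
  A <- estimate_abundance(nrow(sc),
                          T_size = sum(Biostrings::width(tx$transcripts)),
                          N = length(reads), L = nchar(tpl$sequence))
  # the paired-insert sampling slightly depletes fragment starts near ends;
  # recovery within 15% of the planted copy number
  expect_lt(abs(A - n_copies) / n_copies, 0.15)

  # doubling N at fixed composition leaves A unchanged in expectation
  rd2 <- simulate_reads(tx$transcripts, 2 * N, insert_mean = 250, seed = 615)
  reads2 <- c(rd2$read1, rd2$read2)
  sc2 <- scan_read_divergence(reads2, tpl$sequence)
  A2 <- estimate_abundance(nrow(sc2),
                           T_size = sum(Biostrings::width(tx$transcripts)),
                           N = length(reads2), L = nchar(tpl$sequence))
  expect_lt(abs(A2 - A) / A, 0.1)
})

test_that("divergence profiles locate peaks and conserve mass", {
  scans <- data.frame(read_id = paste0("r", 1:100), aln_len = 75,
                      mismatches = 7, divergence = rep(0.09, 100))
  pr <- divergence_profile(scans, rep("RTE", 100))
  expect_equal(pr$RTE$peak_divergence, 0.09)
  expect_identical(sum(pr$RTE$abundance > 0), 1L)

  # bimodal: global peak at the more abundant mode, both maxima present
  d2 <- c(rep(0.05, 120), rep(0.20, 80))
  pr2 <- divergence_profile(
    data.frame(read_id = seq_along(d2), aln_len = 75,
               mismatches = round(75 * d2), divergence = d2),
    rep("I", length(d2)))
  expect_equal(pr2$I$peak_divergence, 0.05)
  expect_identical(sum(pr2$I$abundance > 0), 2L)

  # mass conservation across bin refinement
  set.seed(621)
  d3 <- runif(500, 0, 0.3)
  mk <- function(bw) divergence_profile(
    data.frame(read_id = seq_along(d3), aln_len = 75,
               mismatches = round(75 * d3), divergence = d3),
    rep("X", length(d3)), bin_width = bw)$X
  expect_equal(sum(mk(0.01)$abundance), sum(mk(0.005)$abundance))
  expect_equal(sum(mk(0.01)$abundance), 500)

  # a narrow, recently-invading family occupies few bins
  d4 <- c(0.005, 0.01, 0.012, 0.02, 0.022)
  pr4 <- divergence_profile(
    data.frame(read_id = seq_along(d4), aln_len = 75,
               mismatches = round(75 * d4), divergence = d4),
    rep("Vingi", length(d4)))
  expect_lte(sum(pr4$Vingi$abundance > 0), 3)
})

test_that("family divergence parameter is recovered as the histogram peak", {
  tpl <- make_nonltr_template("RTE", orf1 = FALSE, seed = 631)
  fam <- evolve_family(tpl, 10, 0.09, seed = 632)
  tx <- build_transcriptome(list(fam), n_host_genes = 0,
                            n_transposase_decoys = 0, seed = 633)
  rd <- simulate_reads(tx$transcripts, 8000, insert_mean = 250, seed = 634)
  sc <- scan_read_divergence(c(rd$read1, rd$read2), tpl$sequence)
  pr <- divergence_profile(sc, rep("RTE", nrow(sc)))
  expect_lte(abs(pr$RTE$peak_divergence - 0.09), 0.01)
})

test_that("Jukes-Cantor dating matches the closed form and is monotone", {
  z <- jc_date(0)
  expect_identical(z$K, 0)
  expect_identical(z$age_years, 0)

  j <- jc_date(0.09, rate = 1.66e-8)
  expect_equal(j$K, 0.09587503, tolerance = 1e-6)
  expect_equal(j$age_years / 1e6, 2.888, tolerance = 1e-3)

  # single-lineage clock doubles the age
  expect_equal(jc_date(0.09, single_lineage = TRUE)$age_years,
               2 * j$age_years)

  p <- seq(0, 0.7, by = 0.01)
  K <- vapply(p, function(x) jc_date(x)$K, 0)
  expect_true(all(diff(K) > 0))
  expect_true(all(K[-1] >= p[-1]))
  expect_error(jc_date(0.75), "saturation")
  expect_error(jc_date(0.2, rate = 0), "positive")
})
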