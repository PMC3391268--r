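aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_pep <- function(n, seed) {
  set.seed(seed)
  paste(sample(aa20, n, TRUE), collapse = "")
}

mutate_pep <- function(x, p, seed) {
  set.seed(seed)
  v <- strsplit(x, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(aa20, v[i]), 1)
  paste(v, collapse = "")
}

test_that("Poisson distances follow the closed form and its invariances", {
  a <- rand_pep(100, 401)
  aln <- Biostrings::AAStringSet(c(x = a, y = a))
  d <- poisson_distance(aln)
  expect_identical(unname(d["x", "y"]), 0)

  # p = 0.1 -> d = -ln(0.9) = 0.10536
  b <- strsplit(a, "")[[1]]
  b[1:10] <- vapply(b[1:10], function(ch) setdiff(aa20, ch)[1], "")
  aln2 <- Biostrings::AAStringSet(c(x = a, y = paste(b, collapse = "")))
  d2 <- poisson_distance(aln2)
  expect_equal(unname(d2["x", "y"]), 0.1053605, tolerance = 1e-6)

  # duplicating every column leaves d unchanged
  dup <- Biostrings::AAStringSet(vapply(as.character(aln2), function(s) {
    v <- strsplit(s, "")[[1]]
    paste(rep(v, each = 2), collapse = "")
  }, ""))
  expect_equal(poisson_distance(dup)["x", "y"], d2["x", "y"])

  # saturation: all columns differ
  z <- vapply(strsplit(a, "")[[1]], function(ch) setdiff(aa20, ch)[1], "")
  expect_error(poisson_distance(Biostrings::AAStringSet(
    c(x = a, y = paste(z, collapse = "")))), "saturation")
  # monotone in p, and d >= p near 0 (multiple-hit inflation)
  p <- seq(0.05, 0.6, by = 0.05)
  dd <- -log(1 - p)
  expect_true(all(diff(dd) > 0))
  expect_true(all(dd >= p))
})

test_that("center-star alignment preserves its pairwise alignments", {
  base <- rand_pep(80, 402)
  seqs <- c(s1 = base,
            s2 = mutate_pep(base, 0.1, 403),
            s3 = mutate_pep(base, 0.15, 404),
            s4 = paste0(substr(mutate_pep(base, 0.1, 405), 6, 80)),  # 5' gap
            s5 = mutate_pep(base, 0.2, 406))
  aln <- center_star_align(seqs)
  expect_identical(length(unique(nchar(as.character(aln)))), 1L)
  # degapping restores every input
  for (nm in names(seqs))
    expect_identical(gsub("-", "", as.character(aln[[nm]])), seqs[[nm]])

  ident <- center_star_align(c(a = base, b = base, c = base))
  expect_false(any(grepl("-", as.character(ident))))

  one_sub <- center_star_align(c(a = base, b = mutate_pep(base, 0, 1),
                                 c = sub("^.", "W", base)))
  m <- do.call(rbind, strsplit(as.character(one_sub), ""))
  expect_identical(sum(apply(m, 2, function(col) length(unique(col)) > 1)), 1L)
})

test_that("NJ recovers additive trees exactly", {
  # 4-taxon additive matrix with known topology ((a,b),(c,d))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  el <- c(a = 2, b = 3, c = 4, d = 5)  # external edges; internal = 6
  d["a", "b"] <- d["b", "a"] <- el["a"] + el["b"]
  d["c", "d"] <- d["d", "c"] <- el["c"] + el["d"]
  for (x in c("a", "b")) for (y in c("c", "d"))
    d[x, y] <- d[y, x] <- el[x] + el[y] + 6
  tr <- nj_tree(d)$tree
  expect_identical(ape::Ntip(tr), 4L)
  # recovered path lengths reproduce the input distances (additivity)
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  want <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(want))), 0)

  # 3 taxa: the unique unrooted topology
  d3 <- d[1:3, 1:3]
  tr3 <- nj_tree(d3)$tree
  expect_identical(ape::Ntip(tr3), 3L)
  expect_identical(tr3$Nnode, 1L)
})

test_that("NJ equals brute-force least-squares search on 6-taxon additive matrices", {
  all6 <- phangorn::allTrees(6, rooted = FALSE, tip.label = letters[1:6])
  for (seed in c(411, 412, 413)) {
    set.seed(seed)
    gen <- ape::rtree(6, rooted = FALSE, tip.label = letters[1:6])
    gen$edge.length <- runif(nrow(gen$edge), 0.3, 1.5)
    d <- as.matrix(stats::cophenetic(gen))[letters[1:6], letters[1:6]]
    tr <- nj_tree(d)$tree
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(gen))), 0)
    # brute force: fit branch lengths to every topology, pick minimal RSS
    rss <- vapply(all6, function(tp) {
      f <- phangorn::nnls.tree(stats::as.dist(d), tp, method = "unrooted")
      sum((as.matrix(stats::cophenetic(f))[letters[1:6], letters[1:6]] - d)^2)
    }, 0)
    best <- all6[[which.min(rss)]]
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(best), ape::unroot(gen))), 0)
  }
})

test_that("clean two-clade structure earns high bootstrap support", {
  base1 <- rand_pep(120, 421)
  base2 <- mutate_pep(base1, 0.4, 422)
  seqs <- c(
    a1 = mutate_pep(base1, 0.05, 423), a2 = mutate_pep(base1, 0.05, 424),
    a3 = mutate_pep(base1, 0.05, 425),
    b1 = mutate_pep(base2, 0.05, 426), b2 = mutate_pep(base2, 0.05, 427),
    b3 = mutate_pep(base2, 0.05, 428))
  aln <- center_star_align(seqs)
  d <- poisson_distance(aln)
  res <- nj_tree(d, aln, bootstrap_reps = 100, seed = 429)
  pp <- ape::prop.part(res$tree)
  tips <- res$tree$tip.label
  grp <- vapply(pp, function(ix) {
    side <- sort(tips[ix])
    identical(side, c("a1", "a2", "a3")) || identical(side, c("b1", "b2", "b3"))
  }, TRUE)
  expect_true(any(grp))
  expect_gte(max(res$support[grp]), 0.95)
})

test_that("clade assignment follows the smallest enclosing split", {
  tr <- ape::read.tree(
    text = "((query1:0.05,REF_RTE:0.05):0.5,(REF_CR1:0.1,REF_L2:0.1):0.4,REF_I:0.6);")
  refs <- c(REF_RTE = "RTE", REF_CR1 = "CR1", REF_L2 = "L2", REF_I = "I")
  asn <- assign_clade(tr, refs)
  q <- asn[asn$element_id == "query1", ]
  expect_identical(q$clade, "RTE")
  expect_identical(q$nearest_reference_id, "REF_RTE")
  # references keep their own clade at full support
  expect_identical(asn$clade[asn$element_id == "REF_CR1"], "CR1")
  expect_identical(asn$support[asn$element_id == "REF_CR1"], 1)

  # a query whose smallest enclosing split mixes clades stays unassigned
  tr2 <- ape::read.tree(
    text = "((query2:0.1,(REF_CR1:0.1,REF_L2:0.1):0.1):0.5,REF_RTE:0.5,REF_I:0.6);")
  expect_message(asn2 <- assign_clade(tr2, refs), "mixed")
  expect_true(is.na(asn2$clade[asn2$element_id == "query2"]))

  expect_error(assign_clade(ape::read.tree(text = "((a,b),(c,d));"),
                            refs), "reference")
})

test_that("synthetic clades are recovered through the full RVT route", {
  els <- c(
    q_rte = make_nonltr_template("RTE", orf1 = FALSE, seed = 431)$sequence,
    q_jockey = make_nonltr_template("Jockey", orf1 = FALSE, seed = 432)$sequence,
    q_gypsy = make_ltr_template("gypsy", ltr_len = 150, internal_len = 2400,
                                seed = 433)$sequence)
  ar <- extract_and_align_rvt(els)
  d <- poisson_distance(ar$alignment, ar$gappy_cols)
  res <- nj_tree(d, ar$alignment, bootstrap_reps = 50, seed = 434)
  asn <- assign_clade(res, ar$ref_clades)
  expect_identical(asn$clade[asn$element_id == "q_rte"], "RTE")
  expect_identical(asn$clade[asn$element_id == "q_jockey"], "Jockey")
  expect_identical(asn$clade[asn$element_id == "q_gypsy"], "gypsy")

  # an element without an RVT domain is excluded with a warning
  expect_warning(
    ar2 <- extract_and_align_rvt(c(els, no_rvt = rand_dna(1200, 435))),
    "no recognisable RVT")
  expect_identical(ar2$excluded, "no_rvt")
})
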