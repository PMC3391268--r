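# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

mutate_at_rate <- function(x, p, seed) {
  set.seed(seed)
  v <- strsplit(x, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

substitute_n <- function(x, n, seed) {
  set.seed(seed)
  v <- strsplit(x, "")[[1]]
  pos <- sample(length(v), n)
  for (i in pos) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# A small gypsy template + family reused across tests.
small_gypsy <- function() fixture("small_gypsy", function() {
  tpl <- make_ltr_template("gypsy", ltr_len = 200, internal_len = 2400,
                           trna_id = "tRNA-Met", seed = 101)
  fam <- evolve_family(tpl, 5, 0.04, seed = 102)
  list(tpl = tpl, fam = fam)
})

small_rte <- function() fixture("small_rte", function() {
  tpl <- make_nonltr_template("RTE", orf1 = FALSE, seed = 103)
  fam <- evolve_family(tpl, 5, 0.05, seed = 104)
  list(tpl = tpl, fam = fam)
})

# The full benchmark study + pipeline report (the expensive fixture, used by
# the acceptance suite).
benchmark_run <- function() fixture("benchmark_run", function() {
  st <- simulate_study(seed = 20124, n_copies = 8, reads_per_sample = 20000)
  cfg <- retro_config(st$contigs, st$samples, bootstrap_reps = 100,
                      seed = 20124)
  rep <- run_full_analysis(cfg)
  list(st = st, rep = rep)
})

# Map each recovered cluster to the template its members came from.
cluster_template_map <- function(clusters) {
  vapply(clusters, function(cl) {
    tids <- unique(sub("_c[0-9]+$", "", sub("^tx_", "", cl$member_contig_ids)))
    if (length(tids) == 1) tids else paste(tids, collapse = "+")
  }, "")
}
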