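# Clade classification by reverse-transcriptase phylogeny: RVT extraction,
# center-star progressive multiple alignment, Poisson-corrected distances,
# neighbor-joining with bootstrap support, and clade assignment of queries
# relative to labelled references.

#' Extract RVT peptides and build a multiple alignment
#'
#' Locates the reverse-transcriptase domain in each element consensus (best
#' local alignment of any ORF peptide to the RVT reference), then aligns all
#' query RVT peptides together with the clade-labelled reference panel by
#' center-star progressive alignment (the center is the sequence with the
#' highest summed pairwise score; all others are merged into its
#' coordinates, once-a-gap-always-a-gap). Elements without a recognisable
#' RVT are excluded with a warning, mirroring the subset selection any
#' RVT-based phylogeny must make.
#'
#' @param elements named character vector / `DNAStringSet` of element
#'   consensus sequences.
#' @param refs clade-labelled RVT panel (default [rvt_reference_set()]).
#' @param min_orf_aa ORF size threshold used before domain location.
#' @param min_rvt_score minimum local-alignment score to accept an RVT call.
#' @return list with `alignment` (equal-width `AAStringSet`: queries then
#'   references), `excluded` (ids without RVT), `gappy_cols` (logical mask of
#'   columns with > 50% gaps, excluded from distances), `ref_clades` (named
#'   vector for [assign_clade()]).
#' @export
extract_and_align_rvt <- function(elements, refs = rvt_reference_set(),
                                  min_orf_aa = 150, min_rvt_score = 100) {
  if (is(elements, "DNAStringSet")) elements <- as.character(elements)
  rvt_ref <- retro_domain_refs()["RVT"]
  peps <- character(0)
  excluded <- character(0)
  for (id in names(elements)) {
    orfs <- find_orfs(elements[[id]], min_aa = min_orf_aa)
    best <- NULL
    if (nrow(orfs)) for (oi in seq_len(nrow(orfs))) {
      d <- locate_domains(orfs$peptide[oi], rvt_ref, min_score = min_rvt_score)
      if (nrow(d)) {
        d <- d[which.max(d$score), ]
        if (is.null(best) || d$score > best$score)
          best <- list(score = d$score,
                       pep = substr(orfs$peptide[oi], d$start_aa + 1, d$end_aa))
      }
    }
    if (is.null(best)) {
      excluded <- c(excluded, id)
      warning("element ", id, " has no recognisable RVT domain; excluded")
    } else peps[id] <- best$pep
  }
  all_peps <- c(peps, setNames(as.character(refs), names(refs)))
  if (length(all_peps) < 2)
    stop_config("need at least 2 RVT sequences to align")
  aln <- center_star_align(all_peps)
  m <- .aln_matrix(aln)
  gappy <- colMeans(m == "-") > 0.5
  list(alignment = aln, excluded = excluded, gappy_cols = gappy,
       ref_clades = setNames(S4Vectors::mcols(refs)$clade, names(refs)))
}

#' Center-star progressive multiple alignment
#'
#' Chooses the center sequence maximizing the summed pairwise global
#' alignment score, aligns every other sequence to it, and merges the
#' pairwise alignments into common coordinates (insertions relative to the
#' center open gap columns for everyone else).
#'
#' @param seqs named character vector of peptides.
#' @return `AAStringSet` of equal-width aligned sequences (input order).
#' @export
center_star_align <- function(seqs) {
  n <- length(seqs)
  if (n == 1) return(Biostrings::AAStringSet(seqs))
  ids <- names(seqs)
  scores <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sc <- align_aa(seqs[[i]], seqs[[j]], type = "global")$score
    scores[i, j] <- sc; scores[j, i] <- sc
  }
  center <- which.max(rowSums(scores))
  Lc <- nchar(seqs[[center]])
  alns <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == center) next
    alns[[i]] <- align_aa(seqs[[i]], seqs[[center]], type = "global")
  }
  # ins[k]: longest insertion (center gap run) before center position k
  ins <- integer(Lc + 1L)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == center) next
    cv <- strsplit(alns[[i]]$subject_aln, "")[[1]]
    r <- integer(Lc + 1L)
    pos <- 1L; run <- 0L
    for (ch in cv) {
      if (ch == "-") run <- run + 1L
      else { r[pos] <- run; run <- 0L; pos <- pos + 1L }
    }
    r[Lc + 1L] <- run
    runs[[i]] <- r
    ins <- pmax(ins, r)
  }
  width <- Lc + sum(ins)
  place <- function(i) {
    if (i == center) {
      out <- character(0)
      cs <- strsplit(seqs[[center]], "")[[1]]
      for (k in seq_len(Lc + 1L)) {
        out <- c(out, rep("-", ins[k]), if (k <= Lc) cs[k] else character(0))
      }
      return(paste(out, collapse = ""))
    }
    pv <- strsplit(alns[[i]]$pattern_aln, "")[[1]]
    cv <- strsplit(alns[[i]]$subject_aln, "")[[1]]
    out <- character(0)
    k <- 1L          # next center position
    buf <- character(0)
    flush <- function(buf, k) c(buf, rep("-", ins[k] - length(buf)))
    for (t in seq_along(cv)) {
      if (cv[t] == "-") buf <- c(buf, pv[t])
      else {
        out <- c(out, flush(buf, k), pv[t])
        buf <- character(0)
        k <- k + 1L
      }
    }
    out <- c(out, flush(buf, Lc + 1L))
    paste(out, collapse = "")
  }
  aligned <- vapply(seq_len(n), place, "")
  stopifnot(all(nchar(aligned) == width))
  Biostrings::AAStringSet(setNames(aligned, ids))
}

.aln_matrix <- function(aln) {
  if (is(aln, "AAStringSet") || is(aln, "DNAStringSet"))
    aln <- as.character(aln)
  do.call(rbind, strsplit(aln, ""))
}

#' Poisson-corrected distance matrix
#'
#' For each pair of aligned sequences, `p` is the mismatch fraction over
#' shared non-gap columns and the distance is `d = -ln(1 - p)`.
#'
#' @param alignment equal-width `AAStringSet` or character matrix.
#' @param exclude_cols optional logical mask of columns to drop (e.g. the
#'   `gappy_cols` of [extract_and_align_rvt()]).
#' @param min_cols minimum usable columns required.
#' @return symmetric distance matrix with zero diagonal.
#' @export
poisson_distance <- function(alignment, exclude_cols = NULL, min_cols = 20) {
  m <- .aln_matrix(alignment)
  if (!is.null(exclude_cols)) m <- m[, !exclude_cols, drop = FALSE]
  if (ncol(m) < min_cols)
    stop_config("alignment has fewer than ", min_cols, " usable columns")
  n <- nrow(m)
  if (n < 2) stop_config("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stop_config("sequences ", i, " and ", j,
                              " share no aligned columns")
    p <- mean(m[i, ok] != m[j, ok])
    if (p >= 1) stop_config("saturation: p >= 1 between sequences ",
                            i, " and ", j)
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

# Distance for bootstrap replicates: saturated pairs are capped, not fatal.
.poisson_capped <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    p <- if (any(ok)) min(mean(m[i, ok] != m[j, ok]), 0.999) else 0.999
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`); when an alignment and
#' `bootstrap_reps > 0` are supplied, alignment columns are resampled with
#' replacement, trees recomputed, and per-split support fractions attached
#' as node labels (splits below 0.5 are retained, following the convention
#' of not displaying rather than discarding them).
#'
#' @param d distance matrix from [poisson_distance()].
#' @param alignment optional aligned sequences (required for bootstrap).
#' @param bootstrap_reps number of bootstrap replicates (0 = none).
#' @param seed RNG seed for resampling (required when bootstrapping).
#' @param exclude_cols optional column mask, as in [poisson_distance()].
#' @return list with `tree` (an `ape::phylo`; node labels are support
#'   fractions when bootstrapped) and `support` (numeric vector or `NULL`).
#' @export
nj_tree <- function(d, alignment = NULL, bootstrap_reps = 0, seed = NULL,
                    exclude_cols = NULL) {
  if (nrow(d) < 3) stop_config("neighbor-joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(d))
  support <- NULL
  if (bootstrap_reps > 0) {
    if (is.null(alignment))
      stop_config("bootstrap requires the alignment")
    if (is.null(seed))
      stop_config("bootstrap requires a seed")
    m <- .aln_matrix(alignment)
    if (!is.null(exclude_cols)) m <- m[, !exclude_cols, drop = FALSE]
    m <- m[tree$tip.label, , drop = FALSE]
    cnt <- with_seed(seed, ape::boot.phylo(
      tree, m, function(x) ape::nj(stats::as.dist(.poisson_capped(x))),
      B = bootstrap_reps, rooted = FALSE, quiet = TRUE))
    support <- cnt / bootstrap_reps
    tree$node.label <- format(round(support, 3))
  }
  list(tree = tree, support = support)
}

#' Assign queries to clades from a reference-labelled tree
#'
#' Every query tip receives the clade of the reference set with which it
#' forms the smallest enclosing split: among all bipartitions of the tree,
#' the smallest side containing the query and at least one reference is
#' found; if its references are all of one clade, that clade is assigned
#' (with the split's bootstrap support), otherwise the query is left
#' unassigned (logged). A reference queried against itself keeps its own
#' clade with support 1.
#'
#' @param tree_result result of [nj_tree()] (or a bare `phylo`).
#' @param ref_clades named character vector mapping reference tip labels to
#'   clades.
#' @return data.frame with `element_id`, `clade` (`NA` when unassigned),
#'   `support`, `nearest_reference_id`.
#' @export
assign_clade <- function(tree_result, ref_clades) {
  tree <- if (is.list(tree_result) && !is.null(tree_result$tree))
    tree_result$tree else tree_result
  support <- if (is.list(tree_result) && !is.null(tree_result$support))
    tree_result$support else NULL
  tips <- tree$tip.label
  refs <- intersect(tips, names(ref_clades))
  if (!length(refs)) stop_config("tree contains no labelled reference")
  queries <- setdiff(tips, refs)
  pp <- ape::prop.part(tree)
  clades_sets <- lapply(pp, function(ix) tips[ix])
  coph <- stats::cophenetic(tree)
  rows <- list()
  all_ids <- tips[order(match(tips, tips))]
  for (q in tips) {
    if (q %in% refs) {
      rows[[length(rows) + 1L]] <- data.frame(
        element_id = q, clade = unname(ref_clades[q]), support = 1,
        nearest_reference_id = q, stringsAsFactors = FALSE)
      next
    }
    best <- NULL
    for (k in seq_along(clades_sets)) {
      for (side in list(clades_sets[[k]], setdiff(tips, clades_sets[[k]]))) {
        if (!(q %in% side)) next
        side_refs <- intersect(side, refs)
        if (!length(side_refs)) next
        sup <- if (!is.null(support) && k <= length(support)) support[k] else NA
        if (is.null(best) || length(side) < length(best$side))
          best <- list(side = side, refs = side_refs, support = sup)
      }
    }
    cl <- NA_character_
    sup <- NA_real_
    if (!is.null(best)) {
      ref_cl <- unique(unname(ref_clades[best$refs]))
      if (length(ref_cl) == 1) {
        cl <- ref_cl
        sup <- best$support
      } else {
        message("query ", q, " is enclosed with mixed clades (",
                paste(ref_cl, collapse = ","), "); unassigned")
      }
    }
    nearest <- refs[which.min(coph[q, refs])]
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = q, clade = cl, support = sup,
      nearest_reference_id = nearest, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
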