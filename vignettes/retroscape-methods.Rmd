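---
title: "Methods: transcriptome-based retroelement discovery, reconstruction and dating"
author: "retroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-based retroelement discovery, reconstruction and dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`retroscape` implements a transcriptome-only workflow for retroelements in
species without a reference genome, of the kind applied to the migratory
locust: starting from de novo assembled contigs and short paired-end reads,
it (1) identifies retroelement transcripts by translated homology to a
retrotransposon protein panel under stringent filters, (2) groups transcripts
into *elements* with the 80/80 rule and builds per-element majority
consensuses, (3) reconstructs full-length LTR retroelements whose
near-identical terminal repeats defeat short-read assemblers, (4) annotates
structural hallmarks (LTR pairs, PBS, PPT, ORFs, domain order, CCHC zinc
fingers, poly-A tails), (5) classifies elements into clades by
neighbor-joining on Poisson-corrected reverse-transcriptase (RVT) distances,
(6) quantifies expression in RPKM, and (7) builds read-versus-consensus
divergence landscapes dated under the Jukes-Cantor model.

The term *element* rather than *family* is deliberate: a consensus
reconstructed from transcriptome data aggregates transcribed copies from
unknown genomic loci, not a curated genomic family.

# Discovery and the stringent filters

Contigs are translated in six frames; stop-free peptide segments are locally
aligned (BLOSUM62, affine gaps) against a panel of retrotransposon
polyproteins labelled by class (gypsy, copia, BEL, DIRS, non-LTR, plus a DDE
transposase used as a DNA-transposon sentinel). A candidate must

* be at least 300 bp long,
* carry retroelement homology of at least 200 aligned amino acids at 30%
  identity or better,
* not be better explained as a DNA transposase,
* and have no non-retroelement ORF of 300+ bp matching the host-protein
  panel (the screen that removes co-transcribed host genes and host/element
  fusion transcripts).

Two implementation choices matter. First, the 200-amino-acid rule is
evaluated on *merged homology regions*: hits to the same panel protein in
the same frame, separated by stop codons or gaps up to 150 nt, are chained
and the union span counts. Diverged copies of an active element accumulate
premature stops (~5% of amino-acid changes hit a stop), so a per-segment
rule would systematically discard exactly the divergent copies the method
is meant to catalogue; protein-based repeat masking likewise reports whole
masked regions, not stop-free fragments. Second, an identity-plus-length
stringency replaces an E-value cutoff: calibrating Karlin–Altschul
statistics for a bespoke aligner adds nothing at this scale because the
length rule dominates.

The 80/80 rule (same element ⇔ ≥80% identity over ≥80% of the shorter
sequence, local alignment) is applied by single-linkage after a canonical
sort, so clustering is order-independent; a brute-force transitive closure
over the same pairwise predicate is the test oracle. For speed, pairs are
first screened on shared 14-mers and an ungapped identity estimate along
the best seed diagonal; only ambiguous pairs (ungapped identity between
0.60 and the threshold) pay for full dynamic programming. Consensus bases
are per-column majorities over members aligned to the longest member, with
single-coverage columns adopting their only base; ties break toward the
representative and then alphabetically, which keeps consensus building
deterministic.

# Full-length LTR reconstruction

An intact LTR retroelement carries two near-identical terminal repeats.
Short-read assemblers therefore either collapse both repeats into one
contig (separating the internal region) or stitch the element in the wrong
orientation. Two signatures recover these cases:

* **self-repeat**: the terminal windows of a sequence align to each other
  at ≥85% identity over ≥80 nt. The repeat offset gives the LTR length
  directly, so the two LTR spans are anchored to the sequence termini and
  their global-alignment identity is the element's LTR pair identity.
* **ltr-pair**: a short contig aligns to both termini of a domain-bearing
  contig. Read pairs with one mate in the LTR contig and the other within
  insert range of an internal terminus support each junction; with at least
  3 supporting pairs per junction (insert tolerance ±3 SD) one LTR copy is
  placed at each end, merging terminal overlaps.

Validation requires at least one ORF of 200+ amino acids and LTR pair
identity ≥85%; if domain evidence sits on the reverse strand the internal
region is reverse-complemented first (an involution, so applying it twice
is the identity). The 85% floor reflects that the approach targets young,
recently active elements — ancient elements flanked by divergent LTRs are a
stated non-goal. PBS calls require a reverse-complement match of ≥12 nt
(≤1 mismatch) between the 30 nt downstream of the 5' LTR and the 3'-terminal
18 nt of a tRNA; PPT calls require a ≥10 nt run of ≥80% purines within
30 nt upstream of the 3' LTR. Both window sizes are conventions of LTR
annotation practice, configurable, and absence of a PPT is reported as a
finding, not an error.

The CCHC zinc-finger pattern is `C-X(2)-C-X(3,4)-H-X(3,6)-C`. The spacer
ranges are deliberately wide enough to jointly accommodate the three
canonical gag-knuckle variants (X4–H–X4, X4–H–X3, X3–H–X6); narrower
published shorthand for the middle variant is inconsistent with its own
sequence, so the scanner matches sequences, not shorthand.

# RVT phylogeny and clade assignment

The RVT domain is located in each consensus by local alignment against the
RVT reference; queries and the clade-labelled reference panel are aligned by
center-star progressive alignment (the center maximizes summed pairwise
global scores; merging is once-a-gap-always-a-gap). Center-star is a
deliberate replacement for a general progressive aligner: RVT peptides are
globally alignable with few gaps, and the construction guarantees that each
sequence's pairwise alignment to the center is preserved in the MSA, which
the tests verify directly. Columns with >50% gaps are excluded from
distances.

Distances are Poisson-corrected, d = −ln(1 − p) with p the mismatch
fraction over shared non-gap columns; trees are Saitou–Nei neighbor-joining
with support from bootstrap resampling of alignment columns (default 1,000
replicates in the CLI; 100 in the benchmark suite, which the two-clade
support test shows is ample at desk scale; the seed is mandatory).
A query's clade is the clade of the smallest bipartition side containing
the query and at least one reference, provided those references are pure;
mixed smallest splits leave the query unassigned. This is an explicit
formalization of what is usually done by visual tree inspection.

# Expression and divergence dating

Reads with more than one third ambiguous bases (strictly greater, so
exactly 1/3 is retained) or shorter than 30 nt are removed. The mapper is
exact-seed-and-extend: 12-mer seeds at fixed offsets locate candidate
placements on both strands, each scored by ungapped full-read mismatch
count. The seed length differs deliberately from the BWA-era default of a
long exact seed: a single exact 20-mer misses roughly 40% of 75 nt reads
drawn from copies at 9% divergence — exactly the divergent families a
repeat-expression method must quantify — while 12-mers at three offsets
miss under 5%. For expression the mismatch ceiling is derived from the
80/80 family definition: members can sit ~10% from their consensus, so the
pipeline allows ceil(0.15 × read length) mismatches; reads tied between
elements split fractionally (transcriptional activity aggregates copies
from many loci, so fractional assignment matches that aggregate reading; a
seeded best-random policy is available). RPKM is
count / (kb × mapped millions), with bins at the conventional edges
(<0.5 below; 0.5–10 low; 10–50 moderate; ≥50 high), lower edge inclusive
since the printed ranges do not state closure. PCA runs on
log2(RPKM + 1)-transformed, centered samples; whether to log-transform
before PCA is not standardized, and log2(x+1) is the default here because
repeat expression spans orders of magnitude.

For divergence landscapes, reads (not assembled transcripts) are aligned
to consensuses and alignments of ≤70 nt informative positions are
discarded (strictly-longer rule; ambiguous bases are excluded from both
numerator and denominator). Seeds are tiled every 6 nt here: divergence
estimation is exquisitely sensitive to seeding bias, because requiring a
clean seed at few offsets preferentially drops high-mismatch reads and
shifts the landscape peak downward by a bin. Per-clade histograms use
1%-wide bins centered on whole percents and abundance weights
`A = o·T / (N·(L + l − 2m))` — the observed alignment count normalized by
the number of read placements that can produce a qualifying alignment
(T transcriptome size, l read length, N total reads, L element length,
m = 70 the minimal alignment length). This is the expectation-normalized
form implied by that variable list, and under uniform sampling it
estimates the effective transcribed copy number, which the
planted-copy-number test verifies within 15%.

The burst date converts the peak divergence P through the one-parameter
Jukes-Cantor correction K = −(3/4)ln(1 − 4P/3) and an insect nuclear
pseudogene rate μ = 1.66×10⁻⁸ substitutions/site/year. The divisor is 2μ:
a copy and the consensus ancestor diverge along two lineages, and this
convention yields 2.89 Myr at P = 0.09, consistent with the ~2.8 Myr scale
such bursts are reported at; K/μ (5.8 Myr) is inconsistent with that
reading and is available only behind the `single_lineage` flag.

# The synthetic-data generator

All reference sets are synthetic stand-ins constructed deterministically in
code: domain peptides carrying the family-diagnostic motifs (DTG; LPQG and
YXDD; the DDE transposase triad context), a 12-tRNA set with distinct
3'-terminal 18-mers, and per-clade RVT variants derived from the base RVT
by fixed substitutions at ~30% of sites. Non-RVT domains (APE, RNH, PRO,
INT) are likewise varied per clade at ~25% — distinct lineages carry
diverged domain copies, and sharing identical domain sequence across
templates would create artificial cross-family multi-mapping that real
clades do not show. Domain stand-ins are sized so a non-LTR ORF2 reaches
~460 amino acids of alignable homology, comfortably clearing the 200-aa
filter even at 9% nucleotide divergence.

Templates obey the structural rules the annotator tests (the round-trip is
itself a test suite invariant). Copy families substitute each site
independently with probability P, uniformly among the three alternatives —
the same one-parameter model the dating assumes, which keeps P directly
interpretable; there are no indels by default. Non-LTR copies may be
5'-truncated, uniform over 10–80% of the element length, emulating the
abortive reverse transcription that truncates most new LINE copies. Reads
are uniform-start, forward-reverse pairs with Gaussian insert sizes and an
optional dial that makes a chosen fraction of reads ambiguous; no attempt
is made to model platform error profiles, quality realism or GC bias.

The benchmark study (`simulate_study()`) fixes the conditions used
throughout validation: three LTR families — gypsy with PBS = tRNA-Met, a
PPT and 3% LTR divergence; BEL with the PPT deleted and identical LTRs;
copia at 6% LTR divergence — and four non-LTR families (CCHC-bearing
Nimb-like, RTE-like at 9% copy divergence representing the proliferation
burst, CR1-like, Daphne-like), eight copies each, with host-gene and
transposase decoys, 75 nt pairs (insert 250 ± 25) and three samples whose
expression weights are log-spread across elements with an elevated egg
stage. Eight copies and 20,000 reads per sample give roughly 20× coverage
of the planted elements — enough that every recovery property is stable
under reseeding while the whole suite stays desk-sized.

# What passing tests do and do not show

The generator's families are substitution-only, with clean structural
signals and well-separated clades; real transcriptomes add indels, chimeric
assembly, nested insertions, segmental low-complexity and clades at every
divergence. Passing recovery tests therefore demonstrates that the
algorithms implement their stated rules and are internally consistent at
realistic signal strengths — not that the pipeline's thresholds are optimal
for any particular real dataset. Known limitations, beyond those already
flagged: ancient LTR elements with divergent repeats are out of scope by
design; the abundance normalization assumes uniform read sampling along
transcripts; consensus quality degrades when fewer than ~4 copies of a
family survive the filters, and single-coverage consensus segments then
reproduce individual copies rather than the ancestral state.

# Numerical conventions

All internal coordinates are 0-based half-open; GFF3 output converts to
1-based inclusive. Nucleotide alignments score match 2 / mismatch −3, gap
open 5 / extend 2; peptide alignments use BLOSUM62 with gap open 10 /
extend 0.5. Degenerate inputs fail loudly: divergence P ≥ 0.75 and pairwise
amino-acid p ≥ 1 are saturation errors (bootstrap replicates cap p instead,
so a single saturated resample cannot abort a tree), empty contig sets and
zero library sizes are configuration errors. Every stochastic stage takes
an explicit seed, and a pipeline rerun under the same configuration is
bit-identical.
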