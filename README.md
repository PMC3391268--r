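# retroscape

Transcriptome-based discovery, reconstruction, classification, expression
profiling and burst dating of retroelements — for species **without a
reference genome**, where assembled RNA-seq contigs and short paired-end
reads are the only evidence. The workflow follows the strategy used for
large-genome insects such as the migratory locust, whose transcriptomes are
rich in LTR retrotransposons (gypsy, BEL, copia) and non-LTR
retrotransposons (LINEs of the RTE, CR1, Jockey, Nimb, Daphne and related
clades).

## What it does

1. **Catalogue** — contigs are translated in six frames and searched
   against a retrotransposon protein panel. Stringent filters retain
   candidates ≥300 bp with ≥200 aa of retroelement homology (≥30%
   identity), remove DNA transposons (transposase homology) and
   host-gene/fusion transcripts (non-retroelement ORFs ≥300 bp matching a
   host-protein panel). Transcripts sharing ≥80% identity over ≥80% of the
   shorter sequence (the 80/80 rule) are single-linkage clustered into
   *elements*, each summarized by a per-column majority consensus.
2. **Full-length LTR reconstruction** — the two near-identical terminal
   repeats of an intact LTR element defeat short-read assemblers
   (collapsed or misoriented contigs). Terminal self-repeats and
   LTR/internal contig pairs are detected, paired-end reads scaffold the
   junctions (≥3 supporting pairs each), domain order
   (gypsy: PRO–RVT–RNH–INT) corrects the orientation, and models are
   validated by an ORF ≥200 aa and an LTR pair identity ≥85%.
3. **Structural annotation** — ORFs, protein domains (PRO, RVT, RNH, INT,
   APE), primer binding sites (reverse complement of a tRNA 3' end, ≥12 nt,
   ≤1 mismatch, within 30 nt of the 5' LTR), polypurine tracts (≥10 nt,
   ≥80% purines, within 30 nt of the 3' LTR), CCHC zinc fingers
   (`C-X2-C-X(3,4)-H-X(3,6)-C`), poly-A tails and AT-rich 3' UTRs.
4. **Clade classification** — reverse-transcriptase (RVT) peptides are
   center-star aligned with a clade-labelled reference panel; distances are
   Poisson-corrected (d = −ln(1 − p)); neighbor-joining trees carry
   bootstrap support; each element receives the clade of its smallest
   enclosing reference split.
5. **Expression** — QC (reads with >1/3 ambiguous bases removed),
   seed-and-extend mapping to element consensuses, RPKM =
   count / (kb × mapped millions), bins at 0.5 / 10 / 50 RPKM, and PCA of
   log2(RPKM+1) sample profiles.
6. **Divergence landscape and dating** — reads are compared with their
   element consensus (alignments >70 nt only); per-clade histograms weight
   1%-divergence bins by the abundance `A = o·T / (N·(L + l − 2m))`; the
   peak divergence P dates the proliferation burst via the Jukes–Cantor
   correction K = −(3/4)ln(1 − 4P/3) and age = K/(2μ) with
   μ = 1.66×10⁻⁸ substitutions/site/year.

A synthetic-data generator (`make_ltr_template()`, `make_nonltr_template()`,
`evolve_family()`, `build_transcriptome()`, `simulate_reads()`,
`simulate_study()`) produces templates, diverged copy families, decoys and
paired reads with complete ground truth, so every stage is testable without
external databases. All bundled reference sets (tRNAs, domain peptides,
protein panel, clade RVT panel) are synthetic stand-ins constructed in code.

## Worked example

```r
library(retroscape)

st  <- simulate_study(seed = 1)            # 7 planted families + decoys
cfg <- retro_config(st$contigs, st$samples, bootstrap_reps = 100, seed = 1)
rep <- run_full_analysis(cfg)

rep
#> <retro_report: 62 contigs -> 52 retained -> 7 elements; 3 full-length LTR model(s)>

rep$full_length$table
#>   element_id length ltr_len ltr_identity pbs_trna   ppt    domain_order
#> 1      RE001   4600     300          100 tRNA-Ser FALSE PRO-RVT-RNH-INT
#> 2      RE002   4600     300           94 tRNA-Val  TRUE PRO-INT-RVT-RNH
#> 3      RE003   4600     300           97 tRNA-Met  TRUE PRO-RVT-RNH-INT

head(rep$phylogeny$assignments, 3)
#>   element_id clade support nearest_reference_id
#> 1      RE001   BEL       1              REF_BEL
#> 2      RE002 copia       1            REF_copia
#> 3      RE003 gypsy       1            REF_gypsy

rep$divergence$burst[rep$divergence$burst$clade == "RTE", ]
#>   clade peak_divergence burst_age_years total_abundance
#> 2   RTE            0.08         2548091        13.25
```

Reading the output: the three reconstructed full-length LTR models report
the identity of their terminal repeat pair — 100% for the element planted
with identical LTRs (whose PPT deletion is also reported: `ppt = FALSE`),
94% and 97% for the elements planted at 6% and 3% LTR divergence — and the
tRNA priming each element's PBS. Every element lands in its planted clade
with full bootstrap support. The RTE-like family was planted at 9% copy
divergence; its recovered peak (8%, within one histogram bin) dates the
burst at ~2.5–2.9 Myr under the Jukes–Cantor clock. For reference,
`jc_date(0.09)$age_years/1e6` is 2.89 Myr.

`run_full_analysis()` with `outdir=` writes `elements.fasta`,
`clusters.tsv`, `rejections.tsv`, `full_length.fasta/.gff3`, `tree.nwk`,
`assignments.tsv`, `rpkm.tsv`, `bins.tsv`, `divergence_hist.tsv`,
`burst_ages.tsv` and a JSON summary. A thin command-line wrapper lives at
`inst/scripts/retroscape.R` (`simulate`, `run`, `refs` subcommands).

## Method notes

See the methods vignette (`vignettes/retroscape-methods.Rmd`) for the model
assumptions, parameter defaults with their rationale, numerical
conventions, what the synthetic generator does and does not emulate, and
known limitations (ancient LTR elements with divergent repeats are out of
scope by design).
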