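Package: retroscape
Title: Transcriptome-Based Discovery, Reconstruction and Dating of
    Retroelements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies retroelement transcripts in de novo transcriptome
    assemblies by translated homology to retrotransposon protein panels,
    groups them into elements under the 80/80 rule with majority-vote
    consensus building, reconstructs full-length LTR retroelements whose
    near-identical terminal repeats confuse short-read assemblers,
    annotates structural hallmarks (LTR pairs, PBS, PPT, ORFs, protein
    domain order, CCHC zinc fingers, poly-A tails), classifies elements
    into clades by neighbor-joining on Poisson-corrected reverse
    transcriptase distances, profiles expression in RPKM across
    developmental samples, and dates proliferation bursts from
    read-versus-consensus divergence landscapes under the Jukes-Cantor
    model. Ships a synthetic-data generator that emulates LTR and non-LTR
    retroelement families with full ground truth, so the entire pipeline
    is testable without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
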