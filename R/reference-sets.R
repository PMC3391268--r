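# Bundled synthetic reference sets.
#
# All reference sequences shipped with the package are synthetic stand-ins
# constructed once with a fixed random stream: short domain peptides carrying
# the canonical catalytic motifs of their families (DTG for the aspartic
# protease, LPQG/YXDD for reverse transcriptase, the DDE signature for
# integrase/transposase), a tRNA set with distinct 3' acceptor ends, and a
# clade-labelled reverse-transcriptase panel derived from the base RVT peptide
# by fixed per-clade substitutions. They emulate the role of Repbase protein
# classes, Pfam domain models and insect tRNA collections at desk scale; they
# are not database entries.

.PEP <- list(
  PRO = "RKLAIASPFFETGGFFPTKGRIANVSSESLSGEIELRKNLLDTGADKSLITFGHTNKPDTVDMEVLALRKFVLRLAEDPTVSVNILGPER",
  RVT = "RCVGICGGKGSAQALGEGPCIILCASTALTIKNSEICGRANELARIHAFSVAFNKPFRALPQGFVTGSMIYGSRSPRSEYLKGMTDCRLRYADISNNGSYVDDILVRAKIYEFLAPKVKYSLTNFSTVENWLTLIISGNKEKGLLTDGAACKGPCESNIKEVDKLYISRPTKQIGVIFPIYGNQSAIEHVACLGQTKLICDSQMDEGELISFKNIAGKTTDLQMIIEPDLNRDCAPIVEWVLPTTEHQVP",
  RNH = "VAQAEVVARAAKIEQQYERILRTLVAHLRSTNMVSGCEQAIRALGGLVGDASQLGIQDIWQFYDEVASMGIVVLDVVIGFCLAARLFSRNPEYKNYLTHPELMGRLNDQV",
  INT = "AKDVAEANKYLVVDVYLQTTSTVGTAGYPHTHCGQTSGSSGVGLIVLVERVARTSSYEKRDNSAENQTVRLAHVPESKHDSGSESARVDGMHNSINKKLIKADSEINLANGWQARFEREY",
  APE = "AQIEKDAVALGGLDSEFMVSPMVAFFKLPLDSFPHQNKKGDMQSNVNGLNSAEIFVVQRVANSGVLSEAGGHAVMRTLALKQIKGAWVKCKEASCVLPTSLNAIKRKPMIMTKFQTQHTPAEPREARQAPSAALNQLDLLDTVYSTKMAMMRGDERGGANYLNFGKVDQDVGMPLRAIIGEEGAVGLSWFVGLKEIYDLK",
  TPASE = "EDLLGISDEEEQRHIAQNLGTRVPKTFPPLRETGQQPQHEVGTGHAVGDPKPLSDDLSEGGAVSFYYSVDDERGWLTNRTRDFRVVQIAETGQAAQSDLGLRSCIKVRKEAVSRLMQAWGPGLFIETDNGTSTATHVKGLGTDALLECRQ",
  HOST1 = "SLYHLKTPTRDTLVVGKTRVTNKKTCVARCGKVPDSQSEFDSHHLESEMSQSGTCVDARWSGVLNLPSTLLCDRSQDHDVLLHSNSDSQEINLEMEAMMLETLGIDQQMLLIEHNLISGSVVTNMLEGMESVLLVAGSNAVIEMESNGEALIYRHVRPLS",
  HOST2 = "LVVVDTWVRPPIADMLLAESGLAVDFPARSFLGGALIQISKQTVGAAQQDSGSAYPLQVSHGEVTLDKEDIIKVRIVQHIRLIRLIGPTMIISQYIMCVAYTQSVVGDAILRPQKQETHNESRSNLIAKQSRFAAAPPSRGQRSLSIPAS",
  HOST3 = "WPKWGLRRLDTNPIRQSFIIQVLCLNAEKVGGESPIVDINVVPKVPLLVTIEIGTNRGIATSTSRGNETKALDILDRAEAKVAVVDLDDVARPFIENVSVYDANYREAIFSYFNGIGTESYIEREICLVAIQWIFRASFEVRPAELERFEAMDDEPDVSERDRQAFGYNG"
)

.TRNAS <- c(
  "tRNA-Ser" = "TAAAGCTCTCTGTTGTGTGGTTCTCCGGGCATGACTATTGGCCCACGATTCGACACCCTAACAGCTCCA",
  "tRNA-Met" = "TATCCCGAATCTATGATTGTCCGGTTTGCAGAGCCTCTCGCTCAAGAACTTAAACCGGTTGATCGACCA",
  "tRNA-Val" = "TGCGACAACCGGATGGGTACCAGGTAAGATTCACCATGGTGTGCCGGCCTGAGTTTAGTACATTGGCCA",
  "tRNA-Leu" = "ATGGACCGCATATCGCCACTTGGTGACAATAGCCGTAAAAGATATTGCCCCGGTACATAGCTGCATCCA",
  "tRNA-Ile" = "TCCTTATATTTGATAATTAGGATAAGCTCACTTCTAGTCTCCCTACCAGGCGAGCCGTACGAGTGTCCA",
  "tRNA-Gly" = "ACTGTGCTGCGGCGCTTAGGCTATCCATTAGGAAGGAGGTAAGTTGCACGGGCCCCCTGATACTAACCA",
  "tRNA-Ala" = "GCCTAAGTGTTCTATGCAATGTGCCTATTGGTCGCATGACCATATGGTACTTCCGACCAGCCAACGCCA",
  "tRNA-Pro" = "CTCGTTTGAGAGTATCCAAACGCCAGGAACCGAGACTTTGTACTGGCTAGTCAGTTAGAAGATTCGCCA",
  "tRNA-Thr" = "GAGACTCTTTCTGCTCAAGAGTAGGTTCTTGGGATTATGCGAGTCTACACTTACCCGTGCATAGGGCCA",
  "tRNA-Lys" = "ACCACGAGCTCAGCCTACGTGTTTCATGACGAATGACCGCGTATAACGTCTTCGGTGGGCCAGTTGCCA",
  "tRNA-Arg" = "AGCAACGAGGTGTGATGTAGTTTCCACGAGAAACCGAAAAACATACTTGGCTACGCTCCCCATAGGCCA",
  "tRNA-Trp" = "CCCAGCAACTCCGCTCCGGCAACGGGCGCCGTCGTTATTTTGGTTACGCACGCTGCGAGGTCTTGGCCA"
)

NONLTR_CLADES <- c("CR1", "L2", "I", "R1", "Jockey", "RTE", "Vingi", "Nimb",
                   "Daphne", "Penelope")
GYPSY_LINEAGES <- c("gypsy", "Osvaldo", "Mag", "CsRN1", "Mdg1", "Mdg3")

#' Bundled synthetic tRNA set
#'
#' Twelve synthetic tRNA sequences with mutually distinct 3'-terminal 18-mers
#' (all ending in the canonical CCA). The primer binding site (PBS) of an LTR
#' retroelement is complementary to the 3' end of one of these tRNAs; the set
#' stands in for a comprehensive insect tRNA collection.
#'
#' @return A [Biostrings::DNAStringSet] named `tRNA-Ser`, `tRNA-Met`, ...
#' @export
retro_trna_set <- function() Biostrings::DNAStringSet(.TRNAS)

#' Bundled synthetic domain reference peptides
#'
#' Short reference peptides for the protein domains used in structural
#' annotation: PRO (aspartic protease), RVT (reverse transcriptase),
#' RNH (ribonuclease H), INT (integrase) and APE (apurinic endonuclease).
#' Each carries the catalytic motif characteristic of its family and stands
#' in for the corresponding Pfam domain model at desk scale.
#'
#' @return An [Biostrings::AAStringSet] named PRO, RVT, RNH, INT, APE.
#' @export
retro_domain_refs <- function() {
  Biostrings::AAStringSet(unlist(.PEP[c("PRO", "RVT", "RNH", "INT", "APE")]))
}

#' Clade-labelled reverse transcriptase reference panel
#'
#' Synthetic RVT peptides, one per retroelement clade, derived from the base
#' RVT reference by fixed per-clade substitutions (about 30% of sites) so that
#' between-clade amino-acid distances are large relative to within-clade
#' divergence. Covers the non-LTR clades CR1, L2, I, R1, Jockey, RTE, Vingi,
#' Nimb, Daphne and Penelope, the gypsy lineages (gypsy, Osvaldo, Mag, CsRN1,
#' Mdg1, Mdg3), plus copia and BEL.
#'
#' @return An [Biostrings::AAStringSet] with metadata columns `clade` and
#'   `superfamily`.
#' @export
rvt_reference_set <- function() {
  clades <- c(NONLTR_CLADES, GYPSY_LINEAGES, "copia", "BEL")
  superf <- c(rep("nonLTR", length(NONLTR_CLADES)),
              rep("gypsy", length(GYPSY_LINEAGES)), "copia", "BEL")
  peps <- vapply(clades, function(cl)
    mutate_peptide(.PEP$RVT, 0.30, seed = str_seed(cl, 77L)), "")
  out <- Biostrings::AAStringSet(setNames(peps, paste0("REF_", clades)))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(clade = clades, superfamily = superf)
  out
}

# RVT peptide used when building a template of the given clade/lineage.
clade_rvt <- function(clade) {
  refs <- rvt_reference_set()
  i <- match(clade, S4Vectors::mcols(refs)$clade)
  if (is.na(i)) stop_config("unknown clade: ", clade)
  as.character(refs[[i]])
}

# Clade-specific variant of a non-RVT domain peptide: distinct retroelement
# lineages carry diverged copies of every domain, not identical ones, so
# templates of different clades must not share exact domain sequences.
clade_domain <- function(domain, clade) {
  base <- .PEP[[domain]]
  if (is.null(base)) stop_config("unknown domain: ", domain)
  mutate_peptide(base, 0.25, seed = str_seed(paste0(domain, "|", clade), 53L))
}

#' Retrotransposon protein panel grouped by superfamily
#'
#' Synthetic polyprotein references emulating a Repbase-style panel: gypsy,
#' copia, BEL and DIRS polyproteins assembled from the bundled domain peptides
#' in their canonical domain orders (gypsy: PRO-RVT-RNH-INT; copia:
#' PRO-INT-RVT-RNH), non-LTR ORF2 references (APE-RVT, with and without RNH),
#' and a DDE transposase decoy used to recognise DNA transposons.
#'
#' @return An [Biostrings::AAStringSet] with a `class` metadata column
#'   (`gypsy`, `copia`, `BEL`, `DIRS`, `nonLTR`, `DNA_TE`).
#' @export
retro_protein_panel <- function() {
  link <- "GSGSGA"
  glue <- function(...) paste(c(...), collapse = link)
  entries <- c(
    gypsy_pol  = glue(.PEP$PRO, clade_rvt("gypsy"), .PEP$RNH, .PEP$INT),
    copia_pol  = glue(.PEP$PRO, .PEP$INT, clade_rvt("copia"), .PEP$RNH),
    bel_pol    = glue(.PEP$PRO, clade_rvt("BEL"), .PEP$RNH, .PEP$INT),
    dirs_pol   = glue(mutate_peptide(.PEP$RVT, 0.30, seed = str_seed("DIRS", 77L)),
                      .PEP$RNH),
    nonltr_orf2     = glue(.PEP$APE, .PEP$RVT),
    nonltr_orf2_rnh = glue(.PEP$APE, .PEP$RVT, .PEP$RNH),
    transposase = .PEP$TPASE
  )
  out <- Biostrings::AAStringSet(entries)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    class = c("gypsy", "copia", "BEL", "DIRS", "nonLTR", "nonLTR", "DNA_TE"))
  out
}

#' Host-protein decoy panel
#'
#' Three synthetic host-gene peptides used to emulate the screen against
#' cellular proteins: a candidate transcript whose non-retroelement ORF
#' matches one of these is rejected as a protein-coding gene.
#'
#' @return An [Biostrings::AAStringSet].
#' @export
retro_host_decoys <- function() {
  Biostrings::AAStringSet(unlist(.PEP[c("HOST1", "HOST2", "HOST3")]))
}

#' Write the bundled reference sets as FASTA files
#'
#' Convenience export of the synthetic tRNA set, domain peptides, protein
#' panel (with `class=` tags in the headers) and clade RVT panel (with
#' `clade=` tags), for use with the command-line interface.
#'
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_reference_fasta <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("synthetic_trna.fasta", "synthetic_domains.fasta",
                        "synthetic_panel.fasta", "synthetic_rvt_refs.fasta"))
  Biostrings::writeXStringSet(retro_trna_set(), p[1])
  Biostrings::writeXStringSet(retro_domain_refs(), p[2])
  panel <- retro_protein_panel()
  names(panel) <- paste0(names(panel), " class=", S4Vectors::mcols(panel)$class)
  Biostrings::writeXStringSet(panel, p[3])
  refs <- rvt_reference_set()
  names(refs) <- paste0(names(refs), " clade=", S4Vectors::mcols(refs)$clade,
                        " superfamily=", S4Vectors::mcols(refs)$superfamily)
  Biostrings::writeXStringSet(refs, p[4])
  invisible(p)
}
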