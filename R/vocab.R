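# Canonical vocabulary: the 37 mitochondrial genes, the control region,
# the pancrustacean ground pattern, and the invertebrate mitochondrial
# (translation table 5) codon families.

#' Canonical mitochondrial gene tokens
#'
#' The 13 protein-coding genes, 2 ribosomal RNAs and 22 transfer RNAs of the
#' standard animal mitogenome, in MITOS-style nomenclature. The two leucine
#' and two serine tRNAs are distinct tokens: `trnL1` reads CUN codons, `trnL2`
#' reads UUR, `trnS1` reads AGN and `trnS2` reads UCN. The control region is
#' the extra token `"CR"`; it is a positional landmark, not a gene, and is not
#' part of the 37-gene inventory.
#'
#' @format Character vectors.
#' @name gene_vocabulary
NULL

#' @rdname gene_vocabulary
#' @export
PCG_TOKENS <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
                "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")

#' @rdname gene_vocabulary
#' @export
RRNA_TOKENS <- c("rrnS", "rrnL")

#' @rdname gene_vocabulary
#' @export
TRNA_TOKENS <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                 "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                 "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                 "trnY")

#' @rdname gene_vocabulary
#' @export
GENE_TOKENS <- c(PCG_TOKENS, RRNA_TOKENS, TRNA_TOKENS)

#' @rdname gene_vocabulary
#' @export
CR_TOKEN <- "CR"

#' Category of a canonical gene token
#'
#' @param token character vector of canonical tokens (possibly carrying a
#'   `.2`, `.3`, ... duplicate suffix).
#' @return character vector with values `"PCG"`, `"rRNA"`, `"tRNA"`,
#'   `"control_region"` or `NA` for unknown tokens.
#' @export
gene_category <- function(token) {
  base <- sub("\\.[0-9]+$", "", token)
  out <- rep(NA_character_, length(base))
  out[base %in% PCG_TOKENS] <- "PCG"
  out[base %in% RRNA_TOKENS] <- "rRNA"
  out[base %in% TRNA_TOKENS] <- "tRNA"
  out[base == CR_TOKEN] <- "control_region"
  out
}

# The pancrustacean ground pattern: the ancestral arrangement shared by
# crustaceans and hexapods (the Drosophila-like order), anchored at cox1.
# Sign +1 = majority strand, -1 = minority strand. CR sits between rrnS and
# trnI. 37 genes + CR = 38 positional tokens.
GROUND_TOKENS <- c(
  "cox1",  "trnL2", "cox2",  "trnK",  "trnD",  "atp8",  "atp6",  "cox3",
  "trnG",  "nad3",  "trnA",  "trnR",  "trnN",  "trnS1", "trnE",  "trnF",
  "nad5",  "trnH",  "nad4",  "nad4l", "trnT",  "trnP",  "nad6",  "cob",
  "trnS2", "nad1",  "trnL1", "rrnL",  "trnV",  "rrnS",  "CR",    "trnI",
  "trnQ",  "trnM",  "nad2",  "trnW",  "trnC",  "trnY")
GROUND_SIGNS <- c(
  +1, +1, +1, +1, +1, +1, +1, +1,
  +1, +1, +1, +1, +1, +1, +1, -1,
  -1, -1, -1, -1, +1, -1, +1, +1,
  +1, -1, -1, -1, -1, -1, +1, +1,
  -1, +1, +1, +1, -1, -1)

#' The pancrustacean ground pattern
#'
#' The inferred ancestral mitochondrial gene arrangement of Pancrustacea,
#' used as the baseline all observed gene orders are compared against.
#'
#' @param include_cr logical; keep the control region as a positional marker
#'   (default `TRUE`).
#' @return a [gene_order] object.
#' @export
ground_pattern <- function(include_cr = TRUE) {
  keep <- if (include_cr) rep(TRUE, length(GROUND_TOKENS)) else
    GROUND_TOKENS != CR_TOKEN
  gene_order(GROUND_TOKENS[keep], GROUND_SIGNS[keep],
             include_cr = include_cr)
}

# --- invertebrate mitochondrial code (NCBI translation table 5) -----------
#
# Stops are TAA and TAG only; TGA encodes Trp, ATA Met, AGA/AGG Ser. The 62
# sense codons fall into 21 synonymous families once serine is split into
# its two tRNA-defined families S1 (AGN) and S2 (UCN) -- the convention of
# mitogenome RSCU plots. Leucine is one 6-codon family. Family sizes then
# range from two to six.
.codon_families <- list(
  F  = c("TTT", "TTC"),
  L  = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  I  = c("ATT", "ATC"),
  M  = c("ATA", "ATG"),
  V  = c("GTT", "GTC", "GTA", "GTG"),
  S2 = c("TCT", "TCC", "TCA", "TCG"),
  P  = c("CCT", "CCC", "CCA", "CCG"),
  T  = c("ACT", "ACC", "ACA", "ACG"),
  A  = c("GCT", "GCC", "GCA", "GCG"),
  Y  = c("TAT", "TAC"),
  H  = c("CAT", "CAC"),
  Q  = c("CAA", "CAG"),
  N  = c("AAT", "AAC"),
  K  = c("AAA", "AAG"),
  D  = c("GAT", "GAC"),
  E  = c("GAA", "GAG"),
  C  = c("TGT", "TGC"),
  W  = c("TGA", "TGG"),
  R  = c("CGT", "CGC", "CGA", "CGG"),
  S1 = c("AGT", "AGC", "AGA", "AGG"),
  G  = c("GGT", "GGC", "GGA", "GGG"))

#' Sense codons and synonymous families of the invertebrate mitochondrial code
#'
#' `sense_codons()` returns the 62 sense codons of NCBI translation table 5
#' (stops TAA/TAG excluded). `codon_families()` returns the codon-to-family
#' map: 21 families, serine split into its AGN (`S1`) and UCN (`S2`)
#' tRNA-defined halves, leucine a single 6-codon family.
#'
#' @return `sense_codons()`: character vector of length 62.
#'   `codon_families()`: named character vector mapping codon to family label.
#' @export
sense_codons <- function() unname(unlist(.codon_families))

#' @rdname sense_codons
#' @export
codon_families <- function() {
  fam <- rep(names(.codon_families), lengths(.codon_families))
  stats::setNames(fam, unlist(.codon_families))
}

#' Stop codons of the invertebrate mitochondrial code
#' @return character vector (`TAA`, `TAG`).
#' @export
stop_codons <- function() c("TAA", "TAG")

# --- gene name normalization ----------------------------------------------

# amino-acid 3-letter -> tRNA token letter (Leu/Ser handled separately)
.aa3 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
          gln = "Q", glu = "E", gly = "G", his = "H", ile = "I",
          lys = "K", met = "M", phe = "F", pro = "P", thr = "T",
          trp = "W", tyr = "Y", val = "V")

# anticodon -> which leucine/serine tRNA
.ls_anticodon <- c(taa = "trnL2", uaa = "trnL2", uur = "trnL2",
                   tag = "trnL1", uag = "trnL1", cun = "trnL1",
                   tct = "trnS1", ucu = "trnS1", gct = "trnS1",
                   gcu = "trnS1", agn = "trnS1", agy = "trnS1",
                   tga = "trnS2", uga = "trnS2", ucn = "trnS2")

.synonyms <- c(
  # protein-coding genes
  co1 = "cox1", coi = "cox1", cox1 = "cox1", coxi = "cox1", mtco1 = "cox1",
  co2 = "cox2", coii = "cox2", cox2 = "cox2", coxii = "cox2",
  co3 = "cox3", coiii = "cox3", cox3 = "cox3", coxiii = "cox3",
  cytb = "cob", cob = "cob", cytochromeb = "cob",
  nd1 = "nad1", nad1 = "nad1", nd2 = "nad2", nad2 = "nad2",
  nd3 = "nad3", nad3 = "nad3", nd4 = "nad4", nad4 = "nad4",
  nd4l = "nad4l", nad4l = "nad4l", nd5 = "nad5", nad5 = "nad5",
  nd6 = "nad6", nad6 = "nad6",
  atp6 = "atp6", atpase6 = "atp6", atp8 = "atp8", atpase8 = "atp8",
  # ribosomal RNAs
  rrns = "rrnS", srrna = "rrnS", ssu = "rrnS", `12s` = "rrnS",
  `12srrna` = "rrnS", `12sribosomalrna` = "rrnS", rns = "rrnS",
  smallsubunitribosomalrna = "rrnS",
  rrnl = "rrnL", lrrna = "rrnL", lsu = "rrnL", `16s` = "rrnL",
  `16srrna` = "rrnL", `16sribosomalrna` = "rrnL", rnl = "rrnL",
  largesubunitribosomalrna = "rrnL",
  # control region
  cr = "CR", dloop = "CR", controlregion = "CR",
  putativecontrolregion = "CR", atrichregion = "CR", ncr = "CR")

#' Normalize an annotation label to a canonical gene token
#'
#' Maps the many nomenclatures found in GenBank records ("COI", "ND4L",
#' "12S ribosomal RNA", "tRNA-Leu(UUR)", "D-loop", ...) onto the canonical
#' token vocabulary. Leucine and serine tRNAs are resolved to
#' `trnL1`/`trnL2`/`trnS1`/`trnS2` by an anticodon or codon-family qualifier
#' ("(UUR)", "(uaa)", "(AGN)" ...); an ambiguous "tRNA-Leu"/"tRNA-Ser"
#' without one cannot be mapped. The mapping is deterministic and idempotent.
#'
#' @param raw character vector of annotation labels.
#' @return character vector of canonical tokens; `NA` where the label is
#'   unmappable (the unknown-name signal; the raw label travels with the
#'   `NA` via the `names()` attribute).
#' @examples
#' normalize_gene_name(c("COI", "ND4L", "srRNA", "tRNA-Leu(UUR)"))
#' @export
normalize_gene_name <- function(raw) {
  out <- vapply(raw, .normalize_one, character(1), USE.NAMES = FALSE)
  names(out) <- raw
  out
}

.normalize_one <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return(NA_character_)
  # already canonical?
  if (raw %in% c(GENE_TOKENS, CR_TOKEN)) return(raw)
  s <- tolower(raw)
  # extract a parenthesised anticodon/codon-family qualifier before stripping
  anti <- if (grepl("\\(([a-z]{3})\\)", s)) sub(".*\\(([a-z]{3})\\).*", "\\1", s)
          else NA_character_
  s2 <- gsub("[^a-z0-9]", "", sub("\\(.*\\)", "", s))
  lc <- tolower(c(GENE_TOKENS, CR_TOKEN))
  if (s2 %in% lc) return(c(GENE_TOKENS, CR_TOKEN)[match(s2, lc)])
  if (s2 %in% names(.synonyms)) return(unname(.synonyms[s2]))
  # tRNAs: "trna-ala", "trnA", "trn ala", "tRNA-Leu (UUR)" ...
  if (grepl("^trna?", s2)) {
    body <- sub("^trna?", "", s2)
    if (body %in% names(.aa3)) return(paste0("trn", unname(.aa3[body])))
    if (body %in% c("leu", "ser", "l", "s")) {
      key <- if (!is.na(anti)) anti else NA_character_
      if (!is.na(key) && key %in% names(.ls_anticodon))
        return(unname(.ls_anticodon[key]))
      return(NA_character_)  # ambiguous Leu/Ser without anticodon
    }
    # single-letter form trnX (non Leu/Ser)
    up <- toupper(body)
    if (nchar(up) == 1 && paste0("trn", up) %in% TRNA_TOKENS)
      return(paste0("trn", up))
  }
  NA_character_
}
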