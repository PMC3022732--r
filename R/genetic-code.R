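#' @importFrom Biostrings getGeneticCode reverseComplement DNAString
NULL

# Invertebrate mitochondrial code (NCBI translation table 5), DNA alphabet.
# AGA/AGG -> Ser, ATA -> Met, TGA -> Trp; stops are TAA/TAG only.
.code5 <- local({
  gc5 <- Biostrings::getGeneticCode("5")
  attributes(gc5) <- list(names = names(gc5))
  gc5
})

.aa3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "STOP"
)

#' Translate a codon under the invertebrate mitochondrial code
#'
#' Translation table 5: `AGA`/`AGG` code for Ser, `ATA` for Met and `TGA`
#' for Trp; the only stop codons are `TAA` and `TAG`.
#'
#' @param codon Character vector of 3-letter codons over `A`,`C`,`G`,`T`
#'   (`U` accepted and treated as `T`; case-insensitive).
#' @return Character vector of three-letter amino-acid codes (`"Ser"`,
#'   `"Met"`, ...) or `"STOP"`; codons containing any other character
#'   (e.g. `N`) give `NA`.
#' @examples
#' code5_translate(c("AGA", "TGA", "ATA", "TAA", "ANA"))
#' @export
code5_translate <- function(codon) {
  codon <- chartr("Uu", "Tt", toupper(codon))
  aa <- .code5[codon]
  out <- unname(.aa3[aa])
  out[nchar(codon) != 3L] <- NA_character_
  out
}

# ---- synonymous codon families -------------------------------------------

.family_table <- local({
  fam <- function(id, aa, class, prefix) {
    third <- switch(class, NNY = c("T", "C"), NNR = c("A", "G"),
                    NNN = c("T", "C", "A", "G"))
    list(family_id = id, amino_acid = aa, degeneracy_class = class,
         prefix = prefix, codons = paste0(prefix, third))
  }
  fams <- list(
    # fourfold-degenerate quartets
    fam("Leu-CUN", "Leu", "NNN", "CT"),
    fam("Val-GUN", "Val", "NNN", "GT"),
    fam("Ser-UCN", "Ser", "NNN", "TC"),
    fam("Pro-CCN", "Pro", "NNN", "CC"),
    fam("Thr-ACN", "Thr", "NNN", "AC"),
    fam("Ala-GCN", "Ala", "NNN", "GC"),
    fam("Arg-CGN", "Arg", "NNN", "CG"),
    fam("Gly-GGN", "Gly", "NNN", "GG"),
    fam("Ser-AGN", "Ser", "NNN", "AG"),   # AGA/AGG reassigned to Ser in code 5
    # pyrimidine-ending pairs
    fam("Phe-UUY", "Phe", "NNY", "TT"),
    fam("Ile-AUY", "Ile", "NNY", "AT"),
    fam("Tyr-UAY", "Tyr", "NNY", "TA"),
    fam("His-CAY", "His", "NNY", "CA"),
    fam("Asn-AAY", "Asn", "NNY", "AA"),
    fam("Asp-GAY", "Asp", "NNY", "GA"),
    fam("Cys-UGY", "Cys", "NNY", "TG"),
    # purine-ending pairs
    fam("Leu-UUR", "Leu", "NNR", "TT"),
    fam("Met-AUR", "Met", "NNR", "AT"),
    fam("Gln-CAR", "Gln", "NNR", "CA"),
    fam("Lys-AAR", "Lys", "NNR", "AA"),
    fam("Glu-GAR", "Glu", "NNR", "GA"),
    fam("Trp-UGR", "Trp", "NNR", "TG")
  )
  names(fams) <- vapply(fams, `[[`, "", "family_id")
  fams
})

#' Synonymous codon families of translation table 5
#'
#' The 22 codon families of the invertebrate mitochondrial code, each the
#' set of synonymous codons sharing their first two positions and decoded
#' by a single tRNA: 9 fourfold-degenerate quartets (`NNN`, including
#' Ser-AGN since AGA/AGG are Ser in this code), 7 pyrimidine-ending pairs
#' (`NNY`) and 6 purine-ending pairs (`NNR`).  Together they partition the
#' 62 sense codons (stops `TAA`/`TAG` excluded).
#'
#' @return A data frame with one row per family: `family_id`,
#'   `amino_acid`, `degeneracy_class`, `prefix` (first two codon bases,
#'   DNA), and a list-column `codons` of member codons (DNA).
#' @examples
#' fams <- codon_families()
#' table(fams$degeneracy_class)
#' @export
codon_families <- function() {
  df <- data.frame(
    family_id = vapply(.family_table, `[[`, "", "family_id"),
    amino_acid = vapply(.family_table, `[[`, "", "amino_acid"),
    degeneracy_class = vapply(.family_table, `[[`, "", "degeneracy_class"),
    prefix = vapply(.family_table, `[[`, "", "prefix"),
    row.names = NULL
  )
  df$codons <- lapply(.family_table, `[[`, "codons")
  df
}

# codon -> family_id lookup (sense codons only)
.codon_to_family <- local({
  m <- character(0)
  for (f in .family_table) m[f$codons] <- f$family_id
  m
})

#' Map a codon to its synonymous codon family
#'
#' @param codon Character vector of codons (DNA or RNA alphabet).
#' @return `family_id` for sense codons, `NA` for stop codons (`TAA`,
#'   `TAG`) or codons with ambiguity characters.
#' @examples
#' family_of_codon(c("AGA", "TGA", "TAA"))
#' @export
family_of_codon <- function(codon) {
  codon <- chartr("Uu", "Tt", toupper(codon))
  unname(.codon_to_family[codon])
}

.family <- function(family_id) {
  f <- .family_table[[family_id]]
  if (is.null(f)) stop("unknown codon family: ", family_id)
  f
}

is_stop_codon <- function(codon) {
  chartr("Uu", "Tt", toupper(codon)) %in% c("TAA", "TAG")
}

# ---- small sequence utilities --------------------------------------------

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Reverse-complemented sequences, uppercase.
#' @examples
#' reverse_complement("ACGTN")
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname rna_dna
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' Convert between DNA and RNA alphabets
#'
#' The package stores sequence internally in the DNA alphabet and uses the
#' RNA convention only when displaying codons and anticodons.
#'
#' @param x Character vector.
#' @return `as_rna` maps `T`->`U`, `as_dna` maps `U`->`T` (both cases).
#' @name rna_dna
#' @examples
#' as_rna("TCA"); as_dna("UCA")
#' @export
as_dna <- function(x) chartr("Uu", "Tt", x)

# split a sequence into in-frame codons (complete triplets only)
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
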