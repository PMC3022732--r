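# in-code fixtures shared across the suite

coding_gene <- function(nt, name = "toy") {
  structure(list(name = name, nt_sequence = nt,
                 complete_stop = grepl("(TAA|TAG)$", nt)),
            class = "coding_gene")
}

trna_gene <- function(aa, seq = NA_character_, anticodon = NA_character_,
                      offset = NA_integer_, label = paste0("tRNA-", aa)) {
  structure(list(amino_acid = aa, isoacceptor_label = label,
                 nt_sequence = seq, annotated_anticodon = anticodon,
                 anticodon_offset = offset),
            class = "trna_gene")
}

# a codon_usage object built directly from a named codon count vector
usage_from_counts <- function(...) {
  counts <- c(...)
  cds <- coding_gene(paste(rep(names(counts), counts), collapse = ""))
  count_codons(list(cds))
}

# minimal hand-written GenBank text: a 9-nt CDS on +, a 21-nt tRNA-Trp
# with a positional /anticodon qualifier, 60-nt circular genome
toy_genbank_lines <- function() {
  seq60 <- paste0("atgttaggt",            # CDS 1..9
                  "ccccccccc",            # tRNA 10..30, anticodon tca at 19..21
                  "tcaccccccccc",
                  paste(rep("a", 30), collapse = ""))
  origin <- paste0("        1 ", paste(substring(seq60, seq(1, 51, 10),
                                                 seq(10, 60, 10)),
                                       collapse = " "))
  c(
    "LOCUS       TOY0001               60 bp    DNA     circular INV 01-JAN-2000",
    "DEFINITION  Toyorganism toyensis mitochondrion.",
    "ACCESSION   TOY0001",
    "SOURCE      mitochondrion Toyorganism toyensis",
    "  ORGANISM  Toyorganism toyensis",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "                     /organism=\"Toyorganism toyensis\"",
    "     CDS             1..9",
    "                     /gene=\"ND9\"",
    "                     /transl_table=5",
    "     tRNA            10..30",
    "                     /product=\"tRNA-Trp\"",
    "                     /anticodon=(pos:19..21,aa:Trp,seq:tca)",
    "ORIGIN",
    origin,
    "//"
  )
}

write_toy_genbank <- function(path = tempfile(fileext = ".gbk")) {
  writeLines(toy_genbank_lines(), path)
  path
}

# random DNA string under the current RNG
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
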