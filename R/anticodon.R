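# Anticodon resolution and mapping of tRNAs to the codon families they
# decode.  Anticodons are written 5'->3' in the RNA alphabet, so the
# wobble base (structural position 34, pairing with the codon's third
# position) is the FIRST character of the triplet.

new_anticodon <- function(triplet, source) {
  triplet <- as_rna(toupper(triplet))
  stopifnot(nchar(triplet) == 3L)
  structure(list(triplet = triplet,
                 wobble = substr(triplet, 1L, 1L),
                 source = source),
            class = "anticodon")
}

#' Canonical anticodon of a codon family
#'
#' Builds the 5'->3' anticodon whose positions 2-3 Watson-Crick pair with
#' the family's first two codon positions, with a chosen wobble base.
#'
#' @param family A `family_id`.
#' @param wobble Wobble base (RNA: `A`, `C`, `G` or `U`).
#' @return Anticodon triplet (RNA, 5'->3').
#' @examples
#' canonical_anticodon("Trp-UGR", "U")   # UCA
#' canonical_anticodon("Ser-AGN", "G")   # GCU
#' @export
canonical_anticodon <- function(family, wobble) {
  f <- .family(family)
  stopifnot(as_rna(toupper(wobble)) %in% c("A", "C", "G", "U"))
  paste0(as_rna(toupper(wobble)), as_rna(reverse_complement(f$prefix)))
}

# families whose codons' first two positions pair with anticodon pos 2-3;
# a two-codon prefix can host an NNY and an NNR family, disambiguated by
# the wobble base (G/A read pyrimidine-ending codons, U/C purine-ending).
anticodon_to_family <- function(triplet) {
  triplet <- as_rna(toupper(triplet))
  prefix <- as_dna(reverse_complement(as_dna(substr(triplet, 2L, 3L))))
  fams <- Filter(function(f) identical(f$prefix, prefix), .family_table)
  if (length(fams) == 0L) return(NA_character_)
  if (length(fams) == 1L) return(fams[[1]]$family_id)
  wob <- substr(triplet, 1L, 1L)
  class_wanted <- if (wob %in% c("G", "A")) "NNY" else "NNR"
  for (f in fams) if (identical(f$degeneracy_class, class_wanted))
    return(f$family_id)
  NA_character_
}

#' Resolve the anticodon of a tRNA gene
#'
#' Priority order: (1) the annotated `/anticodon` qualifier triplet;
#' (2) the slice of the gene sequence at the annotated anticodon offset;
#' (3) inference — scan the central third of the gene (where the
#' anticodon loop of a cloverleaf tRNA lies) for a triplet that decodes a
#' codon family of the tRNA's amino acid.  When both qualifier and offset
#' exist and disagree, the qualifier wins and the discrepancy is logged.
#'
#' @param trna A `trna_gene` from [extract_trnas()].
#' @return An `anticodon` object (`triplet`, `wobble`, `source` one of
#'   `"qualifier"`, `"offset_slice"`, `"inferred"`), or `NULL` when no
#'   candidate is found (a warning is raised).
#' @export
resolve_anticodon <- function(trna) {
  stopifnot(inherits(trna, "trna_gene"))
  slice <- NA_character_
  if (!is.na(trna$anticodon_offset)) {
    slice <- substr(trna$nt_sequence, trna$anticodon_offset + 1L,
                    trna$anticodon_offset + 3L)
  }
  if (!is.na(trna$annotated_anticodon)) {
    if (!is.na(slice) && !identical(as_rna(slice), trna$annotated_anticodon)) {
      message("tRNA-", trna$amino_acid, ": /anticodon qualifier (",
              trna$annotated_anticodon, ") disagrees with sequence slice (",
              as_rna(slice), "); qualifier wins")
    }
    return(new_anticodon(trna$annotated_anticodon, "qualifier"))
  }
  if (!is.na(slice)) return(new_anticodon(slice, "offset_slice"))

  # inference within the central third of the gene
  s <- as_dna(trna$nt_sequence)
  n <- nchar(s)
  if (n < 9L || is.na(trna$amino_acid)) {
    warning("tRNA-", trna$amino_acid, ": anticodon unresolved", call. = FALSE)
    return(NULL)
  }
  lo <- max(1L, floor(n / 3) + 1L)
  hi <- min(n - 2L, ceiling(2 * n / 3))
  centre <- (n - 2L) / 2
  best <- NULL; best_d <- Inf
  for (i in lo:hi) {
    cand <- substr(s, i, i + 2L)
    fam <- anticodon_to_family(cand)
    if (is.na(fam)) next
    if (!identical(.family(fam)$amino_acid, trna$amino_acid)) next
    d <- abs(i - centre)
    if (d < best_d) { best <- cand; best_d <- d }
  }
  if (is.null(best)) {
    warning("tRNA-", trna$amino_acid, ": anticodon unresolved", call. = FALSE)
    return(NULL)
  }
  new_anticodon(best, "inferred")
}

#' Codon family decoded by a tRNA
#'
#' The unique family whose codons' first two positions are the reverse
#' complement of anticodon positions 2-3, disambiguated by the wobble
#' base for prefixes hosting both an NNY and an NNR family.  Leu and Ser
#' isoacceptors are told apart by the anticodon, never by name.  When the
#' annotated amino acid disagrees with the anticodon, the anticodon wins
#' with a warning (mis-annotation handling).
#'
#' @param trna A `trna_gene`.
#' @param ac An `anticodon` object.
#' @return A list: `family_id` and `consistent` (TRUE when the annotated
#'   amino acid matches the family's).
#' @export
family_of_trna <- function(trna, ac) {
  stopifnot(inherits(ac, "anticodon"))
  fam <- anticodon_to_family(ac$triplet)
  if (is.na(fam)) {
    warning("anticodon ", ac$triplet, " decodes no codon family", call. = FALSE)
    return(list(family_id = NA_character_, consistent = FALSE))
  }
  consistent <- identical(.family(fam)$amino_acid, trna$amino_acid)
  if (!consistent) {
    warning("tRNA annotated as ", trna$amino_acid, " but anticodon ",
            ac$triplet, " decodes ", fam, "; using the anticodon",
            call. = FALSE)
  }
  list(family_id = fam, consistent = consistent)
}

#' Anticodon repertoire of a genome
#'
#' Resolves every tRNA and groups the anticodons by the codon family they
#' decode.  Duplicated isoacceptors are preserved with multiplicity (a
#' genome may carry up to nine tRNA-Met genes); families with no tRNA are
#' absent from the map; unresolvable tRNAs are dropped with a warning.
#'
#' @param trnas List of `trna_gene` objects.
#' @return Named list `family_id` -> character vector of anticodon
#'   triplets (RNA, with multiplicity).
#' @export
anticodon_repertoire <- function(trnas) {
  rep <- list()
  for (trna in trnas) {
    ac <- resolve_anticodon(trna)
    if (is.null(ac)) next
    fam <- family_of_trna(trna, ac)$family_id
    if (is.na(fam)) next
    rep[[fam]] <- c(rep[[fam]], ac$triplet)
  }
  rep
}

#' @export
print.anticodon <- function(x, ...) {
  cat("<anticodon> ", x$triplet, " (wobble ", x$wobble, ", ",
      x$source, ")\n", sep = "")
  invisible(x)
}
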