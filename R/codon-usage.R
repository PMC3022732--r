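# Codon counting over all CDS of a genome and aggregation by synonymous
# codon family under translation table 5.

.all_codons <- local({
  b <- c("T", "C", "A", "G")
  g <- expand.grid(third = b, second = b, first = b,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  paste0(g$first, g$second, g$third)
})

#' Count codons over a set of coding genes
#'
#' Reading-frame triplets are tallied per gene and summed.  Stop codons
#' (`TAA`/`TAG`) and codons containing ambiguity characters are excluded
#' from the counts but tallied in `skipped_codons`; start codons are
#' ordinary codons and are included.
#'
#' @param cds_list Non-empty list of `coding_gene` objects.
#' @return A `codon_usage` object: `counts` (named integer vector over all
#'   64 codons), `skipped_codons`, `genes_counted`.
#' @examples
#' g <- structure(list(name = "toy", nt_sequence = "ATGTTATAA",
#'                     complete_stop = TRUE), class = "coding_gene")
#' count_codons(list(g))$counts[c("ATG", "TTA")]
#' @export
count_codons <- function(cds_list) {
  if (length(cds_list) == 0L) stop("no coding genes supplied")
  all_codons <- unlist(lapply(cds_list, function(g) split_codons(g$nt_sequence)))
  if (is.null(all_codons)) all_codons <- character(0)
  clean <- grepl("^[ACGT]{3}$", all_codons)
  keep <- clean & !is_stop_codon(all_codons)
  counts <- table(factor(all_codons[keep], levels = .all_codons))
  counts <- setNames(as.integer(counts), .all_codons)
  structure(list(
    counts = counts,
    skipped_codons = sum(!keep),
    genes_counted = length(cds_list)
  ), class = "codon_usage")
}

#' Per-family codon usage
#'
#' Restricts a codon usage table to one synonymous codon family and
#' tallies third-position bases.  For purine-ending (`NNR`) families the
#' A/G third-base ratio `na_ng_ratio` (the quantity the wobble cost
#' hypothesis conditions on) is computed when the G count is positive.
#'
#' @param table A `codon_usage` object from [count_codons()].
#' @param family A `family_id` (see [codon_families()]).
#' @return A `family_usage` object: `family_id`, `amino_acid`,
#'   `degeneracy_class`, `per_codon` (named counts), `total`, `n_A`,
#'   `n_G`, `n_C`, `n_T` and `na_ng_ratio` (`NA` unless NNR with G > 0).
#' @export
family_usage <- function(table, family) {
  stopifnot(inherits(table, "codon_usage"))
  f <- .family(family)
  per <- table$counts[f$codons]
  third <- substr(f$codons, 3L, 3L)
  n_of <- function(b) sum(per[third == b])
  nA <- n_of("A"); nG <- n_of("G"); nC <- n_of("C"); nT <- n_of("T")
  ratio <- if (identical(f$degeneracy_class, "NNR") && nG > 0) nA / nG else NA_real_
  structure(list(
    family_id = f$family_id, amino_acid = f$amino_acid,
    degeneracy_class = f$degeneracy_class,
    per_codon = per, total = sum(per),
    n_A = nA, n_G = nG, n_C = nC, n_T = nT,
    na_ng_ratio = ratio
  ), class = "family_usage")
}

#' Most abundant codon of a family
#'
#' @param fu A `family_usage` object.
#' @return The codon (DNA) with the strictly largest count; `"TIE"` when
#'   the maximum is shared; `"NO_DATA"` when the family is unused.
#' @export
most_abundant_codon <- function(fu) {
  stopifnot(inherits(fu, "family_usage"))
  if (fu$total == 0L) return("NO_DATA")
  mx <- max(fu$per_codon)
  winners <- names(fu$per_codon)[fu$per_codon == mx]
  if (length(winners) > 1L) "TIE" else winners
}

#' Percentage of the A-ending codon in a two-codon R family
#'
#' `P_XUA = 100 * N_XUA / (N_XUA + N_XUG)`: the share of the A-ending
#' codon within its purine-ending family — Leu-UUR for `x = "U"`
#' (`P_UUA`), Met-AUR for `x = "A"` (`P_AUA`).  Used to test the tRNA-Met
#' translation initiation/elongation conflict hypothesis, which predicts
#' selection against AUA (hence `P_AUA < P_UUA`) in genomes whose only
#' Met anticodon is CAU.
#'
#' @param table A `codon_usage` object.
#' @param x `"U"` or `"A"` (first base of the codon pair, RNA).
#' @return Percentage in `[0, 100]`, or `NA` with a warning when the
#'   family is unused.
#' @export
p_xua <- function(table, x = c("U", "A")) {
  x <- match.arg(x)
  stopifnot(inherits(table, "codon_usage"))
  xa <- paste0(as_dna(x), "TA")
  xg <- paste0(as_dna(x), "TG")
  denom <- table$counts[[xa]] + table$counts[[xg]]
  if (denom == 0L) {
    warning("P_", x, "UA undefined: no ", x, "UR codons counted", call. = FALSE)
    return(NA_real_)
  }
  100 * table$counts[[xa]] / denom
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("<codon_usage> ", sum(x$counts), " codons over ", x$genes_counted,
      " genes (", x$skipped_codons, " skipped)\n", sep = "")
  invisible(x)
}
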