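# Strand composition statistics: GT content and AT/GC skew.
#
# AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C); positive AT
# skew means an excess of A over T on the counted strand.  Marine bivalve
# mitogenomes encode all genes on the H strand, which is GT-rich, so the
# deposited strand is counted as-is and never silently complemented.

#' Tally nucleotide counts of a sequence
#'
#' @param sequence DNA string (case-insensitive; empty allowed).
#' @return A `base_counts` list: `nA`, `nC`, `nG`, `nT`, `nOther`.
#' @examples
#' base_counts("ACGTN")
#' @export
base_counts <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  structure(list(
    nA = unname(tab[["A"]]), nC = unname(tab[["C"]]),
    nG = unname(tab[["G"]]), nT = unname(tab[["T"]]),
    nOther = length(ch) - sum(tab)
  ), class = "base_counts")
}

#' Composition statistics from base counts
#'
#' Computes GT percent, AT skew and GC skew with no internal rounding;
#' a skew whose denominator is zero is `NA`.
#'
#' @param counts A `base_counts` object (or list with `nA`, `nC`, `nG`,
#'   `nT`).
#' @return A `composition_stats` list: `gt_percent` in `[0, 100]`,
#'   `at_skew` and `gc_skew` in `[-1, 1]` (or `NA` when undefined).
#' @examples
#' composition_stats(base_counts("GGTTTA"))
#' @export
composition_stats <- function(counts) {
  a <- counts$nA; c_ <- counts$nC; g <- counts$nG; t <- counts$nT
  total <- a + c_ + g + t
  structure(list(
    gt_percent = if (total > 0) 100 * (g + t) / total else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_
  ), class = "composition_stats")
}

# codons counted by the codon-usage module: complete, N-free, non-stop
counted_codons <- function(cds_list) {
  codons <- unlist(lapply(cds_list, function(g) split_codons(g$nt_sequence)))
  if (is.null(codons)) codons <- character(0)
  clean <- grepl("^[ACGT]{3}$", codons)
  codons[clean & !is_stop_codon(codons)]
}

#' Composition of third codon positions across coding genes
#'
#' Concatenates the third base of every counted codon over all coding
#' genes (stop codons and codons containing ambiguity characters are
#' excluded, the same scope as [count_codons()]) and returns its
#' composition statistics.
#'
#' @param cds_list List of `coding_gene` objects from [extract_cds()].
#' @return A `composition_stats` object.
#' @export
third_position_stats <- function(cds_list) {
  if (length(cds_list) == 0L) stop("no coding genes supplied")
  codons <- counted_codons(cds_list)
  third <- paste(substr(codons, 3L, 3L), collapse = "")
  composition_stats(base_counts(third))
}

#' @export
print.composition_stats <- function(x, digits = 2, ...) {
  cat(sprintf("GT%% = %.*f, AT skew = %.*f, GC skew = %.*f\n",
              digits, x$gt_percent, digits, x$at_skew, digits, x$gc_skew))
  invisible(x)
}
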