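# Published per-genome summary statistics for the 29 marine bivalve
# mitogenomes, shipped as plain TSV under inst/extdata/.  These printed
# values are inputs: recomputing their internal arithmetic (support
# percentage, column means, Met-repertoire group means, row consistency)
# requires no sequence downloads.

#' Published summary statistics for 29 marine bivalve mitogenomes
#'
#' Two reference tables shipped with the package.  `"genome"`: per-genome
#' whole-strand GT percent, AT skew, GC skew, third-position GT percent,
#' and the counts of codon families unambiguously supporting the
#' codon-anticodon adaptation hypothesis (`n_caah`) and the wobble
#' versatility hypothesis (`n_wvh`).  `"met"`: per-genome tRNA-Met
#' anticodon repertoire with `p_uua`, `p_aua` and their printed
#' difference.
#'
#' @param table `"genome"` or `"met"`.
#' @return A data frame with 29 rows.
#' @examples
#' ref <- bivalve_reference("genome")
#' sum(ref$n_wvh); sum(ref$n_caah)
#' @export
bivalve_reference <- function(table = c("genome", "met")) {
  table <- match.arg(table)
  file <- switch(table,
    genome = "bivalve_genome_stats.tsv",
    met = "bivalve_met_stats.tsv")
  path <- system.file("extdata", file, package = "mitowobble", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Overall WVH support percentage from per-genome counts
#'
#' `100 * sum(n_wvh) / (sum(n_wvh) + sum(n_caah))`: the share of
#' unambiguously classified codon families that support the wobble
#' versatility hypothesis.
#'
#' @param genome_stats Data frame with `n_wvh` and `n_caah` columns (e.g.
#'   `bivalve_reference("genome")`, or recomputed summaries).
#' @return Percentage in `[0, 100]`.
#' @export
wvh_support_percent <- function(genome_stats) {
  s_wvh <- sum(genome_stats$n_wvh)
  s_caah <- sum(genome_stats$n_caah)
  100 * s_wvh / (s_wvh + s_caah)
}

#' Met repertoire group from its display text
#'
#' Parses the `"CAU"`, `"CAU/CAU"`, `"CAU/UAU"`, `"4CAU/5UAU"` dialect.
#'
#' @param display Character vector of repertoire display strings.
#' @return `"HAS_UAU"` where a UAU anticodon is present, else
#'   `"CAU_ONLY"`.
#' @export
met_group_from_display <- function(display) {
  ifelse(grepl("UAU", display, fixed = TRUE), "HAS_UAU", "CAU_ONLY")
}
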