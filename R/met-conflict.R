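# tRNA-Met translation initiation/elongation conflict statistics.
#
# A lone CAU anticodon must both initiate at AUG and elongate at AUA;
# the conflict hypothesis predicts selection against AUA, so P_AUA
# (share of AUA within the AUR family) should fall below P_UUA (share of
# UUA within UUR, the mutational baseline).  Genomes that also carry a
# UAU-tRNA-Met are released from the conflict and are predicted to use
# AUA relatively more.

#' Group a genome by its Met anticodon repertoire
#'
#' @param repertoire Named list from [anticodon_repertoire()].
#' @return List with `group` (`"HAS_UAU"` if any Met anticodon is UAU,
#'   else `"CAU_ONLY"`; `"UNGROUPED"` with a warning when no Met tRNA is
#'   present) and `display` (e.g. `"CAU"`, `"CAU/UAU"`, `"4CAU/5UAU"`).
#' @export
met_group <- function(repertoire) {
  acs <- repertoire[["Met-AUR"]]
  if (is.null(acs) || length(acs) == 0L) {
    warning("no tRNA-Met in repertoire", call. = FALSE)
    return(list(group = "UNGROUPED", display = ""))
  }
  group <- if (any(acs == "UAU")) "HAS_UAU" else "CAU_ONLY"
  list(group = group, display = format_met_display(acs))
}

#' Display text for a Met anticodon multiset
#'
#' Follows the conventional dialect: occurrences joined with `/` when
#' there are at most two genes (`"CAU"`, `"CAU/CAU"`, `"CAU/UAU"`);
#' otherwise multiplicities are prefixed per distinct triplet
#' (`"4CAU/5UAU"`), CAU listed first.
#'
#' @param acs Character vector of Met anticodon triplets (RNA).
#' @return Display string.
#' @export
format_met_display <- function(acs) {
  ord <- order(match(acs, c("CAU", "UAU"), nomatch = 3L), acs)
  acs <- acs[ord]
  if (length(acs) <= 2L) return(paste(acs, collapse = "/"))
  tab <- table(factor(acs, levels = unique(acs)))
  paste(ifelse(tab > 1L, paste0(tab, names(tab)), names(tab)), collapse = "/")
}

#' Met-conflict summary of one mitogenome
#'
#' @param record A `mito_record` with countable UUR and AUR codons.
#' @return A `met_summary` list: `accession`, `organism`,
#'   `met_anticodons` (display text), `group`, `p_uua`, `p_aua`, `diff`
#'   (`p_uua - p_aua`, unrounded).  Undefined P values propagate as `NA`.
#' @export
met_summary <- function(record) {
  stopifnot(inherits(record, "mito_record"))
  usage <- count_codons(extract_cds(record))
  repertoire <- anticodon_repertoire(extract_trnas(record))
  grp <- met_group(repertoire)
  p_uua <- p_xua(usage, "U")
  p_aua <- p_xua(usage, "A")
  structure(list(
    accession = record$accession, organism = record$organism,
    met_anticodons = grp$display, group = grp$group,
    p_uua = p_uua, p_aua = p_aua, diff = p_uua - p_aua
  ), class = "met_summary")
}

#' Group means of Met-conflict summaries
#'
#' Unweighted arithmetic means of `p_uua`, `p_aua` and their difference,
#' per repertoire group plus an overall `ALL` row covering every genome;
#' `NA` values are excluded from each mean.  Empty groups are omitted.
#'
#' @param summaries A list of `met_summary` objects, or a data frame with
#'   columns `group`, `p_uua`, `p_aua`, `diff`.
#' @return Data frame: `group`, `n_genomes`, `mean_p_uua`, `mean_p_aua`,
#'   `mean_diff`.
#' @export
group_means <- function(summaries) {
  df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, lapply(summaries, function(s) data.frame(
      group = s$group, p_uua = s$p_uua, p_aua = s$p_aua, diff = s$diff,
      stringsAsFactors = FALSE)))
  one <- function(label, sub) data.frame(
    group = label, n_genomes = nrow(sub),
    mean_p_uua = mean(sub$p_uua, na.rm = TRUE),
    mean_p_aua = mean(sub$p_aua, na.rm = TRUE),
    mean_diff = mean(sub$diff, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  groups <- unique(df$group)
  out <- do.call(rbind, lapply(groups, function(g) one(g, df[df$group == g, ])))
  rbind(out, one("ALL", df))
}
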