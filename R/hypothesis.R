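# Classification of every codon family against the three wobble-site
# hypotheses:
#   WVH  (wobble versatility): the wobble base is the most versatile
#        pairer — G for NNY families (G pairs C and U), U for NNR and NNN.
#   CAAH (codon-anticodon adaptation): the wobble base Watson-Crick
#        matches the third position of the family's most abundant codon.
#   WCH  (wobble cost): for NNR families only — C when N_A << N_G
#        (wobble-U against abundant G-ending codons is costly), else U.

.wc_complement <- c(A = "U", C = "G", G = "C", T = "A", U = "A")

#' Wobble versatility prediction for a codon family
#'
#' @param family A `family_id`.
#' @return `"G"` for NNY families, `"U"` for NNR and NNN families.
#' @export
predict_wvh <- function(family) {
  f <- .family(family)
  if (identical(f$degeneracy_class, "NNY")) "G" else "U"
}

#' Codon-anticodon adaptation prediction
#'
#' The Watson-Crick complement (RNA) of the third base of the family's
#' most abundant codon.
#'
#' @param fu A `family_usage` object.
#' @return A base (`A`/`C`/`G`/`U`), `"AMBIGUOUS"` on an exact count tie,
#'   or `"NO_DATA"` for an unused family.
#' @export
predict_caah <- function(fu) {
  top <- most_abundant_codon(fu)
  if (top %in% c("TIE", "NO_DATA")) {
    return(if (identical(top, "TIE")) "AMBIGUOUS" else "NO_DATA")
  }
  unname(.wc_complement[substr(top, 3L, 3L)])
}

#' Wobble cost prediction for NNR families
#'
#' Only when the A-ending codon is much rarer than the G-ending codon
#' (`n_A / n_G < tau`) is the cost of a wobble U higher than that of a C,
#' and a C is predicted; otherwise U.  The shipped threshold `tau = 0.25`
#' separates the Pectinoida Trp-UGR ratios (0.098-0.226, where the fixed
#' CCA anticodon is observed) from all other reported ratios
#' (0.44-2.382).
#'
#' @param fu A `family_usage` object.
#' @param tau Threshold ratio (strict inequality; default 0.25).
#' @return `"C"` or `"U"` for NNR families; `"NOT_APPLICABLE"` otherwise
#'   (also, with a warning, when `n_G = 0`).
#' @export
predict_wch <- function(fu, tau = 0.25) {
  stopifnot(inherits(fu, "family_usage"), tau > 0)
  if (!identical(fu$degeneracy_class, "NNR")) return("NOT_APPLICABLE")
  if (fu$n_G == 0L) {
    warning(fu$family_id, ": n_G = 0, wobble cost prediction undefined",
            call. = FALSE)
    return("NOT_APPLICABLE")
  }
  if (fu$na_ng_ratio < tau) "C" else "U"
}

#' Classify one codon family against the hypotheses
#'
#' Compares the observed wobble bases of all anticodons decoding the
#' family with the WVH and CAAH predictions.  Support categories:
#' `WVH_ONLY` / `CAAH_ONLY` (observed matches exactly one of two distinct
#' predictions), `BOTH` (observed matches both — normally because the
#' predictions coincide), `NEITHER`, `NO_TRNA` (family has no tRNA),
#' `AMBIGUOUS` (CAAH tied, unless the observed base matches WVH without
#' matching any tied complement).  A multi-anticodon family supports a
#' hypothesis if any of its wobble bases matches.
#'
#' @param family A `family_id`.
#' @param anticodons Character vector of anticodon triplets decoding the
#'   family (RNA, possibly empty/`NULL`).
#' @param fu The family's `family_usage`.
#' @param tau Threshold passed to [predict_wch()].
#' @return A `family_verdict` list: `family_id`, `degeneracy_class`,
#'   `observed_wobbles` (sorted unique bases), `wvh`, `caah`, `wch`,
#'   `support`.
#' @export
classify_family <- function(family, anticodons, fu, tau = 0.25) {
  f <- .family(family)
  wvh <- predict_wvh(family)
  caah <- predict_caah(fu)
  wch <- predict_wch(fu, tau)
  observed <- sort(unique(substr(anticodons, 1L, 1L)))

  support <- if (length(observed) == 0L) {
    "NO_TRNA"
  } else if (identical(caah, "AMBIGUOUS")) {
    mx <- max(fu$per_codon)
    tied <- names(fu$per_codon)[fu$per_codon == mx]
    tied_comp <- unname(.wc_complement[substr(tied, 3L, 3L)])
    if (any(observed == wvh) && !any(observed %in% tied_comp)) "WVH_ONLY"
    else "AMBIGUOUS"
  } else {
    m_wvh <- any(observed == wvh)
    m_caah <- !identical(caah, "NO_DATA") && any(observed == caah)
    if (identical(caah, wvh)) {
      if (m_wvh) "BOTH" else "NEITHER"
    } else if (m_wvh && m_caah) {
      "BOTH"      # heterogeneous repertoire matching two distinct predictions
    } else if (m_wvh) {
      "WVH_ONLY"
    } else if (m_caah) {
      "CAAH_ONLY"
    } else {
      "NEITHER"
    }
  }

  structure(list(
    family_id = f$family_id, degeneracy_class = f$degeneracy_class,
    observed_wobbles = observed, wvh = wvh, caah = caah, wch = wch,
    support = support
  ), class = "family_verdict")
}

#' Count hypothesis support over a verdict ledger
#'
#' Shipped convention (`"both-counts-wvh"`): `n_wvh` counts `WVH_ONLY`
#' and `BOTH` verdicts, `n_caah` counts `CAAH_ONLY` only.  The
#' `"exclusive"` convention counts only the `_ONLY` categories on both
#' sides.  The full ledger allows recounting under any convention.
#'
#' @param verdicts Data frame with a `support` column (as produced by
#'   [summarize_genome()]).
#' @param convention `"both-counts-wvh"` (default) or `"exclusive"`.
#' @return List with `n_wvh` and `n_caah`.
#' @export
count_support <- function(verdicts, convention = c("both-counts-wvh", "exclusive")) {
  convention <- match.arg(convention)
  s <- verdicts$support
  n_wvh <- sum(s == "WVH_ONLY") +
    if (identical(convention, "both-counts-wvh")) sum(s == "BOTH") else 0L
  list(n_wvh = n_wvh, n_caah = sum(s == "CAAH_ONLY"))
}

#' Summarize one mitogenome
#'
#' Runs the whole per-genome analysis: whole-genome and third-position
#' composition, codon usage, anticodon repertoire, and a verdict for each
#' of the 22 codon families, plus the tRNA-Met conflict statistics.
#'
#' @param record A `mito_record` with at least one CDS and one resolvable
#'   tRNA.
#' @param tau Wobble-cost threshold (see [predict_wch()]).
#' @param convention Counting convention (see [count_support()]).
#' @return A `genome_summary` list: `accession`, `organism`,
#'   `composition` (whole genome), `third_pos`, `usage` (`codon_usage`),
#'   `repertoire`, `verdicts` (data frame, one row per family), `n_wvh`,
#'   `n_caah`.
#' @export
summarize_genome <- function(record, tau = 0.25,
                             convention = c("both-counts-wvh", "exclusive")) {
  stopifnot(inherits(record, "mito_record"))
  convention <- match.arg(convention)
  cds <- extract_cds(record)
  if (length(cds) == 0L) stop(record$accession, ": no CDS features")
  trnas <- extract_trnas(record)
  usage <- count_codons(cds)
  repertoire <- anticodon_repertoire(trnas)

  fams <- codon_families()$family_id
  rows <- lapply(fams, function(fam) {
    v <- classify_family(fam, repertoire[[fam]], family_usage(usage, fam), tau)
    fu <- family_usage(usage, fam)
    data.frame(
      family_id = v$family_id,
      degeneracy_class = v$degeneracy_class,
      observed = paste(v$observed_wobbles, collapse = "/"),
      anticodons = paste(repertoire[[fam]] %||% character(0), collapse = "/"),
      wvh = v$wvh, caah = v$caah, wch = v$wch,
      n_A = fu$n_A, n_G = fu$n_G, n_C = fu$n_C, n_T = fu$n_T,
      na_ng_ratio = fu$na_ng_ratio,
      support = v$support,
      stringsAsFactors = FALSE
    )
  })
  verdicts <- do.call(rbind, rows)
  counts <- count_support(verdicts, convention)

  structure(list(
    accession = record$accession, organism = record$organism,
    composition = composition_stats(base_counts(record$sequence)),
    third_pos = third_position_stats(cds),
    usage = usage, repertoire = repertoire, verdicts = verdicts,
    n_wvh = counts$n_wvh, n_caah = counts$n_caah
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("<genome_summary> ", x$accession, "  ", x$organism, "\n", sep = "")
  cat(sprintf("  GT%% %.2f | AT skew %.2f | GC skew %.2f | 3rd-pos GT%% %.2f\n",
              x$composition$gt_percent, x$composition$at_skew,
              x$composition$gc_skew, x$third_pos$gt_percent))
  cat("  N_CAAH =", x$n_caah, " N_WVH =", x$n_wvh, "\n")
  invisible(x)
}
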