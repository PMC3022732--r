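# WVH / CAAH / WCH predictions and family classification

test_that("WVH prediction is the fixed 7 G / 15 U table", {
  fams <- codon_families()
  pred <- vapply(fams$family_id, predict_wvh, "")
  expect_equal(sum(pred == "G"), 7L)
  expect_equal(sum(pred == "U"), 15L)
  expect_true(all(pred[fams$degeneracy_class == "NNY"] == "G"))
  expect_true(all(pred[fams$degeneracy_class != "NNY"] == "U"))
  expect_equal(predict_wvh("Phe-UUY"), "G")
  expect_equal(predict_wvh("Trp-UGR"), "U")
  expect_equal(predict_wvh("Leu-CUN"), "U")
})

test_that("CAAH predicts the complement of the dominant third base", {
  expect_equal(predict_caah(family_usage(
    usage_from_counts(TGA = 10, TGG = 40), "Trp-UGR")), "C")
  expect_equal(predict_caah(family_usage(
    usage_from_counts(TTT = 50, TTC = 20), "Phe-UUY")), "A")
  expect_equal(predict_caah(family_usage(
    usage_from_counts(TGA = 7, TGG = 7), "Trp-UGR")), "AMBIGUOUS")
  expect_equal(predict_caah(family_usage(
    usage_from_counts(TTT = 1), "Trp-UGR")), "NO_DATA")
})

test_that("WCH predicts C only under strong G dominance in NNR families", {
  wch_at <- function(na, ng, tau = 0.25) predict_wch(
    family_usage(usage_from_counts(TGA = na, TGG = ng), "Trp-UGR"), tau)
  expect_equal(wch_at(98, 1000), "C")         # ratio 0.098
  expect_equal(wch_at(1244, 1000), "U")       # ratio 1.244
  expect_equal(wch_at(1, 4), "U")             # ratio == tau: strict inequality
  expect_equal(predict_wch(family_usage(
    usage_from_counts(TTT = 9), "Phe-UUY")), "NOT_APPLICABLE")
  expect_warning(res <- predict_wch(family_usage(
    usage_from_counts(TGA = 5), "Trp-UGR")), "n_G")
  expect_equal(res, "NOT_APPLICABLE")
})

test_that("family classification reproduces the canonical verdicts", {
  # NNY, observed G, T-ending dominant: WVH only
  v <- classify_family("Phe-UUY", "GAA",
                       family_usage(usage_from_counts(TTT = 50, TTC = 20), "Phe-UUY"))
  expect_equal(v$support, "WVH_ONLY")
  # Trp with CCA anticodon and UGG dominant: CAAH only (Pectinoida pattern)
  v <- classify_family("Trp-UGR", "CCA",
                       family_usage(usage_from_counts(TGA = 9, TGG = 41), "Trp-UGR"))
  expect_equal(v$support, "CAAH_ONLY")
  # Trp with UCA anticodon and UGA dominant: predictions coincide -> BOTH
  v <- classify_family("Trp-UGR", "UCA",
                       family_usage(usage_from_counts(TGA = 30, TGG = 10), "Trp-UGR"))
  expect_equal(v$support, "BOTH")
  # Ser-AGN with GCU anticodon: supports neither (Mytiloida pattern)
  v <- classify_family("Ser-AGN", "GCU",
                       family_usage(usage_from_counts(AGA = 40, AGT = 30, AGG = 10, AGC = 5),
                                    "Ser-AGN"))
  expect_equal(v$support, "NEITHER")
  # Met with lone CAU anticodon and AUA dominant: violates both
  v <- classify_family("Met-AUR", c("CAU", "CAU"),
                       family_usage(usage_from_counts(ATA = 60, ATG = 40), "Met-AUR"))
  expect_equal(v$support, "NEITHER")
  # no tRNA for the family
  v <- classify_family("Ser-AGN", NULL,
                       family_usage(usage_from_counts(AGA = 10), "Ser-AGN"))
  expect_equal(v$support, "NO_TRNA")
  # CAAH tie: ambiguous unless the WVH base is untied
  v <- classify_family("Trp-UGR", "UCA",
                       family_usage(usage_from_counts(TGA = 7, TGG = 7), "Trp-UGR"))
  expect_equal(v$support, "AMBIGUOUS")
  # NNY tie always leaves the wobble G among the tied complements
  v <- classify_family("Phe-UUY", "GAA",
                       family_usage(usage_from_counts(TTT = 7, TTC = 7), "Phe-UUY"))
  expect_equal(v$support, "AMBIGUOUS")
  # NNN tie between pyrimidine-ending codons: U is untied, WVH wins
  v <- classify_family("Leu-CUN", "UAG",
                       family_usage(usage_from_counts(CTT = 7, CTC = 7), "Leu-CUN"))
  expect_equal(v$support, "WVH_ONLY")
})

test_that("verdict flip: switching the Trp anticodon C<->U swaps the counts", {
  base <- synth_spec(profile = "pectinoida", seed = 406)  # UGG-dominant
  g1 <- suppressMessages(synth_genome(base))              # Trp anticodon CCA
  flipped <- base
  flipped$trna_set[["Trp-UGR"]] <- "UCA"
  g2 <- suppressMessages(synth_genome(flipped))

  v1 <- g1$truth$verdicts; v2 <- g2$truth$verdicts
  expect_equal(v1$support[v1$family_id == "Trp-UGR"], "CAAH_ONLY")
  expect_equal(v2$support[v2$family_id == "Trp-UGR"], "WVH_ONLY")
  expect_equal(g2$truth$n_wvh - g1$truth$n_wvh, 1L)
  expect_equal(g2$truth$n_caah - g1$truth$n_caah, -1L)
  # the full pipeline agrees with the planted verdicts
  s2 <- suppressWarnings(suppressMessages(summarize_genome(g2$record)))
  expect_equal(s2$verdicts$support, v2$support)
})

test_that("summaries have exactly 22 mutually exclusive verdicts", {
  g <- suppressMessages(synth_genome(synth_spec(seed = 407)))
  s <- suppressWarnings(suppressMessages(summarize_genome(g$record)))
  expect_equal(nrow(s$verdicts), 22L)
  expect_equal(anyDuplicated(s$verdicts$family_id), 0L)
  expect_true(all(s$verdicts$support %in%
    c("WVH_ONLY", "CAAH_ONLY", "BOTH", "NEITHER", "NO_TRNA", "AMBIGUOUS")))
  cnt_b <- count_support(s$verdicts, "both-counts-wvh")
  cnt_x <- count_support(s$verdicts, "exclusive")
  expect_equal(cnt_b$n_wvh - cnt_x$n_wvh, sum(s$verdicts$support == "BOTH"))
  expect_equal(cnt_b$n_caah, cnt_x$n_caah)
})
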