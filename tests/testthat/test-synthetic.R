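# synthetic mitogenome generator: determinism, planted-truth recovery,
# composition control, lineage profiles

test_that("generation is deterministic and byte-identical under a seed", {
  g1 <- suppressMessages(synth_genome(synth_spec(seed = 501)))
  g2 <- suppressMessages(synth_genome(synth_spec(seed = 501)))
  p1 <- tempfile(); p2 <- tempfile()
  write_genbank(g1$record, p1); write_genbank(g2$record, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the sequence
  g3 <- suppressMessages(synth_genome(synth_spec(seed = 502)))
  expect_false(identical(g1$record$sequence, g3$record$sequence))
})

test_that("zero intergenic length gives a genome of exactly the gene lengths", {
  spec <- synth_spec(seed = 503, intergenic_length = 0)
  g <- suppressMessages(synth_genome(spec))
  n_codons <- sum(vapply(spec$codon_counts, sum, 0))
  n_trnas <- length(unlist(spec$trna_set))
  expect_equal(g$record$length, 3 * n_codons + 3 * spec$n_cds + 70 * n_trnas)
})

test_that("stop codons in planted counts are rejected", {
  expect_error(synth_spec(codon_counts = list("Tyr-UAY" = c(TAT = 5, TAA = 1)),
                          seed = 1), "stop")
  expect_error(synth_spec(codon_counts = list("Phe-UUY" = c(TTA = 5)),
                          seed = 1), "belong")
})

test_that("whole-genome GT fraction tracks the spec target", {
  for (target in c(0.56, 0.60, 0.64)) {
    g <- suppressMessages(synth_genome(
      synth_spec(seed = 504 + round(100 * target),
                 intergenic_gt_fraction = target, intergenic_length = 4000)))
    expect_gte(g$record$length, 10000)
    gt <- composition_stats(base_counts(g$record$sequence))$gt_percent
    expect_lt(abs(gt - 100 * target), 2, label = paste("target", target))
  }
})

test_that("full-pipeline identity holds over a broad fixture suite", {
  # >= 20 specs: three lineage profiles, ties, missing Ser-AGN tRNA,
  # duplicated Met, a family with zero usage, heterogeneous Met wobbles
  specs <- list()
  for (i in 1:5) specs[[length(specs) + 1L]] <-
    synth_spec("ostreoida", seed = 510 + i)
  for (i in 1:5) specs[[length(specs) + 1L]] <-
    synth_spec("pectinoida", seed = 520 + i)
  for (i in 1:5) specs[[length(specs) + 1L]] <-
    synth_spec("mytiloida", seed = 530 + i)

  no_agn <- default_trna_set()
  no_agn[["Ser-AGN"]] <- NULL
  specs[[length(specs) + 1L]] <- synth_spec(trna_set = no_agn, seed = 541)

  many_met <- default_trna_set()
  many_met[["Met-AUR"]] <- c(rep("CAU", 4), rep("UAU", 5))
  specs[[length(specs) + 1L]] <- synth_spec(trna_set = many_met, seed = 542)

  tie_counts <- list("Trp-UGR" = c(TGA = 7, TGG = 7),
                     "Leu-UUR" = c(TTA = 30, TTG = 20),
                     "Met-AUR" = c(ATA = 20, ATG = 20),
                     "Phe-UUY" = c(TTT = 40, TTC = 10))
  specs[[length(specs) + 1L]] <- synth_spec(codon_counts = tie_counts,
                                            n_cds = 3, seed = 543)

  zero_fam <- list("Phe-UUY" = c(TTT = 60, TTC = 10),
                   "Leu-UUR" = c(TTA = 25, TTG = 12),
                   "Met-AUR" = c(ATA = 9, ATG = 11))
  specs[[length(specs) + 1L]] <- synth_spec(codon_counts = zero_fam,
                                            n_cds = 2, seed = 544)

  hetero_met <- default_trna_set()
  hetero_met[["Met-AUR"]] <- c("CAU", "UAU")
  specs[[length(specs) + 1L]] <- synth_spec(trna_set = hetero_met, seed = 545)

  specs[[length(specs) + 1L]] <- synth_spec(n_cds = 1, seed = 546,
                                            intergenic_length = 100)

  expect_gte(length(specs), 20L)
  for (k in seq_along(specs)) {
    g <- suppressWarnings(suppressMessages(synth_genome(specs[[k]])))
    s <- suppressWarnings(suppressMessages(summarize_genome(g$record)))
    expect_identical(s$usage$counts, g$truth$counts, info = paste("spec", k))
    expect_equal(s$verdicts$support, g$truth$verdicts$support,
                 info = paste("spec", k))
    expect_equal(c(s$n_wvh, s$n_caah), c(g$truth$n_wvh, g$truth$n_caah),
                 info = paste("spec", k))
    m <- suppressWarnings(suppressMessages(met_summary(g$record)))
    expect_equal(m$p_uua, g$truth$p_uua, info = paste("spec", k))
    expect_equal(m$p_aua, g$truth$p_aua, info = paste("spec", k))
    expect_equal(m$group, g$truth$group, info = paste("spec", k))
  }
})

test_that("lineage profiles carry their anticodon signatures", {
  pect <- make_paperlike_cohort("pectinoida", n = 3, seed = 601)
  for (g in pect) {
    v <- g$truth$verdicts
    expect_equal(v$support[v$family_id == "Trp-UGR"], "CAAH_ONLY")
    fu <- family_usage(suppressMessages(count_codons(extract_cds(g$record))),
                       "Trp-UGR")
    expect_true(fu$na_ng_ratio >= 0.098 - 0.05 && fu$na_ng_ratio <= 0.226 + 0.05)
  }
  myt <- make_paperlike_cohort("mytiloida", n = 3, seed = 602)
  for (g in myt) {
    v <- g$truth$verdicts
    expect_equal(v$support[v$family_id == "Ser-AGN"], "NEITHER")
    expect_equal(g$truth$group, "HAS_UAU")
  }
  ost <- make_paperlike_cohort("ostreoida", n = 3, seed = 603)
  for (g in ost) {
    v <- g$truth$verdicts
    expect_true(v$support[v$family_id == "Trp-UGR"] %in% c("WVH_ONLY", "BOTH"))
    expect_equal(g$truth$group, "CAU_ONLY")
  }
})
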