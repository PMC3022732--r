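---
title: "Testing wobble-site hypotheses on mitochondrial tRNA anticodons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing wobble-site hypotheses on mitochondrial tRNA anticodons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitowobble)
```

## The model

Mitochondrial genomes of marine bivalves encode every gene on one
strand (the H strand), which accumulates a strand-specific mutation
bias toward G and T.  Each synonymous codon family — the set of sense
codons sharing their first two positions — is decoded by a single tRNA
whose anticodon wobble base (position 34, the 5' base of the anticodon
written 5'→3') must pair with every third-position base the family
uses.  Under the invertebrate mitochondrial code (translation table 5)
there are 22 such families over the 62 sense codons: 9 fourfold
quartets (NNN, including Ser-AGN because AGA/AGG are serine codons in
this code), 7 pyrimidine-ending pairs (NNY) and 6 purine-ending pairs
(NNR).  The only stop codons are UAA and UAG.

Three hypotheses predict the wobble base per family:

* **Wobble versatility (WVH).**  G for NNY families, because G pairs
  both C and U; U for NNR and NNN families, because U is the most
  versatile wobble pairer.  This prediction is a fixed table — 7 G and
  15 U — independent of codon usage.
* **Codon-anticodon adaptation (CAAH).**  The Watson-Crick complement
  of the third base of the family's most abundant codon.  An exact
  count tie yields an `AMBIGUOUS` prediction rather than an arbitrary
  winner; an unused family yields `NO_DATA`.
* **Wobble cost (WCH).**  Defined for NNR families only.  When the
  A-ending codon is much rarer than the G-ending codon
  (n_A/n_G below a threshold τ), a wobble U would mostly wobble-pair
  against G-ending codons at high cost, and C is predicted; otherwise
  U.  Only the qualitative decision rule is implemented; no cost
  magnitudes are estimated.

The per-family verdict compares the set of observed wobble bases (all
anticodons decoding the family, so duplicated isoacceptors contribute
a set) with the WVH and CAAH predictions: `WVH_ONLY` and `CAAH_ONLY`
when exactly one of two distinct predictions is matched, `BOTH` when
both are matched (normally because the predictions coincide, e.g. a
wobble U facing A-dominant usage in an NNR family), `NEITHER`,
`NO_TRNA` when the family has no tRNA, and `AMBIGUOUS` when CAAH is
tied — unless the observed base matches WVH while matching none of the
tied complements, in which case the verdict is `WVH_ONLY`.

## The tRNA-Met conflict statistics

The Met family (AUR) is the systematic exception: its anticodon is
typically CAU, matching AUG, although AUA is usually the more frequent
codon.  The translation initiation/elongation conflict explanation is
that AUG is the efficient initiation codon, so a lone CAU anticodon is
maintained by initiation despite its elongation cost, imposing
selection against AUA.  The testable signal is

P_UUA = 100·N(UUA)/(N(UUA)+N(UUG)),  P_AUA = 100·N(AUA)/(N(AUA)+N(AUG)),

where the UUR family (read by a wobble-U anticodon) serves as the
unconstrained baseline.  Genomes whose only Met anticodon is CAU are
predicted to show P_UUA − P_AUA > 0; genomes that also carry a
UAU-tRNA-Met (group `HAS_UAU`) are released from the conflict.  Group
means are unweighted row means, with an overall `ALL` row over every
genome regardless of group.

## Parameters and conventions

* **τ (wobble-cost threshold), default 0.25, strict inequality.**
  Chosen once so that the UGG-dominant regime reported for Pectinoida
  Trp-UGR usage (n_A/n_G between 0.098 and 0.226) predicts C while all
  other reported ratios (0.44–2.382) predict U.  At the boundary
  (ratio = τ) the prediction is U.  `predict_wch(fu, tau = ...)` and
  `run_pipeline(..., tau = ...)` override it.
* **Counting convention for N_WVH/N_CAAH, default `both-counts-wvh`.**
  N_WVH counts `WVH_ONLY` and `BOTH` verdicts; N_CAAH counts
  `CAAH_ONLY` only.  In a GT-biased genome the two predictions coincide
  for many families (T-ending dominance makes CAAH predict A for NNY
  and U for many NNR families), so a purely exclusive count would
  understate WVH support; the exclusive convention is available as
  `"exclusive"`, and the full verdict ledger (`verdicts.tsv`) allows
  recounting under any convention.
* **Counting scope.**  Codon counts include start codons (no special
  casing; at most one codon per gene) and exclude stop codons,
  N-containing codons and incomplete trailing codons (annotation
  dialects with polyadenylation-completed stops leave a 1–2 nt
  fragment, which is not a codon).  Third-position composition uses
  exactly this codon set, so the composition and codon-usage modules
  agree.  Whole-genome composition uses the full deposited strand,
  non-coding regions included, and the deposited strand is never
  silently complemented.
* **Anticodon resolution priority.**  `/anticodon` qualifier triplet,
  then the slice at the annotated anticodon position, then inference:
  a scan of the central third of the gene (the anticodon loop of a
  ~70 nt cloverleaf gene lies near the middle; restricting the window
  avoids acceptor-stem false hits) for a triplet decoding a family of
  the annotated amino acid, the candidate closest to the gene centre
  winning.  When qualifier and slice disagree the qualifier wins and
  the discrepancy is logged.  When the annotated amino acid and the
  anticodon disagree, the anticodon decides the family, with a warning
  — annotation errors of this kind occur in public records, so
  validation is part of the pipeline rather than an afterthought.

## The synthetic generator

`synth_spec()` fixes, deterministically under one seed, planted codon
counts (multinomial per family), a tRNA set, and an intergenic
composition target; `synth_genome()` shuffles the planted codons into
`n_cds` genes (each closed by a UAA/UAG stop), writes one 70-nt tRNA
gene per planted anticodon with the triplet at a fixed central offset
and a positional `/anticodon` qualifier, and appends an intergenic
spacer whose base composition steers the whole genome toward the
target G+T fraction (clamped to what the spacer length can absorb).
Defaults emulate the statistical structure of marine bivalve
mitogenomes: 12 CDS (no ATP8, which most marine bivalves lack),
T-ending dominance in NNY/NNN families, a Leu-UUR A-share of 0.64 and
a Met-AUR A-share of 0.55 (0.67 under the conflict-released mytiloida
profile), a whole-genome G+T target of 0.60, and the three lineage
profiles: `ostreoida` (UCA-Trp, UCU-Ser(AGN), CAU/CAU-Met),
`pectinoida` (CCA-Trp with Trp-UGR n_A/n_G drawn in [0.098, 0.226])
and `mytiloida` (GCU-Ser(AGN), CAU+UAU Met pair).

What the generator does *not* emulate: cloverleaf secondary structure,
rRNA genes, genome rearrangement, within-gene codon autocorrelation,
or mutational evolution.  Passing planted-truth tests therefore shows
that the pipeline's arithmetic and bookkeeping are exact on genomes
with the planted statistical structure — not that the biological
hypotheses are true of real data, which is what the published
29-genome summary tables under `inst/extdata/` are for.

Anticodon placement uses rejection sampling: a tRNA flank that happens
to contain a competing triplet (decoding a family of the same amino
acid at least as close to the gene centre) is redrawn, so that
anticodon inference has a unique correct answer on every synthetic
gene.

## Numerical and degenerate-input choices

* Skews with a zero denominator, P values with an empty codon pair,
  and all statistics of an empty sequence are `NA`, never 0; undefined
  P values are excluded from group means with a warning.
* No internal rounding anywhere; 2-decimal formatting happens only at
  report (TSV) time, with ASCII hyphens for negative values.
* Ties in `most_abundant_codon` return an explicit `TIE` marker that
  propagates to an `AMBIGUOUS` CAAH prediction.
* Internal coordinates are 0-based half-open, converted exactly once
  at the GenBank boundary (1-based inclusive); minus-strand and
  origin-spanning `join()` locations are resolved at parse time.
* DNA is the single internal alphabet; RNA (U) appears only in
  anticodon/codon display and the tRNA sequence field.

## Problem sizes

The test suite generates synthetic genomes of roughly 12–14 kb (about
3 200 planted codons over 12 CDS and 23 tRNA genes); the fixture suite
covers 20 specs (three lineage profiles, count ties, a missing
Ser-AGN tRNA, nine Met genes, heterogeneous Met wobbles, single-gene
genomes) and recovery is asserted integer-exact for counts and
category-exact for verdicts.  The acceptance script runs a six-genome
cohort.  These sizes match one real mitogenome per record, so the
suite exercises the same scale the pipeline targets in practice.

## Known limitations

* De novo tRNA detection is out of scope: a tRNA gene absent from the
  annotation is invisible, and a mis-annotated anticodon can only be
  corrected when the gene sequence or qualifier allows it.
* The support enum has no separate category for a heterogeneous
  repertoire matching two *distinct* predictions (possible only with
  multiple different wobble bases in one family, e.g. Met {C, U} with
  AUG-dominant usage); the package classifies this as `BOTH`, reading
  it as "the repertoire supports both hypotheses", and the ledger
  preserves the full wobble set for recounting.
* N_WVH/N_CAAH depend on the counting convention; published per-genome
  counts assembled under an undocumented convention may differ from a
  recount even when every verdict agrees.
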