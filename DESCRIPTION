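Package: mitowobble
Title: Wobble Nucleotides of Mitochondrial tRNA Anticodons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of the wobble nucleotide (position 34) of
    mitochondrial tRNA anticodons from annotated mitogenome records.  Parses
    GenBank flat files, computes strand composition statistics (GT content,
    AT and GC skew), tallies codon usage by synonymous codon family under the
    invertebrate mitochondrial genetic code (translation table 5), resolves
    and validates tRNA anticodons, and classifies every codon family against
    the codon-anticodon adaptation hypothesis (CAAH), the wobble versatility
    hypothesis (WVH) and the wobble cost hypothesis (WCH).  Includes the
    tRNA-Met translation initiation/elongation conflict statistics (P_UUA,
    P_AUA) and a fully seeded synthetic mitogenome generator with planted
    ground truth for end-to-end testing without network access.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Collate:
    'genetic-code.R'
    'genbank-io.R'
    'composition.R'
    'codon-usage.R'
    'anticodon.R'
    'hypothesis.R'
    'met-conflict.R'
    'synthetic.R'
    'reference-data.R'
    'report.R'
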