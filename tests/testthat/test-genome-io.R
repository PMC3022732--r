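# GenBank parsing, coordinate conversion, strand handling, extraction

test_that("toy GenBank record parses with converted coordinates", {
  rec <- parse_genbank(write_toy_genbank())[[1]]
  expect_s3_class(rec, "mito_record")
  expect_equal(rec$accession, "TOY0001")
  expect_equal(rec$organism, "Toyorganism toyensis")
  expect_equal(rec$length, 60L)
  expect_equal(rec$topology, "circular")
  expect_equal(nchar(rec$sequence), rec$length)

  kinds <- vapply(rec$features, `[[`, "", "kind")
  cds <- rec$features[[which(kinds == "CDS")]]
  # GenBank 1..9 becomes 0-based half-open [0, 9)
  expect_equal(c(cds$start, cds$end), c(0L, 9L))
  expect_equal(cds$strand, "+")
  expect_equal(cds$qualifiers$transl_table, "5")
})

test_that("complement() features extract the reverse complement", {
  rec <- parse_genbank(write_toy_genbank())[[1]]
  f <- structure(list(kind = "CDS", name = "rev", start = 9L, end = 18L,
                      strand = "-", wrap = FALSE, parts = list(c(9L, 18L)),
                      qualifiers = list()), class = "gene_feature")
  fwd <- substr(rec$sequence, 10, 18)
  expect_equal(feature_sequence(rec, f), reverse_complement(fwd))
  # involution: extracting the complement of the complement restores it
  expect_equal(reverse_complement(feature_sequence(rec, f)), fwd)
})

test_that("CDS extraction drops incomplete trailing codons and flags stops", {
  g <- extract_cds(parse_genbank(write_toy_genbank())[[1]])
  expect_length(g, 1L)
  expect_equal(g[[1]]$nt_sequence, "ATGTTAGGT")
  expect_equal(length(split_codons(g[[1]]$nt_sequence)), 3L)

  # 13-nt CDS: trailing 1 nt dropped, 4 codons usable
  rec <- parse_genbank(write_toy_genbank())[[1]]
  rec$features <- list(structure(list(
    kind = "CDS", name = "frag", start = 0L, end = 13L, strand = "+",
    wrap = FALSE, parts = list(c(0L, 13L)), qualifiers = list()),
    class = "gene_feature"))
  expect_message(g2 <- extract_cds(rec), "trailing")
  expect_equal(nchar(g2[[1]]$nt_sequence), 12L)

  # internal stop warns but keeps the gene
  rec$sequence <- paste0("ATGTAATTAGGG", strrep("A", 48))
  rec$features[[1]]$end <- 12L
  rec$features[[1]]$parts <- list(c(0L, 12L))
  expect_warning(g3 <- extract_cds(rec), "internal stop")
  expect_length(g3, 1L)
})

test_that("tRNA extraction reads product, qualifier anticodon and offset", {
  rec <- parse_genbank(write_toy_genbank())[[1]]
  trnas <- extract_trnas(rec)
  expect_length(trnas, 1L)
  t1 <- trnas[[1]]
  expect_equal(t1$amino_acid, "Trp")
  expect_equal(t1$annotated_anticodon, "UCA")
  expect_equal(t1$anticodon_offset, 9L)
  # offset points at the anticodon within the gene (RNA convention)
  expect_equal(substr(t1$nt_sequence, 10, 12), "UCA")
})

test_that("duplicate tRNAs and missing isoacceptors are preserved as-is", {
  tset <- default_trna_set("mytiloida")
  tset[["Ser-AGN"]] <- NULL                     # missing isoacceptor
  spec <- synth_spec(profile = "mytiloida", trna_set = tset, seed = 11)
  g <- suppressMessages(synth_genome(spec))
  trnas <- extract_trnas(g$record)
  mets <- Filter(function(x) identical(x$amino_acid, "Met"), trnas)
  expect_length(mets, 2L)
  rep <- anticodon_repertoire(trnas)
  expect_false("Ser-AGN" %in% names(rep))
  expect_setequal(rep[["Met-AUR"]], c("CAU", "UAU"))
})

test_that("write_genbank round-trips the internal model", {
  spec <- synth_spec(seed = 7, intergenic_length = 500)
  g <- suppressMessages(synth_genome(spec))
  path <- tempfile(fileext = ".gbk")
  write_genbank(g$record, path)
  r2 <- parse_genbank(path)[[1]]
  expect_equal(r2$accession, g$record$accession)
  expect_equal(r2$organism, g$record$organism)
  expect_equal(r2$sequence, g$record$sequence)
  expect_equal(r2$topology, g$record$topology)
  for (i in seq_along(g$record$features)) {
    a <- g$record$features[[i]]; b <- r2$features[[i]]
    expect_equal(b$kind, a$kind)
    expect_equal(c(b$start, b$end, b$strand), c(a$start, a$end, a$strand))
  }
  # second write of the re-parsed record is byte-identical
  path2 <- tempfile(fileext = ".gbk")
  write_genbank(r2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed input errors name the problem", {
  p <- tempfile()
  writeLines(c("LOCUS       BAD001   30 bp DNA circular",
               "FEATURES             Location/Qualifiers",
               "     CDS             5..1"), p)
  expect_error(parse_genbank(p), "ORIGIN")
  expect_error(parse_genbank(tempfile()), "not found")
})

test_that("minus-strand features survive a write/parse cycle", {
  rec <- parse_genbank(write_toy_genbank())[[1]]
  rec$features[[2]] <- structure(list(
    kind = "CDS", name = "NDR", start = 9L, end = 18L, strand = "-",
    wrap = FALSE, parts = list(c(9L, 18L)),
    qualifiers = list(gene = "NDR")), class = "gene_feature")
  path <- tempfile(fileext = ".gbk")
  write_genbank(rec, path)
  txt <- readLines(path)
  expect_true(any(grepl("complement\\(10\\.\\.18\\)", txt)))
  r2 <- parse_genbank(path)[[1]]
  expect_equal(r2$features[[2]]$strand, "-")
  expect_equal(feature_sequence(r2, r2$features[[2]]),
               reverse_complement(substr(rec$sequence, 10, 18)))
})
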