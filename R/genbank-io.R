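# GenBank flat-file reader/writer for annotated mitogenomes.
#
# Scope: LOCUS/ACCESSION/ORGANISM header fields, the FEATURES table with
# simple, complement(), and join() locations (including origin-spanning
# joins on circular molecules), qualifiers, and the ORIGIN sequence block.
# Coordinates are converted once, at this boundary, from GenBank 1-based
# inclusive to internal 0-based half-open.

#' Parse a GenBank flat file into mitogenome records
#'
#' Reads one or more `LOCUS` records from a GenBank flat file.  Feature
#' locations (`a..b`, `complement(...)`, `join(...)`, partial markers
#' `<`/`>`) are resolved to 0-based half-open intervals on the deposited
#' strand; origin-spanning joins on circular molecules are kept as parts
#' and flagged `wrap`.  The sequence is uppercased with `U` mapped to `T`.
#'
#' @param path Path to a `.gb`/`.gbk` file (single- or multi-record).
#' @return A list of `mito_record` objects, one per LOCUS, each with
#'   `accession`, `organism`, `sequence`, `length`, `topology` and
#'   `features` (a list of `gene_feature`).
#' @seealso [write_genbank()], [extract_cds()], [extract_trnas()]
#' @export
parse_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- list()
  for (k in seq_along(ends)) {
    chunk <- lines[starts[k]:ends[k]]
    chunk <- chunk[nzchar(trimws(chunk)) | seq_along(chunk) == 1L]
    if (!any(grepl("^LOCUS", chunk))) next
    recs[[length(recs) + 1L]] <- .parse_record(chunk, path)
  }
  if (length(recs) == 0L) stop("no GenBank records found in ", path)
  recs
}

.parse_record <- function(lines, path) {
  locus_i <- grep("^LOCUS", lines)[1]
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i])), "\\s+")[[1]]
  locus_name <- locus[1]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  acc_i <- grep("^ACCESSION", lines)
  accession <- if (length(acc_i)) {
    strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1]])), "\\s+")[[1]][1]
  } else locus_name
  if (is.na(accession) || !nzchar(accession)) accession <- locus_name

  org_i <- grep("^\\s{2}ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^\\s*ORGANISM", "", lines[org_i[1]])) else ""

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L)
    stop("record '", locus_name, "' in ", path, ": missing ORIGIN sequence block")

  sequence <- .parse_origin(lines[(orig_i[1] + 1L):length(lines)])
  len <- nchar(sequence)

  features <- list()
  if (length(feat_i)) {
    last <- orig_i[1] - 1L
    if (last > feat_i[1]) {
      features <- .parse_features(lines[(feat_i[1] + 1L):last], len, locus_name)
    }
  }

  structure(list(
    accession = accession, organism = organism, sequence = sequence,
    length = len, topology = topology, features = features
  ), class = "mito_record")
}

.parse_origin <- function(lines) {
  stop_i <- grep("^//", lines)
  if (length(stop_i)) lines <- lines[seq_len(stop_i[1] - 1L)]
  seq <- gsub("[^A-Za-z]", "", paste(lines, collapse = ""))
  chartr("Uu", "Tt", toupper(seq))
}

.parse_features <- function(lines, genome_len, locus_name) {
  # feature keys start at column 6; locations/qualifiers continue at col 22
  key_i <- grep("^\\s{5}\\S", lines)
  if (length(key_i) == 0L) return(list())
  feats <- list()
  bounds <- c(key_i, length(lines) + 1L)
  for (j in seq_along(key_i)) {
    block <- lines[key_i[j]:(bounds[j + 1L] - 1L)]
    head_parts <- strsplit(trimws(block[1]), "\\s+")[[1]]
    key <- head_parts[1]
    rest <- block[-1]
    # location may continue over lines until the first qualifier
    qual_start <- grep("^\\s*/", rest)
    loc_extra <- if (length(qual_start)) {
      if (qual_start[1] > 1L) rest[seq_len(qual_start[1] - 1L)] else character(0)
    } else rest
    loc_text <- paste0(paste(head_parts[-1], collapse = ""),
                       paste(trimws(loc_extra), collapse = ""))
    qual_lines <- if (length(qual_start)) rest[qual_start[1]:length(rest)] else character(0)
    qualifiers <- .parse_qualifiers(qual_lines)

    loc <- tryCatch(.parse_location(loc_text, genome_len),
                    error = function(e) stop("record '", locus_name,
                      "', feature ", key, " at '", loc_text, "': ",
                      conditionMessage(e)))
    kind <- if (key %in% c("CDS", "tRNA", "rRNA")) key else "other"
    name <- qualifiers[["gene"]]
    if (is.null(name)) name <- qualifiers[["product"]]
    if (is.null(name)) name <- key
    feats[[length(feats) + 1L]] <- structure(list(
      kind = kind, name = name,
      start = loc$parts[[1]][1], end = loc$parts[[length(loc$parts)]][2],
      strand = loc$strand, wrap = loc$wrap, parts = loc$parts,
      qualifiers = qualifiers
    ), class = "gene_feature")
  }
  feats
}

.parse_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  lines <- trimws(lines)
  # merge continuation lines (those not starting a new qualifier)
  merged <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "/") || length(merged) == 0L) merged <- c(merged, ln)
    else merged[length(merged)] <- paste(merged[length(merged)], ln)
  }
  quals <- list()
  for (q in merged) {
    m <- regmatches(q, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", q))[[1]]
    if (length(m) == 0L) next
    key <- m[2]
    val <- if (nzchar(m[3])) gsub('^"|"$', "", m[4]) else ""
    quals[[key]] <- val
  }
  quals
}

# Parse a GenBank location string into strand, wrap flag and 0-based
# half-open parts (in reading order on the deposited strand).
.parse_location <- function(text, genome_len) {
  text <- gsub("\\s", "", text)
  strand <- "+"
  if (grepl("^complement\\(", text)) {
    strand <- "-"
    text <- sub("^complement\\((.*)\\)$", "\\1", text)
  }
  if (grepl("^(join|order)\\(", text)) {
    text <- sub("^(join|order)\\((.*)\\)$", "\\2", text)
  }
  segs <- strsplit(text, ",")[[1]]
  parts <- lapply(segs, function(s) {
    s <- gsub("[<>]", "", s)
    if (grepl("^[0-9]+$", s)) {
      p <- as.integer(s); return(c(p - 1L, p))
    }
    m <- regmatches(s, regexec("^([0-9]+)\\.\\.([0-9]+)$", s))[[1]]
    if (length(m) == 0L) stop("unsupported location segment '", s, "'")
    a <- as.integer(m[2]); b <- as.integer(m[3])
    if (a > b) stop("inverted interval ", s)
    c(a - 1L, b)
  })
  for (p in parts) {
    if (p[1] < 0L || p[2] > genome_len)
      stop("coordinates outside [1, ", genome_len, "]")
  }
  wrap <- length(parts) > 1L &&
    any(diff(vapply(parts, `[`, integer(1), 1L)) < 0L)
  list(strand = strand, wrap = wrap, parts = parts)
}

# Sequence of a feature in reading orientation (concatenate parts on the
# deposited strand, then reverse-complement for '-' features).
feature_sequence <- function(record, feature) {
  segs <- vapply(feature$parts, function(p) {
    substr(record$sequence, p[1] + 1L, p[2])
  }, character(1))
  s <- paste(segs, collapse = "")
  if (identical(feature$strand, "-")) reverse_complement(s) else s
}

# ---- gene extraction ------------------------------------------------------

#' Extract protein-coding genes from a mitogenome record
#'
#' One `coding_gene` per CDS feature, with its nucleotide sequence in
#' reading orientation.  Trailing bases that do not form a complete codon
#' (incomplete stop codons completed by polyadenylation) are dropped with
#' a message.  Internal stop codons under translation table 5 raise a
#' warning but the gene is retained.
#'
#' @param record A `mito_record` from [parse_genbank()].
#' @return List of `coding_gene` objects (`name`, `nt_sequence`,
#'   `complete_stop`).
#' @export
extract_cds <- function(record) {
  stopifnot(inherits(record, "mito_record"))
  out <- list()
  for (f in record$features) {
    if (!identical(f$kind, "CDS")) next
    s <- feature_sequence(record, f)
    extra <- nchar(s) %% 3L
    if (extra > 0L) {
      message("CDS ", f$name, " (", record$accession, "): dropping ", extra,
              " trailing nt not forming a complete codon")
      s <- substr(s, 1L, nchar(s) - extra)
    }
    codons <- split_codons(s)
    internal <- which(is_stop_codon(codons))
    internal <- internal[internal < length(codons)]
    if (length(internal))
      warning("CDS ", f$name, " (", record$accession, "): ",
              length(internal), " internal stop codon(s) under code 5",
              call. = FALSE)
    complete_stop <- length(codons) > 0L && is_stop_codon(codons[length(codons)])
    out[[length(out) + 1L]] <- structure(list(
      name = f$name, nt_sequence = s, complete_stop = complete_stop
    ), class = "coding_gene")
  }
  out
}

# amino-acid name lookup for tRNA products ("tRNA-Ser", "trnS", ...)
.aa_by_name <- local({
  full <- c(Ala = "Alanine", Arg = "Arginine", Asn = "Asparagine",
            Asp = "Aspartate", Cys = "Cysteine", Gln = "Glutamine",
            Glu = "Glutamate", Gly = "Glycine", His = "Histidine",
            Ile = "Isoleucine", Leu = "Leucine", Lys = "Lysine",
            Met = "Methionine", Phe = "Phenylalanine", Pro = "Proline",
            Ser = "Serine", Thr = "Threonine", Trp = "Tryptophan",
            Tyr = "Tyrosine", Val = "Valine")
  one <- setdiff(names(.aa3), "*")
  names(one) <- unname(.aa3[one])
  list(full = full, one = one)
})

.trna_amino_acid <- function(name) {
  if (is.null(name) || !nzchar(name)) return(NA_character_)
  for (aa in names(.aa_by_name$full)) {
    if (grepl(aa, name, ignore.case = TRUE) ||
        grepl(.aa_by_name$full[[aa]], name, ignore.case = TRUE))
      return(aa)
  }
  # trnS / trnS1 dialect: single letter after 'trn'
  m <- regmatches(name, regexec("^trn([A-Za-z])", name))[[1]]
  if (length(m) && toupper(m[2]) %in% names(.aa3)) {
    return(unname(.aa3[toupper(m[2])]))
  }
  NA_character_
}

#' Extract tRNA genes from a mitogenome record
#'
#' One `trna_gene` per tRNA feature.  The amino acid is inferred from the
#' `/product` or gene name; a `/anticodon` qualifier is parsed in both the
#' `(pos:x..y,aa:Trp,seq:tca)` and bare `seq:tca` dialects, yielding both
#' the annotated triplet and its 0-based offset within the gene when the
#' position is given.  Duplicated tRNAs for one amino acid are all kept.
#'
#' @param record A `mito_record`.
#' @return List of `trna_gene` objects: `amino_acid` (three-letter code or
#'   `NA` with a warning when unparseable), `isoacceptor_label`,
#'   `nt_sequence` (RNA convention, reading orientation),
#'   `annotated_anticodon` (RNA, 5'->3') and `anticodon_offset` (or `NA`).
#' @export
extract_trnas <- function(record) {
  stopifnot(inherits(record, "mito_record"))
  out <- list()
  for (f in record$features) {
    if (!identical(f$kind, "tRNA")) next
    s <- feature_sequence(record, f)
    name <- f$qualifiers[["product"]]
    if (is.null(name)) name <- f$name
    aa <- .trna_amino_acid(name)
    if (is.na(aa))
      warning("tRNA feature '", name, "' (", record$accession,
              "): cannot infer amino acid", call. = FALSE)
    anticodon <- NA_character_
    offset <- NA_integer_
    q <- f$qualifiers[["anticodon"]]
    if (!is.null(q)) {
      mseq <- regmatches(q, regexec("seq:([acgtuACGTU]{3})", q))[[1]]
      if (length(mseq)) anticodon <- as_rna(toupper(mseq[2]))
      mpos <- regmatches(q, regexec("pos:(complement\\()?([0-9]+)\\.\\.([0-9]+)", q))[[1]]
      if (length(mpos)) {
        a <- as.integer(mpos[3]); b <- as.integer(mpos[4])
        offset <- if (identical(f$strand, "-")) f$end - b else a - 1L - f$start
        if (is.na(offset) || offset < 0L || offset + 3L > nchar(s)) offset <- NA_integer_
      }
    }
    label <- name
    out[[length(out) + 1L]] <- structure(list(
      amino_acid = aa, isoacceptor_label = label,
      nt_sequence = as_rna(s),
      annotated_anticodon = anticodon, anticodon_offset = offset
    ), class = "trna_gene")
  }
  out
}

# ---- writer ---------------------------------------------------------------

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits a flat file that [parse_genbank()] reads back with full fidelity
#' of every field the pipeline consumes (round-trip identity).  The LOCUS
#' date is a fixed constant so that output is byte-identical across runs.
#'
#' @param record A `mito_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "mito_record"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %6d bp    DNA     %-8s INV 01-JAN-2000",
            record$accession, record$length, record$topology))
  w("DEFINITION  ", record$organism, " mitochondrion, complete genome.")
  w("ACCESSION   ", record$accession)
  w("SOURCE      mitochondrion ", record$organism)
  w("  ORGANISM  ", record$organism)
  w("FEATURES             Location/Qualifiers")
  for (f in record$features) {
    loc <- .format_location(f)
    w(sprintf("     %-16s%s", .feature_key(f), loc))
    for (key in names(f$qualifiers)) {
      val <- f$qualifiers[[key]]
      if (key %in% c("transl_table", "codon_start") ||
          (key == "anticodon" && startsWith(val, "("))) {
        w(sprintf("                     /%s=%s", key, val))
      } else if (identical(val, "")) {
        w(sprintf("                     /%s", key))
      } else {
        w(sprintf("                     /%s=\"%s\"", key, val))
      }
    }
  }
  w("ORIGIN")
  seq <- tolower(record$sequence)
  pos <- seq(1L, nchar(seq), by = 60L)
  for (p in pos) {
    line <- substr(seq, p, min(p + 59L, nchar(seq)))
    groups <- substring(line, seq(1L, nchar(line), 10L),
                        pmin(seq(10L, nchar(line) + 9L, 10L), nchar(line)))
    w(sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  w("//")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.feature_key <- function(f) {
  if (f$kind %in% c("CDS", "tRNA", "rRNA")) f$kind
  else if (identical(f$name, "source")) "source"
  else "misc_feature"
}

.format_location <- function(f) {
  seg <- vapply(f$parts, function(p) {
    if (p[2] - p[1] == 1L) as.character(p[2]) else paste0(p[1] + 1L, "..", p[2])
  }, character(1))
  loc <- if (length(seg) > 1L) paste0("join(", paste(seg, collapse = ","), ")") else seg
  if (identical(f$strand, "-")) paste0("complement(", loc, ")") else loc
}

#' @export
print.mito_record <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, "", "kind")
  cat("<mito_record> ", x$accession, "  ", x$organism, "\n",
      "  ", x$length, " bp, ", x$topology,
      "; features: ", sum(kinds == "CDS"), " CDS, ",
      sum(kinds == "tRNA"), " tRNA, ",
      sum(kinds == "rRNA"), " rRNA\n", sep = "")
  invisible(x)
}
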