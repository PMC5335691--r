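# GenBank flat-file input/output for annotated mitogenomes, plus the
# annotation-anomaly screen that catches the defect classes seen in public
# mitogenome databases (missing/duplicated genes, inverted or absent
# coordinates, out-of-range features, unmappable names).

#' Construct an annotated mitogenome record
#'
#' @param record_id accession-like identifier (non-empty).
#' @param length total length in bases.
#' @param features data.frame with columns `name` (canonical token or `NA`),
#'   `category`, `start`, `end` (1-based inclusive; `NA` allowed), `strand`
#'   (+1/-1), `wraps` (logical: spans the origin), `raw_label`.
#' @param taxon,group free-text labels.
#' @param circular logical; wrap-around features are only legal on circular
#'   records.
#' @param sequence optional nucleotide string over A,C,G,T,N whose length
#'   must equal `length`.
#' @return object of class `mitogenome_record`.
#' @export
mitogenome_record <- function(record_id, length, features,
                              taxon = NA_character_, group = NA_character_,
                              circular = TRUE, sequence = NULL) {
  if (!nzchar(record_id)) .stopf("record_id must be non-empty")
  if (!is.null(sequence) && !is.na(sequence) &&
      nchar(sequence) != length)
    .stopf("sequence length (%d) != declared length (%d)",
           nchar(sequence), length)
  need <- c("name", "category", "start", "end", "strand", "wraps", "raw_label")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) .stopf("features lack column(s): %s",
                               paste(miss, collapse = ", "))
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(record_id = record_id, taxon = taxon, group = group,
                 length = as.integer(length), circular = isTRUE(circular),
                 features = features,
                 sequence = if (is.null(sequence)) NA_character_ else sequence),
            class = "mitogenome_record")
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat(sprintf("<mitogenome_record> %s (%s), %d bp%s, %d features\n",
              x$record_id, ifelse(is.na(x$taxon), "?", x$taxon), x$length,
              if (x$circular) ", circular" else "", nrow(x$features)))
  invisible(x)
}

# build a features data.frame row
.feature_row <- function(raw_label, start, end, strand, wraps = FALSE,
                         name = NULL) {
  if (is.null(name)) name <- unname(normalize_gene_name(raw_label))
  data.frame(name = name,
             category = ifelse(is.na(name), NA_character_,
                               gene_category(name)),
             start = as.integer(start), end = as.integer(end),
             strand = as.integer(strand), wraps = wraps,
             raw_label = raw_label, stringsAsFactors = FALSE)
}

# --- location strings -----------------------------------------------------

# parse a GenBank location; returns list(start, end, strand, wraps) with NA
# coordinates when unparseable
.parse_location <- function(loc, declared_length = NA_integer_) {
  strand <- 1L
  s <- gsub("[<>[:space:]]", "", loc)
  if (grepl("^complement\\(", s)) {
    strand <- -1L
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", s)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    rng <- regmatches(parts, regexec("^([0-9]+)\\.\\.([0-9]+)$", parts))
    ok <- lengths(rng) == 3
    if (length(parts) == 2 && all(ok)) {
      a <- as.integer(rng[[1]][2]); b <- as.integer(rng[[2]][3])
      # wrap-around join(a..L, 1..b)
      return(list(start = a, end = b, strand = strand, wraps = TRUE))
    }
    return(list(start = NA_integer_, end = NA_integer_, strand = strand,
                wraps = FALSE))
  }
  m <- regexec("^([0-9]+)\\.\\.([0-9]+)$", s)
  g <- regmatches(s, m)[[1]]
  if (length(g) == 3)
    return(list(start = as.integer(g[2]), end = as.integer(g[3]),
                strand = strand, wraps = FALSE))
  if (grepl("^[0-9]+$", s))
    return(list(start = as.integer(s), end = as.integer(s), strand = strand,
                wraps = FALSE))
  list(start = NA_integer_, end = NA_integer_, strand = strand, wraps = FALSE)
}

.format_location <- function(start, end, strand, wraps, record_length) {
  core <- if (is.na(start) || is.na(end)) "?"
  else if (wraps) sprintf("join(%d..%d,1..%d)", start, record_length, end)
  else sprintf("%d..%d", start, end)
  if (strand < 0) sprintf("complement(%s)", core) else core
}

# --- parsing --------------------------------------------------------------

#' Parse one GenBank flat-file record
#'
#' Reads a single LOCUS..// record. `gene`, `CDS`, `tRNA`, `rRNA`, `D-loop`
#' and `misc_feature` entries become gene features, with names normalized by
#' [normalize_gene_name()] from the `/gene`, `/product` or `/note` qualifier.
#' `complement(a..b)` gives strand -1; `join(a..L,1..b)` marks a wrap-around
#' feature; unparseable locations yield `NA` coordinates (picked up later by
#' [validate_annotation()]). Coordinates beyond the declared length attach an
#' out-of-range anomaly to the record instead of raising an error. An ORIGIN
#' block becomes the uppercased sequence.
#'
#' @param text GenBank record as a single string, character vector of lines,
#'   or path to a file.
#' @return a [mitogenome_record]; parse-time anomalies (out-of-range) are in
#'   `attr(record, "anomalies")`.
#' @export
parse_genbank_record <- function(text) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    readLines(text, warn = FALSE)
  else if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]]
  else text

  iloc <- grep("^LOCUS", lines)
  if (length(iloc) != 1)
    .stopf("expected exactly one LOCUS line, found %d", length(iloc))
  loc <- strsplit(trimws(lines[iloc]), "[[:space:]]+")[[1]]
  locus_name <- loc[2]
  ibp <- match("bp", loc)
  declared <- if (!is.na(ibp) && ibp > 2) suppressWarnings(as.integer(loc[ibp - 1]))
              else NA_integer_
  if (is.na(declared))
    .stopf("malformed LOCUS line (line %d): no length in bp", iloc)
  circular <- any(grepl("circular", loc, ignore.case = TRUE))

  grab <- function(key) {
    i <- grep(paste0("^", key), lines)
    if (length(i) == 0) return(NA_character_)
    trimws(sub(paste0("^", key), "", lines[i[1]]))
  }
  accession <- grab("ACCESSION")
  version <- grab("VERSION")
  record_id <- if (!is.na(version) && nzchar(version))
    strsplit(version, "[[:space:]]+")[[1]][1]
  else if (!is.na(accession) && nzchar(accession))
    strsplit(accession, "[[:space:]]+")[[1]][1]
  else locus_name
  iorg <- grep("^[[:space:]]+ORGANISM", lines)
  taxon <- if (length(iorg) > 0)
    trimws(sub("^[[:space:]]+ORGANISM", "", lines[iorg[1]]))
  else NA_character_
  icmt <- grep("^COMMENT[[:space:]]+group:", lines)
  group <- if (length(icmt) > 0)
    trimws(sub("^COMMENT[[:space:]]+group:", "", lines[icmt[1]]))
  else NA_character_

  ifeat <- grep("^FEATURES", lines)
  if (length(ifeat) != 1)
    .stopf("expected a FEATURES table (line with 'FEATURES' not found)")
  iend <- grep("^(ORIGIN|//)", lines)
  iend <- iend[iend > ifeat][1]
  if (is.na(iend)) iend <- length(lines) + 1L
  ftl <- lines[seq(ifeat + 1L, iend - 1L)]

  # split into feature blocks: a new feature starts with a key at column 6
  starts <- grep("^ {5}[A-Za-z]", ftl)
  feats <- list()
  anomalies <- list()
  for (si in seq_along(starts)) {
    from <- starts[si]
    to <- if (si < length(starts)) starts[si + 1] - 1L else length(ftl)
    block <- ftl[from:to]
    head <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]]
    key <- head[1]
    locstr <- paste(head[-1], collapse = "")
    # continuation lines before the first qualifier extend the location
    rest <- block[-1]
    qstart <- grep("^[[:space:]]*/", rest)
    if (length(qstart) > 0 && qstart[1] > 1)
      locstr <- paste0(locstr, paste(trimws(rest[seq_len(qstart[1] - 1)]),
                                     collapse = ""))
    if (!key %in% c("gene", "CDS", "tRNA", "rRNA", "D-loop", "misc_feature",
                    "D_loop"))
      next
    qual <- function(q) {
      i <- grep(paste0("^[[:space:]]*/", q, "="), block)
      if (length(i) == 0) return(NA_character_)
      v <- sub(paste0("^[[:space:]]*/", q, "="), "", block[i[1]])
      gsub("\"", "", trimws(v))
    }
    raw <- qual("gene")
    if (is.na(raw)) raw <- qual("product")
    if (is.na(raw)) raw <- qual("note")
    if (is.na(raw) && key %in% c("D-loop", "D_loop")) raw <- "D-loop"
    if (is.na(raw)) next
    pl <- .parse_location(locstr, declared)
    if (!is.na(pl$start) && !pl$wraps &&
        (pl$start > declared || pl$end > declared)) {
      anomalies[[length(anomalies) + 1L]] <- data.frame(
        record_id = record_id, kind = "out-of-range",
        gene = ifelse(is.na(normalize_gene_name(raw)), raw,
                      unname(normalize_gene_name(raw))),
        detail = sprintf("feature %s at %s exceeds declared length %d",
                         raw, locstr, declared),
        severity = "defect", stringsAsFactors = FALSE)
    }
    feats[[length(feats) + 1L]] <- cbind(
      .feature_row(raw, pl$start, pl$end, pl$strand, pl$wraps),
      key = key, stringsAsFactors = FALSE)
  }
  if (length(feats) == 0) .stopf("no gene features found in FEATURES table")
  ft <- do.call(rbind, feats)
  # drop bare `gene` entries duplicated by a typed feature at the same spot
  dupgene <- ft$key == "gene" & vapply(seq_len(nrow(ft)), function(i) {
    any(ft$key != "gene" &
          (ft$name %in% ft$name[i] & !is.na(ft$name) & !is.na(ft$name[i])) &
          ft$start %in% ft$start[i])
  }, logical(1))
  ft <- ft[!dupgene, setdiff(names(ft), "key"), drop = FALSE]

  sequence <- NULL
  iori <- grep("^ORIGIN", lines)
  if (length(iori) == 1) {
    iterm <- grep("^//", lines)
    iterm <- iterm[iterm > iori][1]
    if (is.na(iterm)) iterm <- length(lines) + 1L
    seqlines <- lines[seq(iori + 1L, iterm - 1L)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NULL
  }

  rec <- mitogenome_record(record_id, declared, ft, taxon = taxon,
                           group = group, circular = circular,
                           sequence = sequence)
  attr(rec, "anomalies") <- if (length(anomalies) > 0)
    do.call(rbind, anomalies) else NULL
  rec
}

# --- writing --------------------------------------------------------------

.gb_feature_key <- function(category) {
  switch(ifelse(is.na(category), "unknown", category),
         PCG = "CDS", rRNA = "rRNA", tRNA = "tRNA",
         control_region = "misc_feature", "misc_feature")
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Produces text that [parse_genbank_record()] maps back to the identical
#' record (field-level round trip). Minus-strand features render as
#' `complement(a..b)`, wrap-around features as `join(a..L,1..b)`.
#'
#' @param record a [mitogenome_record] with at least one feature.
#' @param path optional file path; when given the text is also written there.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_genbank_record <- function(record, path = NULL) {
  ft <- record$features
  if (is.null(ft) || nrow(ft) == 0)
    .stopf("refusing to write a record without features")
  out <- character(0)
  out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %s MIT",
                        record$record_id, record$length,
                        if (record$circular) "circular" else "linear"))
  if (!is.na(record$taxon)) {
    out <- c(out, sprintf("DEFINITION  %s mitochondrion.", record$taxon))
  }
  out <- c(out, sprintf("ACCESSION   %s", record$record_id),
           sprintf("VERSION     %s", record$record_id))
  if (!is.na(record$group))
    out <- c(out, sprintf("COMMENT     group: %s", record$group))
  if (!is.na(record$taxon))
    out <- c(out, sprintf("SOURCE      %s", record$taxon),
             sprintf("  ORGANISM  %s", record$taxon))
  out <- c(out, "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(ft))) {
    key <- .gb_feature_key(ft$category[i])
    loc <- .format_location(ft$start[i], ft$end[i], ft$strand[i],
                            ft$wraps[i], record$length)
    out <- c(out, sprintf("     %-16s%s", key, loc),
             sprintf("                     /gene=\"%s\"", ft$raw_label[i]))
    if (!is.na(ft$category[i]) && ft$category[i] == "control_region")
      out <- c(out, "                     /note=\"putative control region\"")
  }
  if (!is.na(record$sequence)) {
    out <- c(out, "ORIGIN")
    s <- tolower(record$sequence)
    n <- nchar(s)
    for (pos in seq(1L, n, by = 60L)) {
      chunk <- substr(s, pos, min(pos + 59L, n))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", pos, paste(tens, collapse = " ")))
    }
  }
  out <- c(out, "//")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# --- annotation QC --------------------------------------------------------

.empty_anomalies <- function() {
  data.frame(record_id = character(0), kind = character(0),
             gene = character(0), detail = character(0),
             severity = character(0), stringsAsFactors = FALSE)
}

.anom <- function(record_id, kind, gene, detail, severity = "defect") {
  data.frame(record_id = record_id, kind = kind, gene = gene,
             detail = detail, severity = severity, stringsAsFactors = FALSE)
}

#' Screen a record for annotation anomalies
#'
#' Reproduces the defect classes that curation against ab initio
#' re-annotation uncovers in public databases: each of the 37 expected genes
#' that is absent (`missing-gene`); any token except the control region
#' present more than once (`duplicated-gene`; a second trnQ is documented
#' biology in some shrimp and is reported with severity `"info"` rather than
#' `"defect"`); `start > end` on a non-wrap-around feature
#' (`inverted-coordinates`; strand-only contradictions are deliberately not
#' flagged, since legitimate rearrangements relocate rRNAs between strands);
#' named
#' genes without positions (`missing-coordinates`); features beyond the
#' declared length (`out-of-range`); unmappable labels (`unknown-name`).
#'
#' @param record a [mitogenome_record].
#' @return data.frame with columns `record_id`, `kind`, `gene`, `detail`,
#'   `severity`, sorted by (kind, gene); zero rows means clean.
#' @export
validate_annotation <- function(record) {
  ft <- record$features
  res <- list()
  id <- record$record_id

  present <- ft$name[!is.na(ft$name)]
  for (g in setdiff(GENE_TOKENS, present))
    res[[length(res) + 1L]] <- .anom(id, "missing-gene", g,
                                     "expected gene not annotated")
  tab <- table(present[present != CR_TOKEN])
  for (g in names(tab[tab > 1]))
    res[[length(res) + 1L]] <- .anom(
      id, "duplicated-gene", g,
      sprintf("%d copies annotated", tab[[g]]),
      severity = if (g == "trnQ") "info" else "defect")

  bad_inv <- which(!is.na(ft$start) & !is.na(ft$end) &
                     ft$start > ft$end & !ft$wraps)
  for (i in bad_inv)
    res[[length(res) + 1L]] <- .anom(
      id, "inverted-coordinates",
      ifelse(is.na(ft$name[i]), ft$raw_label[i], ft$name[i]),
      sprintf("start %d > end %d on non-wrap-around feature",
              ft$start[i], ft$end[i]))

  for (i in which(!is.na(ft$name) & (is.na(ft$start) | is.na(ft$end))))
    res[[length(res) + 1L]] <- .anom(id, "missing-coordinates", ft$name[i],
                                     "annotated gene lacks coordinates")
  oor <- which(!is.na(ft$start) & !ft$wraps &
                 (ft$start > record$length | ft$end > record$length))
  for (i in oor)
    res[[length(res) + 1L]] <- .anom(
      id, "out-of-range",
      ifelse(is.na(ft$name[i]), ft$raw_label[i], ft$name[i]),
      sprintf("feature %d..%d exceeds record length %d",
              ft$start[i], ft$end[i], record$length))
  for (i in which(is.na(ft$name)))
    res[[length(res) + 1L]] <- .anom(id, "unknown-name", ft$raw_label[i],
                                     "label could not be normalized")

  if (length(res) == 0) return(.empty_anomalies())
  out <- do.call(rbind, res)
  out <- out[order(out$kind, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
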