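# Per-record summary statistics: length, AT content, gene counts by
# category, intergenic spacers (overlaps negative) and the control region.

#' AT content of a nucleotide sequence
#'
#' 100 x (A+T) / (A+C+G+T); N is excluded from the denominator. Invariant
#' under rotation of a circular sequence.
#'
#' @param seq nucleotide string over A,C,G,T,N.
#' @return percentage in \[0, 100\].
#' @export
at_content <- function(seq) {
  if (is.null(seq) || is.na(seq) || !nzchar(seq)) .stopf("empty sequence")
  s <- strsplit(toupper(seq), "")[[1]]
  counts <- table(factor(s, levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) .stopf("sequence contains no unambiguous bases")
  100 * sum(counts[c("A", "T")]) / denom
}

#' Intergenic spacers of a circular record
#'
#' For consecutive features in start order (including the wrap pair last ->
#' first), the spacer length is `next_start - prev_end - 1`; overlapping
#' genes give negative lengths, which keeps the conservation identity
#' sum(feature spans) + sum(spacers) = record length exact.
#'
#' @param record a circular [mitogenome_record] with >= 2 features.
#' @return data.frame with columns `left`, `right`, `length`.
#' @export
intergenic_spacers <- function(record) {
  ft <- record$features
  ft <- ft[!is.na(ft$start), , drop = FALSE]
  if (nrow(ft) < 2) .stopf("need at least two positioned features")
  ft <- ft[order(ft$start, ft$end), , drop = FALSE]
  n <- nrow(ft)
  nm <- ifelse(is.na(ft$name), ft$raw_label, ft$name)
  lens <- c(ft$start[-1] - ft$end[-n] - 1L,
            record$length - ft$end[n] + ft$start[1] - 1L)
  data.frame(left = nm, right = nm[c(2:n, 1L)], length = as.integer(lens),
             stringsAsFactors = FALSE)
}

#' Summarize a mitogenome record
#'
#' One row of the per-record summary table: length, AT%, gene counts by
#' category, total intergenic bases (overlaps negative), the longest
#' non-coding stretch and the annotated control-region span. Both the
#' annotated CR span and the longest spacer are computed, and
#' `longest_noncoding` is the larger of the two, since database practice is
#' ambiguous about which one a reported control-region length refers to.
#'
#' @param record a [mitogenome_record].
#' @return one-row data.frame (`summary_row`).
#' @export
summarize_record <- function(record) {
  ft <- record$features
  cat <- ft$category
  n_pcg <- sum(cat == "PCG", na.rm = TRUE)
  n_trna <- sum(cat == "tRNA", na.rm = TRUE)
  n_rrna <- sum(cat == "rRNA", na.rm = TRUE)
  at <- if (!is.na(record$sequence)) at_content(record$sequence) else NA_real_
  sp <- tryCatch(intergenic_spacers(record), error = function(e) NULL)
  intergenic_total <- if (is.null(sp)) NA_integer_ else sum(sp$length)
  max_spacer <- if (is.null(sp)) NA_integer_ else max(0L, sp$length)
  icr <- which(!is.na(cat) & cat == "control_region" & !is.na(ft$start))
  cr_length <- if (length(icr) > 0) {
    i <- icr[1]
    if (ft$wraps[i] || ft$start[i] > ft$end[i])
      record$length - ft$start[i] + 1L + ft$end[i]
    else ft$end[i] - ft$start[i] + 1L
  } else NA_integer_
  longest_noncoding <- max(c(max_spacer, cr_length), na.rm = TRUE)
  data.frame(record_id = record$record_id, taxon = record$taxon,
             group = record$group, length = record$length,
             at_percent = at, n_pcg = n_pcg, n_trna = n_trna,
             n_rrna = n_rrna, n_genes = n_pcg + n_trna + n_rrna,
             intergenic_total = intergenic_total,
             longest_noncoding = as.integer(longest_noncoding),
             cr_length = cr_length, stringsAsFactors = FALSE)
}
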