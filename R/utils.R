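# small shared helpers

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# random nucleotide string with a target AT fraction
.random_seq <- function(n, at = 0.7) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# circular substring of a sequence string (1-based inclusive, wraps)
.circ_substr <- function(seq, start, end) {
  n <- nchar(seq)
  if (start <= end) return(substr(seq, start, end))
  paste0(substr(seq, start, n), substr(seq, 1, end))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
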