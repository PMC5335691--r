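# Codon usage under the invertebrate mitochondrial code: counting, RSCU,
# per-amino-acid chi-square comparison among groups, Euclidean RSCU
# distances and classical (Torgerson) multidimensional scaling.

#' Extract strand-resolved coding sequences from a record
#'
#' Returns the nucleotide sequence of every protein-coding gene, reverse
#' complemented to coding orientation for minus-strand genes. Wrap-around
#' features are read across the origin. Features without coordinates are
#' skipped.
#'
#' @param record a [mitogenome_record] with a sequence.
#' @return named character vector (names = gene tokens) of coding sequences.
#' @export
extract_cds <- function(record) {
  if (is.na(record$sequence))
    .stopf("record %s carries no sequence", record$record_id)
  ft <- record$features
  ft <- ft[!is.na(ft$category) & ft$category == "PCG" & !is.na(ft$start), ,
           drop = FALSE]
  if (nrow(ft) == 0) return(stats::setNames(character(0), character(0)))
  out <- vapply(seq_len(nrow(ft)), function(i) {
    s <- .circ_substr(record$sequence, ft$start[i], ft$end[i])
    if (ft$strand[i] < 0) .revcomp(s) else s
  }, character(1))
  stats::setNames(out, ft$name)
}

#' Count codons of in-frame coding sequences
#'
#' Reads non-overlapping triplets from position 1 of each sequence under the
#' invertebrate mitochondrial code (NCBI translation table 5): a trailing
#' partial codon (the truncated-stop case) is dropped, a terminal complete
#' TAA/TAG is excluded, codons containing N are skipped and tallied
#' separately, and TGA / AGA / AGG are counted as the sense codons they are
#' in this code (Trp, Ser). An internal TAA/TAG raises a warning and is
#' excluded from the 62-codon table.
#'
#' @param cds_list character vector/list of coding sequences, already in
#'   coding orientation.
#' @param owner identifier attached to the table (record id or group label).
#' @return object of class `codon_counts`: named integer vector over the 62
#'   sense codons, with attributes `owner`, `n_codons` (total counted),
#'   `n_ambiguous` (N-containing codons skipped) and `n_internal_stops`.
#' @export
count_codons <- function(cds_list, owner = NA_character_) {
  codons <- sense_codons()
  counts <- stats::setNames(integer(length(codons)), codons)
  n_amb <- 0L; n_istop <- 0L
  for (s in cds_list) {
    s <- toupper(s)
    if (nchar(s) < 3) .stopf("coding sequence shorter than one codon")
    ncod <- nchar(s) %/% 3L
    tri <- substring(s, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
    is_stop <- tri %in% stop_codons()
    if (any(is_stop)) {
      internal <- which(is_stop) != length(tri)
      n_istop <- n_istop + sum(internal)
      if (any(internal))
        .warnf("internal stop codon(s) in coding sequence (%d)",
               sum(internal))
      tri <- tri[!is_stop]
    }
    amb <- grepl("[^ACGT]", tri)
    n_amb <- n_amb + sum(amb)
    tri <- tri[!amb]
    t <- table(factor(tri, levels = codons))
    counts <- counts + as.integer(t)
  }
  structure(counts, owner = owner, n_codons = sum(counts),
            n_ambiguous = n_amb, n_internal_stops = n_istop,
            genetic_code = "invertebrate mitochondrial (table 5)",
            class = "codon_counts")
}

#' Pool codon count tables by group
#'
#' @param tables list of `codon_counts` objects.
#' @param grouping named character vector mapping owner to group label.
#' @return named list of pooled `codon_counts`, one per group, with an
#'   `excluded` attribute listing owners that had no group.
#' @export
pool_counts <- function(tables, grouping) {
  owners <- vapply(tables, attr, character(1), "owner")
  grp <- unname(grouping[owners])
  excluded <- owners[is.na(grp)]
  if (length(excluded) > 0)
    .warnf("owner(s) without a group excluded from pooling: %s",
           paste(excluded, collapse = ", "))
  keep <- !is.na(grp)
  if (!any(keep)) .stopf("no owners left after exclusion")
  groups <- unique(grp[keep])
  out <- lapply(groups, function(g) {
    idx <- which(keep & grp == g)
    m <- Reduce(`+`, lapply(tables[idx], unclass))
    structure(as.integer(m), names = names(tables[[idx[1]]]),
              owner = g, n_codons = sum(m),
              n_ambiguous = sum(vapply(tables[idx], attr, numeric(1),
                                       "n_ambiguous")),
              n_internal_stops = sum(vapply(tables[idx], attr, numeric(1),
                                            "n_internal_stops")),
              genetic_code = attr(tables[[idx[1]]], "genetic_code"),
              class = "codon_counts")
  })
  names(out) <- groups
  for (g in groups)
    if (attr(out[[g]], "n_codons") == 0)
      .stopf("group '%s' pooled to zero codons", g)
  attr(out, "excluded") <- excluded
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in synonymous family F is the observed count divided by
#' the count expected if all |F| codons of the family were used equally:
#' `count(c) / (total(F) / |F|)`. A value of 1 means no bias. Families with
#' zero total get RSCU 0 for all members and are flagged, keeping the
#' 62-long vectors comparable across taxa.
#'
#' @param table a `codon_counts` object.
#' @return object of class `rscu_profile`: named numeric vector over the 62
#'   sense codons with attributes `owner` and `zero_families`.
#' @export
compute_rscu <- function(table) {
  fam <- codon_families()[names(table)]
  cnt <- as.numeric(table)
  tot <- tapply(cnt, fam, sum)[fam]
  size <- table(fam)[fam]
  r <- ifelse(tot > 0, cnt / (tot / as.numeric(size)), 0)
  zero <- sort(unique(fam[tot == 0]))
  structure(stats::setNames(as.numeric(r), names(table)),
            owner = attr(table, "owner"), zero_families = zero,
            class = "rscu_profile")
}

#' Per-amino-acid chi-square comparison of pooled codon usage
#'
#' For each synonymous family, forms the groups x codons contingency table
#' of pooled counts and computes the Pearson chi-square statistic with
#' df = (rows - 1)(cols - 1); groups with zero family total are dropped with
#' a warning, as are codon columns observed in no group. Families leaving
#' fewer than two usable rows (or one usable column) are marked
#' not-computable. No continuity correction and no multiple-testing
#' correction are applied; the significance flag uses `alpha`.
#'
#' @param pooled named list of `codon_counts` (one per group), e.g. from
#'   [pool_counts()].
#' @param alpha flag threshold on the p-value (default 0.001, the
#'   conventional reporting threshold for these comparisons).
#' @return data.frame with one row per family: `amino_acid`, `statistic`,
#'   `df`, `p_value`, `significant`, `computable`, sorted by amino acid.
#' @export
chi_square_per_aa <- function(pooled, alpha = 0.001) {
  if (length(pooled) < 2) .stopf("need at least two groups")
  fam <- codon_families()
  fams <- sort(unique(unname(fam)))
  mat <- do.call(rbind, lapply(pooled, as.numeric))
  colnames(mat) <- names(pooled[[1]])
  rows <- lapply(fams, function(f) {
    sub <- mat[, names(fam)[fam == f], drop = FALSE]
    keep_r <- rowSums(sub) > 0
    if (sum(keep_r) < nrow(sub))
      .warnf("family %s: dropping group(s) with zero total", f)
    sub <- sub[keep_r, , drop = FALSE]
    keep_c <- colSums(sub) > 0
    sub <- sub[, keep_c, drop = FALSE]
    if (nrow(sub) < 2 || ncol(sub) < 2)
      return(data.frame(amino_acid = f, statistic = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        significant = NA, computable = FALSE))
    E <- outer(rowSums(sub), colSums(sub)) / sum(sub)
    stat <- sum((sub - E)^2 / E)
    df <- (nrow(sub) - 1L) * (ncol(sub) - 1L)
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    data.frame(amino_acid = f, statistic = stat, df = df, p_value = p,
               significant = p < alpha, computable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Euclidean distance matrix between RSCU profiles
#'
#' @param profiles list of `rscu_profile` objects over identical codon sets.
#' @return symmetric numeric matrix with zero diagonal; dimnames from the
#'   profile owners.
#' @export
rscu_distance_matrix <- function(profiles) {
  if (length(profiles) < 2) .stopf("need at least two profiles")
  keys <- lapply(profiles, names)
  if (!all(vapply(keys, identical, logical(1), keys[[1]])))
    .stopf("profiles have mismatching codon key sets")
  m <- do.call(rbind, lapply(profiles, as.numeric))
  rownames(m) <- vapply(profiles, function(p) {
    o <- attr(p, "owner"); if (is.null(o) || is.na(o)) "" else o
  }, character(1))
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers -d^2/2, eigendecomposes, and takes coordinates from the
#' top-k non-negative eigenvalues. Exact for Euclidean input and fully
#' deterministic: each axis is oriented so its largest-magnitude coordinate
#' is positive. If fewer than `k` positive eigenvalues exist, the remaining
#' axes are zero-padded with a warning.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param k number of output dimensions (default 2).
#' @return list with `coordinates` (n x k matrix, centered columns),
#'   `eigenvalues` (all, descending) and `explained` (fraction of
#'   positive-eigenvalue mass captured by the k axes).
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n) .stopf("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) .stopf("dissimilarity matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-12) .stopf("diagonal must be zero")
  if (k < 1) .stopf("k must be >= 1")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 0) * 1e-12)
  npos <- length(pos)
  kk <- min(k, npos)
  X <- matrix(0, n, k)
  if (kk > 0) {
    X[, seq_len(kk)] <- e$vectors[, seq_len(kk), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(kk)]), kk)
    for (j in seq_len(kk)) {
      i <- which.max(abs(X[, j]))
      if (X[i, j] < 0) X[, j] <- -X[, j]
    }
  }
  if (npos < k)
    .warnf("only %d positive eigenvalue(s); padding %d axis/axes with zeros",
           npos, k - npos)
  rownames(X) <- rownames(d)
  explained <- if (npos > 0) sum(ev[seq_len(kk)]) / sum(ev[pos]) else 0
  list(coordinates = X, eigenvalues = ev, explained = explained)
}
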