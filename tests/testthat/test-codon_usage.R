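# codon_usage: counting under table 5, RSCU, chi-square, distances, MDS

test_that("the sense-codon vocabulary is the 62 codons of table 5", {
  sc <- sense_codons()
  expect_length(sc, 62)
  expect_false(any(stop_codons() %in% sc))
  fam <- codon_families()
  sizes <- table(unname(fam))
  expect_equal(max(sizes), 6)       # leucine
  expect_equal(min(sizes), 2)
  expect_equal(sum(sizes), 62)
  # serine is split into its two tRNA-defined families
  expect_setequal(names(fam)[fam == "S1"], c("AGT", "AGC", "AGA", "AGG"))
  expect_setequal(names(fam)[fam == "S2"], c("TCT", "TCC", "TCA", "TCG"))
  expect_equal(unname(fam[c("TGA", "ATA")]), c("W", "M"))  # table 5 quirks
})

test_that("count_codons applies the stated counting rules", {
  t1 <- count_codons("ATGAAATTT")
  expect_equal(attr(t1, "n_codons"), 3L)
  expect_equal(unname(t1[c("ATG", "AAA", "TTT")]), c(1L, 1L, 1L))
  # TGA is tryptophan here, not a stop
  t2 <- count_codons("ATGTGA")
  expect_equal(unname(t2["TGA"]), 1L)
  expect_equal(attr(t2, "n_codons"), 2L)
  # trailing partial codon (truncated stop) dropped; terminal TAA excluded
  t3 <- count_codons("ATGAAAT")
  expect_equal(attr(t3, "n_codons"), 2L)
  t4 <- count_codons("ATGAAATAA")
  expect_equal(attr(t4, "n_codons"), 2L)
  # N-containing codons skipped and tallied; internal stop warns
  t5 <- count_codons("ATGANATTT")
  expect_equal(attr(t5, "n_codons"), 2L)
  expect_equal(attr(t5, "n_ambiguous"), 1L)
  expect_warning(t6 <- count_codons("ATGTAAATT"), "internal stop")
  expect_equal(attr(t6, "n_codons"), 2L)
  expect_equal(attr(t6, "n_internal_stops"), 1L)
  expect_error(count_codons("AT"), "shorter")
})

test_that("pool_counts sums per group and reports ungrouped owners", {
  t1 <- count_codons("TTTTTT", owner = "a")   # 2 x TTT
  t2 <- count_codons("TTTTTTTTT", owner = "b")
  t3 <- count_codons("AAAAAA", owner = "c")
  grouping <- c(a = "G1", b = "G1", c = "G2")
  pooled <- pool_counts(list(t1, t2, t3), grouping)
  expect_equal(unname(pooled$G1["TTT"]), 5L)
  expect_equal(sum(vapply(pooled, attr, numeric(1), "n_codons")),
               sum(attr(t1, "n_codons"), attr(t2, "n_codons"),
                   attr(t3, "n_codons")))
  expect_warning(p2 <- pool_counts(list(t1, t2, t3), c(a = "G1", b = "G1")),
                 "c")
  expect_equal(attr(p2, "excluded"), "c")
  expect_error(suppressWarnings(pool_counts(list(t3), c(a = "G1"))), "no owners")
})

test_that("RSCU follows the equal-usage expectation formula", {
  codons <- sense_codons()
  fam <- codon_families()
  # equal counts within every family -> RSCU exactly 1 everywhere
  eq <- structure(rep(5L, 62), names = codons, owner = "eq",
                  class = "codon_counts")
  expect_true(all(abs(compute_rscu(eq) - 1) < 1e-12))
  # Phe TTT:3 TTC:1 -> 1.5, 0.5 ; two-codon family (10, 0) -> (2, 0)
  cnt <- structure(rep(0L, 62), names = codons, class = "codon_counts")
  cnt[c("TTT", "TTC")] <- c(3L, 1L)
  cnt[c("GAT", "GAC")] <- c(10L, 0L)
  r <- compute_rscu(cnt)
  expect_equal(unname(r[c("TTT", "TTC")]), c(1.5, 0.5))
  expect_equal(unname(r[c("GAT", "GAC")]), c(2, 0))
  # zero-total families flagged, set to 0
  expect_true("L" %in% attr(r, "zero_families"))
  expect_true(all(r[names(fam)[fam == "L"]] == 0))
})

test_that("family sums of RSCU equal family size on random counts", {
  set.seed(301)
  fam <- codon_families()
  for (i in 1:25) {
    cnt <- structure(as.integer(rpois(62, lambda = sample(c(1, 5, 50), 1))),
                     names = sense_codons(), class = "codon_counts")
    r <- compute_rscu(cnt)
    for (f in unique(unname(fam))) {
      idx <- names(fam)[fam == f]
      tot <- sum(cnt[idx])
      if (tot > 0) expect_equal(sum(r[idx]), length(idx), tolerance = 1e-9)
      else expect_true(all(r[idx] == 0))
    }
  }
})

test_that("per-family chi-square matches the textbook statistic", {
  codons <- sense_codons()
  mk <- function(x, owner) structure(as.integer(x), names = codons,
                                     owner = owner, class = "codon_counts")
  # 2x2 table [[10,0],[0,10]] in the Asp family -> statistic 20, df 1
  a <- rep(0L, 62); names(a) <- codons
  b <- a
  a[c("GAT", "GAC")] <- c(10L, 0L)
  b[c("GAT", "GAC")] <- c(0L, 10L)
  suppressWarnings(chi <- chi_square_per_aa(list(A = mk(a, "A"), B = mk(b, "B"))))
  row <- chi[chi$amino_acid == "D", ]
  expect_equal(row$statistic, 20)
  expect_equal(row$df, 1L)
  # identical usage proportions -> statistic 0, p 1
  c1 <- a; c1[c("GAT", "GAC")] <- c(6L, 2L)
  c2 <- a; c2[c("GAT", "GAC")] <- c(12L, 4L)
  suppressWarnings(chi2 <- chi_square_per_aa(list(A = mk(c1, "A"), B = mk(c2, "B"))))
  row2 <- chi2[chi2$amino_acid == "D", ]
  expect_equal(row2$statistic, 0)
  expect_equal(row2$p_value, 1)
  # empty family: not computable, no exception
  expect_true(all(!chi$computable[chi$amino_acid == "K"]))
  expect_error(chi_square_per_aa(list(A = mk(a, "A"))), "two groups")
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(302)
  codons <- sense_codons()
  fam <- codon_families()
  for (i in 1:10) {
    m <- matrix(rpois(3 * 62, 40), nrow = 3)
    colnames(m) <- codons
    pooled <- lapply(1:3, function(j)
      structure(as.integer(m[j, ]), names = codons, owner = paste0("g", j),
                class = "codon_counts"))
    names(pooled) <- paste0("g", 1:3)
    chi <- chi_square_per_aa(pooled)
    f <- sample(unique(unname(fam)), 1)
    sub <- m[, names(fam)[fam == f], drop = FALSE]
    ref <- suppressWarnings(stats::chisq.test(sub, correct = FALSE))
    row <- chi[chi$amino_acid == f, ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$df, unname(ref$parameter))
    expect_equal(row$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("rscu_distance_matrix is Euclidean, symmetric, triangle-safe", {
  set.seed(303)
  mk_profile <- function(owner) {
    cnt <- structure(as.integer(rpois(62, 30)), names = sense_codons(),
                     owner = owner, class = "codon_counts")
    compute_rscu(cnt)
  }
  ps <- lapply(c("a", "b", "c"), mk_profile)
  d <- rscu_distance_matrix(ps)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_lte(d["a", "b"], d["a", "c"] + d["c", "b"] + 1e-12)
  # identical profiles at distance 0; single-coordinate difference = delta
  p1 <- ps[[1]]
  p2 <- p1
  attr(p2, "owner") <- "b"
  p2["TTT"] <- p2["TTT"] + 0.25
  dd <- rscu_distance_matrix(list(p1, p2))
  expect_equal(dd[1, 2], 0.25)
  expect_equal(rscu_distance_matrix(list(p1, p1))[1, 2], 0)
})

test_that("classical MDS inverts planted configurations exactly", {
  set.seed(304)
  X <- matrix(rnorm(20), ncol = 2)
  X <- scale(X, scale = FALSE)
  d <- as.matrix(dist(X))
  mds <- classical_mds(d, 2)
  Y <- mds$coordinates
  # Procrustes: optimal rotation/reflection of Y onto X
  s <- svd(t(Y) %*% X)
  resid <- max(abs(Y %*% s$u %*% t(s$v) - X))
  expect_lt(resid, 1e-8)
  expect_equal(colMeans(Y), c(0, 0), tolerance = 1e-9)
  expect_false(is.unsorted(rev(mds$eigenvalues)))
  # three mutually equidistant points form a unit equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  tri <- classical_mds(d3, 2)$coordinates
  expect_equal(unname(as.matrix(dist(tri))), unname(d3), tolerance = 1e-9)
  # coincident points stay coincident
  d4 <- as.matrix(dist(rbind(X[1, ], X[1, ], X[2, ])))
  # two coincident of three points leave a single positive eigenvalue
  expect_warning(co <- classical_mds(d4, 2)$coordinates, "padding")
  expect_equal(co[1, ], co[2, ], tolerance = 1e-9)
})

test_that("classical MDS matches cmdscale up to axis sign", {
  set.seed(305)
  X <- matrix(rnorm(36), ncol = 3)
  d <- as.matrix(dist(X))
  mds <- classical_mds(d, 3)
  ref <- stats::cmdscale(d, k = 3)
  expect_equal(abs(mds$coordinates), abs(ref), tolerance = 1e-8,
               ignore_attr = TRUE)
  # k beyond the positive spectrum pads with zeros and warns
  d2 <- matrix(1, 3, 3) - diag(3)
  expect_warning(pad <- classical_mds(d2, 3), "padding")
  expect_equal(unname(pad$coordinates[, 3]), rep(0, 3))
})
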