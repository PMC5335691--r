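# gene_order: canonical form, breakpoint distance, event inference,
# pattern grouping

test_that("ground pattern has the full 38-token inventory", {
  g <- ground_pattern()
  expect_equal(length(g), 38)
  expect_setequal(g$tokens, c(GENE_TOKENS, CR_TOKEN))
  expect_equal(length(ground_pattern(include_cr = FALSE)), 37)
})

test_that("canonicalize is rotation/mirror invariant and idempotent", {
  g <- ground_pattern()
  n <- length(g)
  key <- mitocomp:::.canonical_key(g)
  for (r in c(1, 5, 17, 38)) {
    idx <- c(r:n, seq_len(r - 1))[seq_len(n)]
    rot <- gene_order(g$tokens[idx], g$signs[idx])
    expect_equal(mitocomp:::.canonical_key(rot), key)
  }
  mir <- gene_order(rev(g$tokens), rev(-g$signs))
  expect_equal(mitocomp:::.canonical_key(mir), key)
  set.seed(101)
  for (i in 1:100) {
    o <- toy_order(sample(4:9, 1))
    c1 <- canonicalize(o)
    expect_equal(canonicalize(c1), c1)
  }
  expect_error(canonicalize(gene_order(c("g2", "g3"))), "cox1")
})

test_that("extract_gene_order round-trips the generator and suffixes dups", {
  set.seed(102)
  cfg <- default_generator_config(seed = 102)
  rec <- build_ground_record(cfg)
  expect_true(orders_equal(extract_gene_order(rec), ground_pattern()))
  expect_true(orders_equal(extract_gene_order(rec, include_cr = FALSE),
                           ground_pattern(include_cr = FALSE)))
  # extra trnQ between nad4l and trnT
  ord <- apply_events(ground_pattern(), pattern_scripts()$Ap1)
  rec_q <- mitocomp:::.build_record_from_order(ord, cfg, "Q1", "q", NA,
                                               codon_profile(0.7))
  o <- extract_gene_order(rec_q)
  expect_equal(length(o), 39)
  expect_equal(sum(grepl("^trnQ", o$tokens)), 2)
  expect_true("trnQ.2" %in% o$tokens)
  i <- which(sub("\\..*$", "", o$tokens) == "nad4l")
  expect_match(o$tokens[i + 1], "^trnQ")
  expect_match(o$tokens[i + 2], "^trnT")
})

test_that("breakpoint_distance: identity, known examples, mismatch error", {
  g <- ground_pattern()
  expect_equal(breakpoint_distance(g, g), 0)
  # single tRNA moved to a new non-adjacent spot: 3 breakpoints
  d <- apply_events(g, rearrangement_event("translocation", "trnN",
                                           sign = 1L, target_left = "cob"))
  expect_equal(breakpoint_distance(g, d), 3)
  expect_equal(breakpoint_distance(d, g), 3)
  # internal block inverted in place: 2 breakpoints
  d2 <- apply_events(g, rearrangement_event("block-inversion",
                                            c("nad5", "trnH", "nad4")))
  expect_equal(breakpoint_distance(g, d2), 2)
  expect_error(breakpoint_distance(g, ground_pattern(include_cr = FALSE)),
               "CR")
})

test_that("breakpoint_distance behaves as a metric on random triples", {
  set.seed(103)
  for (i in 1:40) {
    n <- sample(5:9, 1)
    base <- toy_order(n)
    a <- rand_event_script(base, sample(1:3, 1))$derived
    b <- rand_event_script(base, sample(1:3, 1))$derived
    c_ <- rand_event_script(base, sample(1:3, 1))$derived
    dab <- breakpoint_distance(a, b)
    dba <- breakpoint_distance(b, a)
    expect_equal(dab, dba)
    expect_equal(breakpoint_distance(a, a), 0)
    expect_gte(breakpoint_distance(a, c_) + breakpoint_distance(c_, b), dab)
    expect_equal(dab == 0, orders_equal(a, b))
  }
})

test_that("infer_events classifies the canonical example moves", {
  g <- ground_pattern()
  expect_equal(infer_events(g, g), list())

  # contiguous 4-gene block inverted in place -> one block-inversion
  blk <- c("nad1", "trnL1", "rrnL", "trnV")
  d <- apply_events(g, rearrangement_event("block-inversion", blk))
  ev <- infer_events(g, d)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$kind, "block-inversion")
  expect_setequal(ev[[1]]$genes, blk)

  # trnD moved sign-flipped to between trnS2 and nad1: translocation+inversion
  d2 <- apply_events(g, rearrangement_event("translocation", "trnD",
                                            sign = -1L,
                                            target_left = "trnS2"))
  ev2 <- infer_events(g, d2)
  expect_length(ev2, 1)
  expect_equal(ev2[[1]]$kind, "translocation+inversion")
  expect_equal(ev2[[1]]$genes, "trnD")
  expect_equal(ev2[[1]]$target_left, "trnS2")
  expect_equal(ev2[[1]]$source_left, "trnK")
  expect_equal(ev2[[1]]$source_right, "atp8")

  # supernumerary copy -> duplication event; lost gene -> loss event
  d3 <- apply_events(g, pattern_scripts()$Ap1)
  kinds3 <- vapply(infer_events(g, d3), `[[`, character(1), "kind")
  expect_true("duplication" %in% kinds3)
  d4 <- apply_events(g, rearrangement_event("loss", "trnE"))
  ev4 <- infer_events(g, d4)
  expect_length(ev4, 1)
  expect_equal(ev4[[1]]$kind, "loss")
  expect_equal(ev4[[1]]$genes, "trnE")
})

test_that("replay soundness holds on seeded random scripts", {
  set.seed(104)
  g <- ground_pattern()
  for (r in 1:40) {
    s <- rand_event_script(g)
    ev <- infer_events(g, s$derived)
    expect_true(orders_equal(apply_events(g, ev), s$derived),
                info = sprintf("script %d", r))
  }
})

test_that("heuristic event count is near the brute-force minimum", {
  set.seed(105)
  for (r in 1:15) {
    n <- sample(5:8, 1)
    a <- toy_order(n)
    s <- rand_event_script(a, sample(1:2, 1))
    ev <- infer_events(a, s$derived)
    m <- oracle_min_events(a, s$derived, max_depth = 2)
    expect_false(is.na(m))
    expect_gte(length(ev), m)
    expect_lte(length(ev), m + 2)
  }
})

test_that("group_patterns partitions by canonical equality, order-invariant", {
  set.seed(106)
  g <- ground_pattern()
  pa <- apply_events(g, pattern_scripts()$Pa)
  up <- apply_events(g, pattern_scripts()$Up)
  orders <- list(r1 = pa, r2 = g, r3 = pa, r4 = up, r5 = pa, r6 = up)
  pats <- group_patterns(orders)
  labs <- vapply(pats, `[[`, character(1), "label")
  sizes <- vapply(pats, function(p) length(p$members), integer(1))
  expect_setequal(labs, c("Gr", "P1", "P2"))
  expect_setequal(sizes, c(1L, 3L, 2L))
  expect_equal(sort(pats[[which(labs == "P1")]]$members),
               c("r1", "r3", "r5"))
  # permuting the input changes nothing
  pats2 <- group_patterns(orders[c(4, 2, 6, 1, 5, 3)])
  expect_equal(pats2, pats)
  # supplied labels are honoured
  pats3 <- group_patterns(orders, labels = c(r1 = "Pa", r3 = "Pa", r5 = "Pa",
                                             r4 = "Up", r6 = "Up"))
  expect_setequal(vapply(pats3, `[[`, character(1), "label"),
                  c("Gr", "Pa", "Up"))
  # all ground -> single Gr class; all unique -> all singletons
  pats4 <- group_patterns(list(a = g, b = g))
  expect_equal(vapply(pats4, `[[`, character(1), "label"), "Gr")
  ax <- apply_events(g, pattern_scripts()$Ax1)
  pats5 <- group_patterns(list(a = pa, b = up, c = ax))
  expect_equal(vapply(pats5, function(p) length(p$members), integer(1)),
               rep(1L, 3))
})

test_that("events carried by patterns reproduce each derived order", {
  set.seed(107)
  g <- ground_pattern()
  sc <- pattern_scripts()
  orders <- lapply(sc[c("Pa", "Ap1", "Up", "Ax1", "Ax2")],
                   function(s) apply_events(g, s))
  names(orders) <- paste0("rec_", names(orders))
  pats <- group_patterns(orders)
  for (p in pats) {
    if (p$label == "Gr") next
    expect_true(orders_equal(apply_events(g, p$events_vs_ground),
                             p$canonical_order), info = p$label)
    expect_gt(p$breakpoints_vs_ground, 0)
  }
})
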