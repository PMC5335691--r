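# genbank_io: parsing, writing, name normalization, annotation QC

test_that("normalize_gene_name maps the field's mixed nomenclatures", {
  cases <- c(COI = "cox1", CO1 = "cox1", COX1 = "cox1",
             ND4L = "nad4l", "ND2" = "nad2", CYTB = "cob", COB = "cob",
             srRNA = "rrnS", "12S rRNA" = "rrnS", "16S" = "rrnL",
             lrRNA = "rrnL", "D-loop" = "CR", "control region" = "CR",
             "ATPase6" = "atp6",
             "tRNA-Leu(UUR)" = "trnL2", "tRNA-Leu(CUN)" = "trnL1",
             "tRNA-Ser(AGN)" = "trnS1", "tRNA-Ser(UCN)" = "trnS2",
             "tRNA-Asp" = "trnD", "trnW" = "trnW", "tRNA-Met" = "trnM")
  got <- normalize_gene_name(names(cases))
  expect_equal(unname(got), unname(cases))
  # idempotence on the whole vocabulary and on every mapped value
  expect_equal(unname(normalize_gene_name(got)), unname(cases))
  expect_equal(unname(normalize_gene_name(c(GENE_TOKENS, CR_TOKEN))),
               c(GENE_TOKENS, CR_TOKEN))
  # ambiguous leucine without anticodon and junk labels are unmappable
  expect_true(is.na(normalize_gene_name("tRNA-Leu")))
  expect_true(is.na(normalize_gene_name("hypothetical ORF")))
})

test_that("parse_genbank_record reads locations, strands and sequence", {
  rec <- parse_genbank_record(tiny_genbank_text())
  expect_s3_class(rec, "mitogenome_record")
  expect_equal(rec$record_id, "TEST0001")
  expect_equal(rec$length, 400L)
  expect_true(rec$circular)
  expect_equal(nrow(rec$features), 3)
  third <- rec$features[3, ]
  expect_equal(third$strand, -1L)
  expect_equal(third$start, 290L)
  expect_equal(third$end, 355L)
  expect_equal(rec$features$name, c("cox1", "trnD", "rrnS"))
})

test_that("parse errors name the problem; out-of-range becomes an anomaly", {
  expect_error(parse_genbank_record(c("FOO", "//")), "LOCUS")
  expect_error(parse_genbank_record(
    c("LOCUS       X 100 bp DNA circular", "//")), "FEATURES")
  txt <- tiny_genbank_text()
  txt[5] <- "     CDS             1..900"   # beyond declared 400 bp
  rec <- parse_genbank_record(txt)
  an <- attr(rec, "anomalies")
  expect_equal(an$kind, "out-of-range")
  expect_equal(an$gene, "cox1")
})

test_that("write/parse round trip is the identity on synthetic records", {
  set.seed(401)
  cfg <- default_generator_config(seed = 401)
  g <- ground_pattern()
  for (i in 1:6) {
    ord <- if (i == 1) g else rand_event_script(g, sample(1:3, 1))$derived
    rec <- mitocomp:::.build_record_from_order(
      ord, cfg, sprintf("RT%02d", i), sprintf("taxon %d", i), "GroupX",
      codon_profile(0.7))
    back <- parse_genbank_record(write_genbank_record(rec))
    expect_equal(unclass(back), unclass(rec), info = sprintf("record %d", i))
  }
})

test_that("minus strand renders as complement() and wrap as join()", {
  ft <- rbind(mitocomp:::.feature_row("COI", 10L, 100L, 1L),
              mitocomp:::.feature_row("tRNA-Trp", 120L, 180L, -1L),
              mitocomp:::.feature_row("16S", 190L, 20L, -1L, wraps = TRUE))
  rec <- mitogenome_record("W1", 200L, ft)
  txt <- write_genbank_record(rec)
  expect_true(any(grepl("complement(120..180)", txt, fixed = TRUE)))
  expect_true(any(grepl("complement(join(190..200,1..20))", txt, fixed = TRUE)))
  back <- parse_genbank_record(txt)
  expect_equal(back$features$wraps, c(FALSE, FALSE, TRUE))
  expect_equal(back$features$strand, c(1L, -1L, -1L))
  expect_error(write_genbank_record(
    mitogenome_record("E1", 10L, ft[0, ])), "without features")
})

test_that("validate_annotation flags the curated defect classes", {
  set.seed(402)
  rec <- build_ground_record(default_generator_config(seed = 402))
  expect_equal(nrow(validate_annotation(rec)), 0)

  # missing nad2 + duplicated trnS (the classic database defect pair)
  bad <- mitocomp:::.plant_defect(
    mitocomp:::.plant_defect(rec, "missing-gene"), "duplicated-gene")
  v <- validate_annotation(bad)
  expect_setequal(v$kind, c("missing-gene", "duplicated-gene"))
  expect_equal(v$gene[v$kind == "missing-gene"], "nad2")
  expect_equal(v$gene[v$kind == "duplicated-gene"], "trnS1")
  expect_true(all(v$severity == "defect"))

  # inverted rRNA coordinates
  v2 <- validate_annotation(mitocomp:::.plant_defect(rec, "inverted-coordinates"))
  expect_equal(sort(v2$gene[v2$kind == "inverted-coordinates"]),
               c("rrnL", "rrnS"))

  # missing rRNA coordinates
  v3 <- validate_annotation(mitocomp:::.plant_defect(rec, "missing-coordinates"))
  expect_equal(sort(v3$gene[v3$kind == "missing-coordinates"]),
               c("rrnL", "rrnS"))

  # unmappable label
  v4 <- validate_annotation(mitocomp:::.plant_defect(rec, "unknown-name"))
  expect_true("unknown-name" %in% v4$kind)

  # a second trnQ is documented biology: informational, not a defect
  extra <- rbind(rec$features, mitocomp:::.feature_row("trnQ", 50L, 120L, -1L))
  rec_q <- mitogenome_record(rec$record_id, rec$length, extra,
                             sequence = rec$sequence)
  vq <- validate_annotation(rec_q)
  expect_equal(vq$kind, "duplicated-gene")
  expect_equal(vq$severity, "info")
})

test_that("anomaly output is deterministically sorted by (kind, gene)", {
  set.seed(403)
  rec <- build_ground_record(default_generator_config(seed = 403))
  bad <- rec
  for (k in c("duplicated-gene", "missing-gene", "inverted-coordinates"))
    bad <- mitocomp:::.plant_defect(bad, k)
  v <- validate_annotation(bad)
  expect_false(is.unsorted(v$kind))
  expect_equal(v, v[order(v$kind, v$gene), ], ignore_attr = TRUE)
})
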