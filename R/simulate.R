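# Seeded synthetic mitogenome generator: fully annotated circular records on
# the pancrustacean ground pattern or any scripted rearrangement of it, with
# per-group codon-usage profiles, AT-rich non-coding regions, optional
# planted annotation defects, plus a study manifest and a Newick tree.

#' Default generator configuration
#'
#' The default emulates the design of the comparative study the package is
#' built around: three shrimp infraorders (8 + 5 + 20 taxa) plus 12
#' penaeid-like outgroup taxa; per-group codon profiles differing in
#' third-position AT bias (stronger in the two mud-shrimp groups, weaker in
#' the true shrimps); mean protein-coding gene length 300 codons, 68 bp
#' tRNAs, 800/1300 bp rRNAs and an 800 bp control region at 80% AT, giving
#' whole-molecule AT contents in the high-50s to low-70s percent range.
#' Pattern scripts follow the study's labels: `Ax1`/`Ax2` (large
#' rearrangements including a block inversion), `Up` (several tRNA
#' translocations), `Pa` (one tRNA translocation), `Ap1`/`Ap2` (extra trnQ,
#' with one more tRNA move in Ap2).
#'
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @param groups list of group specs: `label`, `n`, `at3` (third-position AT
#'   bias in (0,1)), `outgroup` flag.
#' @param pcg_codons mean codons per protein-coding gene.
#' @param trna_length,rrns_length,rrnl_length,cr_length feature lengths (bp).
#' @param cr_at AT fraction of the control region.
#' @param noncoding_at AT fraction of tRNA/rRNA/spacer sequence.
#' @param spacer_max maximal intergenic spacer length (bp), drawn uniformly
#'   from 0..`spacer_max`.
#' @param pattern_assignment named list per group label: character vector of
#'   pattern labels, one per taxon (recycled); defaults to the study-like
#'   assignment.
#' @param defects named list mapping taxon name to a character vector of
#'   anomaly kinds to plant.
#' @param violate_monophyly if `TRUE`, two leaves are swapped across
#'   pattern clades in the output tree (for negative tests).
#' @return a `generator_config` list.
#' @export
default_generator_config <- function(seed = 1,
                                     groups = list(
                                       list(label = "Axiidea", n = 8,
                                            at3 = 0.88, outgroup = FALSE),
                                       list(label = "Gebiidea", n = 5,
                                            at3 = 0.84, outgroup = FALSE),
                                       list(label = "Caridea", n = 20,
                                            at3 = 0.68, outgroup = FALSE),
                                       list(label = "Dendrobranchiata", n = 12,
                                            at3 = 0.75, outgroup = TRUE)),
                                     pcg_codons = 300,
                                     trna_length = 68,
                                     rrns_length = 800,
                                     rrnl_length = 1300,
                                     cr_length = 800,
                                     cr_at = 0.80,
                                     noncoding_at = 0.72,
                                     spacer_max = 20,
                                     pattern_assignment = NULL,
                                     defects = list(),
                                     violate_monophyly = FALSE) {
  labs <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labs)) .stopf("group labels must be unique")
  if (is.null(pattern_assignment)) {
    pattern_assignment <- list(
      Axiidea = c(rep("Ax1", 6), rep("Ax2", 2)),
      Gebiidea = c(rep("Up", 4), "Gr"),
      Caridea = c(rep("Pa", 3), rep("Ap1", 2), "Ap2", rep("Gr", 14)),
      Dendrobranchiata = "Gr")
  }
  structure(list(seed = as.integer(seed), groups = groups,
                 pcg_codons = pcg_codons, trna_length = trna_length,
                 rrns_length = rrns_length, rrnl_length = rrnl_length,
                 cr_length = cr_length, cr_at = cr_at,
                 noncoding_at = noncoding_at, spacer_max = spacer_max,
                 pattern_assignment = pattern_assignment, defects = defects,
                 violate_monophyly = isTRUE(violate_monophyly)),
            class = "generator_config")
}

#' Built-in pattern event scripts
#'
#' Executable stand-ins for the study's gene-order patterns, built from
#' their verbal descriptions (the figure rows themselves are not
#' machine-readable): these are synthetic scripts, not transcriptions.
#'
#' @return named list of event-script lists; `Gr` is the empty script.
#' @export
pattern_scripts <- function() {
  ax1 <- list(
    rearrangement_event("translocation", "cox3", sign = 1L,
                        target_left = "cob", target_right = "trnS2"),
    rearrangement_event("translocation", "trnL2", sign = -1L,
                        target_left = "rrnL", target_right = "trnV"),
    rearrangement_event("translocation", "trnV", sign = 1L,
                        target_left = "trnY", target_right = "cox1"))
  list(
    Gr = list(),
    Pa = list(
      rearrangement_event("translocation", "trnN", sign = 1L,
                          target_left = "cob", target_right = "trnS2")),
    Ap1 = list(
      rearrangement_event("duplication", "trnQ", sign = -1L,
                          target_left = "nad4l", target_right = "trnT")),
    Ap2 = list(
      rearrangement_event("duplication", "trnQ", sign = -1L,
                          target_left = "nad4l", target_right = "trnT"),
      rearrangement_event("translocation", "trnR", sign = 1L,
                          target_left = "trnG", target_right = "nad3")),
    Up = list(
      rearrangement_event("translocation", "trnF", sign = -1L,
                          target_left = "trnC", target_right = "trnY"),
      rearrangement_event("translocation", "trnH", sign = -1L,
                          target_left = "trnM", target_right = "nad2"),
      rearrangement_event("translocation", "trnT", sign = 1L,
                          target_left = "trnG", target_right = "nad3")),
    Ax1 = ax1,
    Ax2 = c(ax1, list(
      rearrangement_event("block-inversion",
                          c("nad1", "trnL1", "rrnL", "trnL2")),
      rearrangement_event("translocation", "trnD", sign = -1L,
                          target_left = "trnS2"))))
}

#' Apply a rearrangement event script to a gene order
#'
#' Alias of [apply_events()], named for the generator context: events are
#' applied left to right and each event's genes and contexts must be
#' resolvable in the order current at that point.
#'
#' @inheritParams apply_events
#' @return the rearranged [gene_order].
#' @export
apply_event_script <- function(order, events) apply_events(order, events)

#' Codon probability profile with a planted third-position AT bias
#'
#' Within every synonymous family, codons whose third base is A or T share
#' probability mass `at3` and G/C-ending codons share `1 - at3`; amino-acid
#' (family) usage is uniform by default. Every family of the invertebrate
#' mitochondrial code has both AT- and GC-ending members, so the profile is
#' well defined for any `at3` in (0,1).
#'
#' @param at3 third-position AT bias in (0,1).
#' @param family_weights optional named numeric over the 21 families
#'   (normalized internally); default uniform.
#' @return named numeric vector over the 62 sense codons summing to 1, with
#'   the within-family conditional probabilities in attribute `conditional`.
#' @export
codon_profile <- function(at3, family_weights = NULL) {
  if (!is.numeric(at3) || at3 <= 0 || at3 >= 1)
    .stopf("at3 must be in (0,1)")
  fam <- codon_families()
  fams <- unique(unname(fam))
  if (is.null(family_weights))
    family_weights <- stats::setNames(rep(1, length(fams)), fams)
  family_weights <- family_weights / sum(family_weights)
  third <- substr(names(fam), 3, 3)
  is_at <- third %in% c("A", "T")
  cond <- numeric(length(fam))
  names(cond) <- names(fam)
  for (f in fams) {
    idx <- which(fam == f)
    nat <- sum(is_at[idx]); ngc <- length(idx) - nat
    w <- ifelse(is_at[idx], at3 / nat, (1 - at3) / ngc)
    cond[idx] <- w
  }
  joint <- cond * unname(family_weights[fam])
  structure(joint / sum(joint), conditional = cond)
}

#' Simulate an in-frame coding sequence from a codon profile
#'
#' Draws `n_codons` sense codons i.i.d. from `profile` and appends a
#' terminal TAA stop. Reproducible under the session RNG (or `seed`).
#'
#' @param profile named numeric probability vector over the 62 sense codons.
#' @param n_codons number of sense codons.
#' @param seed optional integer; when given, a local seed is set.
#' @return coding sequence string of length `3 * (n_codons + 1)`.
#' @export
simulate_cds <- function(profile, n_codons, seed = NULL) {
  if (is.null(names(profile)) || !setequal(names(profile), sense_codons()))
    .stopf("profile must be named by the 62 sense codons")
  if (any(profile < 0) || sum(profile) <= 0) .stopf("invalid probabilities")
  if (!is.null(seed)) set.seed(seed)
  paste0(paste(sample(names(profile), n_codons, replace = TRUE,
                      prob = profile), collapse = ""), "TAA")
}

# build a fully annotated record realizing a given signed gene order
.build_record_from_order <- function(order, config, record_id, taxon, group,
                                     profile) {
  tok <- sub("\\.[0-9]+$", "", order$tokens)
  sgn <- order$signs
  seqs <- character(length(tok))
  for (i in seq_along(tok)) {
    g <- tok[i]
    cat <- gene_category(g)
    body <- switch(cat,
      PCG = simulate_cds(profile,
                         max(60L, round(stats::rnorm(1, config$pcg_codons,
                                                     config$pcg_codons * 0.1)))),
      tRNA = .random_seq(config$trna_length, config$noncoding_at),
      rRNA = .random_seq(if (g == "rrnS") config$rrns_length
                         else config$rrnl_length, config$noncoding_at),
      control_region = .random_seq(config$cr_length, config$cr_at))
    seqs[i] <- if (sgn[i] < 0) .revcomp(body) else body
  }
  spacers <- sample(0:config$spacer_max, length(tok), replace = TRUE)
  pieces <- character(2 * length(tok))
  feats <- vector("list", length(tok))
  cursor <- 0L
  for (i in seq_along(tok)) {
    sp <- .random_seq(spacers[i], config$noncoding_at)
    cursor <- cursor + spacers[i]
    start <- cursor + 1L
    cursor <- cursor + nchar(seqs[i])
    pieces[2 * i - 1L] <- sp
    pieces[2 * i] <- seqs[i]
    feats[[i]] <- .feature_row(tok[i], start, cursor, sgn[i])
  }
  mitogenome_record(record_id, cursor, do.call(rbind, feats),
                    taxon = taxon, group = group, circular = TRUE,
                    sequence = paste(pieces, collapse = ""))
}

#' Build a synthetic ground-pattern record
#'
#' A circular, fully annotated record whose extracted gene order canonically
#' equals the pancrustacean ground pattern: 37 genes plus control region,
#' strands per the ground pattern, small (0..`spacer_max`) intergenic
#' spacers. Draws from the session RNG; seed it for reproducibility.
#'
#' @param config a `generator_config` (default [default_generator_config()]).
#' @param taxon taxon label.
#' @param record_id record id (default derived from taxon).
#' @param group group label.
#' @param at3 third-position AT bias for the codon profile (default: first
#'   group's).
#' @return a [mitogenome_record].
#' @export
build_ground_record <- function(config = default_generator_config(),
                                taxon = "synthetic",
                                record_id = NULL, group = NA_character_,
                                at3 = NULL) {
  if (is.null(record_id)) record_id <- gsub("[^A-Za-z0-9_.]", "_", taxon)
  if (is.null(at3)) at3 <- config$groups[[1]]$at3
  .build_record_from_order(ground_pattern(TRUE), config, record_id, taxon,
                           group, codon_profile(at3))
}

# plant one annotation defect kind into a record (annotation level only)
.plant_defect <- function(record, kind) {
  ft <- record$features
  mod <- switch(kind,
    "missing-gene" = {
      ft[is.na(ft$name) | ft$name != "nad2", , drop = FALSE]
    },
    "duplicated-gene" = {
      i <- which(ft$name == "trnS1")[1]
      rbind(ft, ft[i, , drop = FALSE])
    },
    "inverted-coordinates" = {
      i <- which(ft$name %in% c("rrnS", "rrnL"))
      tmp <- ft$start[i]; ft$start[i] <- ft$end[i]; ft$end[i] <- tmp
      ft
    },
    "missing-coordinates" = {
      i <- which(ft$name %in% c("rrnS", "rrnL"))
      ft$start[i] <- NA_integer_; ft$end[i] <- NA_integer_
      ft
    },
    "unknown-name" = {
      rbind(ft, .feature_row("ORF-X", 1L, 30L, 1L))
    },
    "out-of-range" = {
      i <- nrow(ft)
      ft$end[i] <- record$length + 50L
      ft
    },
    .stopf("cannot plant defect kind '%s'", kind))
  mitogenome_record(record$record_id, record$length, mod,
                    taxon = record$taxon, group = record$group,
                    circular = record$circular, sequence = record$sequence)
}

# ladder newick from a character vector of labels
.ladder <- function(x) {
  if (length(x) == 1) return(x)
  paste0("(", x[1], ",", .ladder(x[-1]), ")")
}

#' Generate the full study fixture
#'
#' One annotated record per taxon, with its group's codon profile and its
#' pattern's event script applied to the ground pattern; optional planted
#' annotation defects; a manifest table; and a binary Newick tree in which
#' every scripted pattern's members form a clade nested inside their group's
#' clade (set `violate_monophyly` in the config to break this for negative
#' tests). Fully deterministic given `config$seed`.
#'
#' @param config a `generator_config`.
#' @return list with `records` (named list of [mitogenome_record]),
#'   `manifest` (data.frame: record_id, taxon, group, pattern, outgroup),
#'   `tree` (ape phylo), `scripts` (the pattern scripts used), `config`.
#' @export
make_study_fixture <- function(config = default_generator_config()) {
  set.seed(config$seed)
  scripts <- pattern_scripts()
  ground <- ground_pattern(TRUE)
  records <- list()
  rows <- list()
  idx <- 0L
  for (gs in config$groups) {
    pats <- config$pattern_assignment[[gs$label]]
    if (is.null(pats)) pats <- "Gr"
    pats <- rep_len(pats, gs$n)
    profile <- codon_profile(gs$at3)
    for (j in seq_len(gs$n)) {
      idx <- idx + 1L
      taxon <- sprintf("%s_%02d", gs$label, j)
      record_id <- sprintf("SYN%03d", idx)
      pat <- pats[j]
      if (!pat %in% names(scripts))
        .stopf("no event script for pattern '%s'", pat)
      order <- apply_events(ground, scripts[[pat]])
      rec <- .build_record_from_order(order, config, record_id, taxon,
                                      gs$label, profile)
      for (kind in config$defects[[taxon]]) rec <- .plant_defect(rec, kind)
      records[[record_id]] <- rec
      rows[[idx]] <- data.frame(record_id = record_id, taxon = taxon,
                                group = gs$label, pattern = pat,
                                outgroup = isTRUE(gs$outgroup),
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)

  # tree: pattern clades nested inside group clades, outgroup first
  grp_clade <- function(lab) {
    m <- manifest[manifest$group == lab, , drop = FALSE]
    sub <- vapply(unique(m$pattern), function(p)
      .ladder(m$record_id[m$pattern == p]), character(1))
    .ladder(unname(sub))
  }
  ingroup <- vapply(config$groups, `[[`, character(1), "label")
  og <- ingroup[vapply(config$groups, function(g) isTRUE(g$outgroup),
                       logical(1))]
  ig <- setdiff(ingroup, og)
  nwk <- if (length(og) > 0)
    paste0("(", paste(vapply(og, grp_clade, character(1)), collapse = ","),
           ",", .ladder(vapply(ig, grp_clade, character(1))), ");")
  else paste0(.ladder(vapply(ig, grp_clade, character(1))), ");")
  if (config$violate_monophyly) {
    derived <- manifest$record_id[manifest$pattern != "Gr"]
    grs <- manifest$record_id[manifest$pattern == "Gr"]
    if (length(derived) > 0 && length(grs) > 0) {
      a <- derived[1]; b <- grs[length(grs)]
      nwk <- gsub(paste0("\\b", a, "\\b"), "@@TMP@@", nwk)
      nwk <- gsub(paste0("\\b", b, "\\b"), a, nwk)
      nwk <- gsub("@@TMP@@", b, nwk, fixed = TRUE)
    }
  }
  list(records = records, manifest = manifest, tree = parse_newick(nwk),
       scripts = scripts, config = config)
}
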