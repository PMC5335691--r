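# Signed circular gene orders: extraction, canonical form, breakpoint
# distance, rearrangement-event inference and pattern grouping.

#' Signed circular gene order
#'
#' A circular, strand-signed sequence of canonical gene tokens — the unit of
#' comparison between mitogenomes. Duplicate tokens are disambiguated with an
#' ordinal suffix (`trnQ`, `trnQ.2`) in genome order. Two orders are equal
#' iff their canonical forms (see [canonicalize()]) are identical.
#'
#' @param tokens character vector of gene tokens (circular order).
#' @param signs integer vector of +1/-1 strand signs, same length.
#' @param include_cr logical; whether the control region participates as a
#'   positional marker.
#' @return an object of class `gene_order`.
#' @export
gene_order <- function(tokens, signs = rep(1L, length(tokens)),
                       include_cr = CR_TOKEN %in% sub("\\.[0-9]+$", "", tokens)) {
  if (length(tokens) == 0) .stopf("a gene order must contain at least one gene")
  if (length(signs) != length(tokens))
    .stopf("tokens and signs differ in length")
  if (!all(signs %in% c(-1L, 1L))) .stopf("signs must be +1 or -1")
  structure(list(tokens = as.character(tokens), signs = as.integer(signs),
                 include_cr = isTRUE(include_cr)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %d tokens (circular%s)\n", length(x$tokens),
              if (x$include_cr) ", CR as marker" else ""))
  cat(paste0(ifelse(x$signs < 0, "-", ""), x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$tokens)

# suffix 2nd+ occurrences of a base token in order: trnQ, trnQ.2, ...
.suffix_dups <- function(tokens) {
  base <- sub("\\.[0-9]+$", "", tokens)
  ave_idx <- stats::ave(seq_along(base), base, FUN = seq_along)
  ifelse(ave_idx > 1, paste0(base, ".", ave_idx), base)
}

#' Extract the signed gene order of a record
#'
#' Features are taken in ascending start order (a wrap-around feature is
#' placed by its start); strand gives the sign; supernumerary copies of a
#' token are suffixed by occurrence (`trnQ.2`). Features whose name could not
#' be normalized, or that lack coordinates, are skipped.
#'
#' @param record a [mitogenome_record].
#' @param include_cr keep the control region as a positional marker
#'   (default `TRUE`).
#' @return a [gene_order].
#' @export
extract_gene_order <- function(record, include_cr = TRUE) {
  ft <- record$features
  if (is.null(ft) || nrow(ft) == 0) .stopf("record %s has no features",
                                           record$record_id)
  ft <- ft[!is.na(ft$name) & !is.na(ft$start), , drop = FALSE]
  if (!include_cr) ft <- ft[ft$name != CR_TOKEN, , drop = FALSE]
  if (nrow(ft) == 0) .stopf("record %s has no usable features",
                            record$record_id)
  ft <- ft[order(ft$start, ft$end), , drop = FALSE]
  gene_order(.suffix_dups(ft$name), ft$strand, include_cr = include_cr)
}

#' Canonical form of a signed circular gene order
#'
#' Makes circular/mirror equality decidable: if the `cox1` anchor carries a
#' minus sign the whole order is first mirrored (reversed with all signs
#' flipped), then the order is rotated so `cox1` comes first, and duplicate
#' suffixes are re-assigned in canonical order. Deterministic and idempotent;
#' all rotations and the strand-mirror image of an order share one canonical
#' form.
#'
#' @param order a [gene_order] containing `cox1`.
#' @return the canonical [gene_order].
#' @export
canonicalize <- function(order) {
  base <- sub("\\.[0-9]+$", "", order$tokens)
  i <- which(base == "cox1")
  if (length(i) == 0)
    .stopf("order lacks the cox1 anchor; supply an order containing cox1")
  i <- i[1]
  tok <- base; sgn <- order$signs
  if (sgn[i] < 0) {            # mirror normalization
    tok <- rev(tok); sgn <- rev(-sgn)
    i <- which(tok == "cox1")[1]
  }
  n <- length(tok)
  rot <- c(i:n, seq_len(i - 1L))[seq_len(n)]
  if (i == 1L) rot <- seq_len(n)
  gene_order(.suffix_dups(tok[rot]), sgn[rot], include_cr = order$include_cr)
}

# canonical string key (used for equality and hashing)
.canonical_key <- function(order) {
  o <- canonicalize(order)
  paste(paste0(ifelse(o$signs < 0, "-", "+"), o$tokens), collapse = " ")
}

#' Test equality of two circular gene orders
#' @param a,b [gene_order] objects.
#' @return logical.
#' @export
orders_equal <- function(a, b) identical(.canonical_key(a), .canonical_key(b))

# set of signed circular adjacencies; (x,y) is identified with (-y,-x)
.adjacencies <- function(order) {
  tok <- order$tokens; sgn <- order$signs
  n <- length(tok)
  nxt <- c(2:n, 1L)[seq_len(n)]
  if (n == 1L) nxt <- 1L
  a1 <- paste0(ifelse(sgn < 0, "-", "+"), tok)
  a2 <- paste0(ifelse(sgn[nxt] < 0, "-", "+"), tok[nxt])
  b1 <- paste0(ifelse(sgn[nxt] < 0, "+", "-"), tok[nxt])  # -y
  b2 <- paste0(ifelse(sgn < 0, "+", "-"), tok)            # -x
  fwd <- paste(a1, a2, sep = "|")
  rev <- paste(b1, b2, sep = "|")
  ifelse(fwd <= rev, fwd, rev)
}

#' Breakpoint distance between two signed circular gene orders
#'
#' Counts the signed circular adjacencies of `a` that are absent from `b`,
#' where an adjacency (x, y) also matches its strand-mirror (-y, -x).
#' Symmetric, zero iff the canonical forms are equal, and a metric on
#' canonical forms over a fixed token multiset.
#'
#' @param a,b [gene_order] objects over the same token multiset (after
#'   duplicate suffixing).
#' @return non-negative integer count.
#' @export
breakpoint_distance <- function(a, b) {
  ta <- sort(.suffix_dups(a$tokens)); tb <- sort(.suffix_dups(b$tokens))
  if (!identical(ta, tb)) {
    d <- c(setdiff(ta, tb), setdiff(tb, ta))
    .stopf("token multisets differ (symmetric difference: %s)",
           paste(unique(d), collapse = ", "))
  }
  sum(!(.adjacencies(a) %in% .adjacencies(b)))
}

# --- rearrangement events -------------------------------------------------

#' Construct a rearrangement event
#'
#' Events describe a classified difference between two gene orders and are
#' executable: [apply_events()] replays them on an order.
#'
#' @param kind one of `"translocation"`, `"translocation+inversion"`,
#'   `"inversion"`, `"block-inversion"`, `"duplication"`, `"loss"`.
#' @param genes ordered character vector of tokens involved (a contiguous
#'   run for block inversions, a single token otherwise).
#' @param sign target strand sign for translocations/duplications.
#' @param target_left,target_right flanking tokens in the derived order.
#' @param source_left,source_right flanking tokens in the reference order.
#' @return an object of class `rearrangement_event`.
#' @export
rearrangement_event <- function(kind, genes, sign = NULL,
                                target_left = NA_character_,
                                target_right = NA_character_,
                                source_left = NA_character_,
                                source_right = NA_character_) {
  kinds <- c("translocation", "translocation+inversion", "inversion",
             "block-inversion", "duplication", "loss")
  if (!kind %in% kinds) .stopf("unknown event kind '%s'", kind)
  if (length(genes) == 0) .stopf("event must involve at least one gene")
  if (kind == "block-inversion" && length(genes) < 2)
    .stopf("block-inversion requires >= 2 contiguous genes")
  structure(list(kind = kind, genes = unname(as.character(genes)),
                 sign = if (is.null(sign)) NULL else unname(sign),
                 target_left = unname(as.character(target_left)),
                 target_right = unname(as.character(target_right)),
                 source_left = unname(as.character(source_left)),
                 source_right = unname(as.character(source_right))),
            class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  cat(sprintf("<%s> %s", x$kind, paste(x$genes, collapse = ",")))
  if (!is.na(x$target_left) || !is.na(x$target_right))
    cat(sprintf(" -> between %s and %s", x$target_left, x$target_right))
  cat("\n")
  invisible(x)
}

# locate gene occurrence in token vector: exact token, else first of base
.locate_gene <- function(tokens, gene) {
  i <- which(tokens == gene)
  if (length(i) == 0) {
    base <- sub("\\.[0-9]+$", "", tokens)
    i <- which(base == sub("\\.[0-9]+$", "", gene))
  }
  if (length(i) == 0) NA_integer_ else i[1]
}

# locate a contiguous circular run of tokens matching seg (by base token)
.locate_run <- function(tokens, seg) {
  n <- length(tokens); m <- length(seg)
  if (m > n) return(NA_integer_)
  base <- sub("\\.[0-9]+$", "", tokens)
  segb <- sub("\\.[0-9]+$", "", seg)
  for (i in seq_len(n)) {
    idx <- ((i - 1L + 0:(m - 1L)) %% n) + 1L
    if (all(base[idx] == segb)) return(i)
  }
  NA_integer_
}

#' Apply rearrangement events to a gene order
#'
#' Events are applied left to right; each event's genes and flanking contexts
#' must be resolvable in the order current at that point.
#'
#' @param order a [gene_order].
#' @param events a list of [rearrangement_event] objects (a single event is
#'   also accepted).
#' @return the rearranged [gene_order].
#' @export
apply_events <- function(order, events) {
  if (inherits(events, "rearrangement_event")) events <- list(events)
  tok <- order$tokens; sgn <- order$signs
  for (k in seq_along(events)) {
    ev <- events[[k]]
    n <- length(tok)
    if (ev$kind %in% c("inversion", "block-inversion")) {
      # the run may be recorded in either orientation; inverting is symmetric
      i <- .locate_run(tok, ev$genes)
      if (is.na(i)) i <- .locate_run(tok, rev(ev$genes))
      if (is.na(i)) .stopf("event %d (%s of %s): run not found in order",
                           k, ev$kind, paste(ev$genes, collapse = ","))
      idx <- ((i - 1L + 0:(length(ev$genes) - 1L)) %% n) + 1L
      tok[idx] <- rev(tok[idx]); sgn[idx] <- rev(-sgn[idx])
    } else if (ev$kind == "loss") {
      i <- .locate_gene(tok, ev$genes[1])
      if (is.na(i)) .stopf("event %d (loss of %s): gene not found",
                           k, ev$genes[1])
      tok <- tok[-i]; sgn <- sgn[-i]
    } else {  # translocation(+inversion) or duplication
      g <- ev$genes[1]
      s <- if (is.null(ev$sign)) 1L else as.integer(ev$sign)
      if (ev$kind != "duplication") {
        i <- .locate_gene(tok, g)
        if (is.na(i)) .stopf("event %d (%s of %s): gene not found",
                             k, ev$kind, g)
        if (is.null(ev$sign)) s <- if (ev$kind == "translocation+inversion")
          -sgn[i] else sgn[i]
        tok <- tok[-i]; sgn <- sgn[-i]
      }
      if (!is.na(ev$target_left)) {
        j <- .locate_gene(tok, ev$target_left)
        if (is.na(j)) .stopf("event %d: target_left '%s' not found",
                             k, ev$target_left)
      } else if (!is.na(ev$target_right)) {
        j <- .locate_gene(tok, ev$target_right)
        if (is.na(j)) .stopf("event %d: target_right '%s' not found",
                             k, ev$target_right)
        j <- j - 1L
      } else .stopf("event %d (%s): no target context", k, ev$kind)
      tok <- append(tok, sub("\\.[0-9]+$", "", g), after = j)
      sgn <- append(sgn, s, after = j)
    }
  }
  gene_order(.suffix_dups(tok), sgn, include_cr = order$include_cr)
}

# neighbours of position i in circular vectors
.flanks <- function(tok, i) {
  n <- length(tok)
  c(left = tok[((i - 2L) %% n) + 1L], right = tok[(i %% n) + 1L])
}

#' Infer rearrangement events between two gene orders
#'
#' A deterministic greedy heuristic (not minimal-event inference, which is
#' NP-hard): supernumerary and missing tokens become duplication/loss events;
#' maximal contiguous runs of the derived order that occur strand-reversed in
#' the reference become (block) inversions; remaining differences are
#' resolved by repeatedly moving the single gene whose relocation to its
#' derived context maximally reduces the breakpoint distance (sign change en
#' route is a translocation+inversion). Ties are broken by leftmost position.
#' Replaying the returned events on `reference` with [apply_events()]
#' reproduces the canonical form of `derived`; duplication events are placed
#' last in the list so that insertion contexts resolve.
#'
#' @param reference,derived [gene_order] objects (both containing `cox1`).
#' @return list of [rearrangement_event]; empty if the orders are equal.
#'   On non-convergence an error of class `mitocomp_infer_error` is thrown
#'   carrying the partial event list in its `events` field.
#' @export
infer_events <- function(reference, derived) {
  ref <- canonicalize(reference); der <- canonicalize(derived)
  losses <- list(); dups <- list()
  rtok <- ref$tokens; rsgn <- ref$signs
  dtok <- der$tokens; dsgn <- der$signs

  # 1. equalize multisets: extra derived copies -> duplications (applied
  #    last), extra reference copies -> losses (applied first). Among copies
  #    of a duplicated token, remove the one whose flanking context matches
  #    the reference least, so the surviving copy needs no extra move.
  radj <- .adjacencies(ref)
  base_r <- sub("\\.[0-9]+$", "", rtok)
  repeat {
    base_d <- sub("\\.[0-9]+$", "", dtok)
    lv <- unique(c(base_d, base_r))
    cnt_r <- table(factor(base_r, levels = lv))
    cnt_d <- table(factor(base_d, levels = lv))
    surplus <- names(cnt_d)[cnt_d > cnt_r]
    if (length(surplus) == 0) break
    t <- surplus[1]
    occ <- which(base_d == t)
    dcur <- gene_order(.suffix_dups(dtok), dsgn, include_cr = der$include_cr)
    dadj <- .adjacencies(dcur)
    n <- length(dtok)
    score <- vapply(occ, function(i) {
      sum(dadj[c(((i - 2L) %% n) + 1L, i)] %in% radj)
    }, numeric(1))
    i <- occ[order(score, -occ)][1]
    fl <- .flanks(dtok, i)
    dups[[length(dups) + 1L]] <- rearrangement_event(
      "duplication", t, sign = dsgn[i],
      target_left = sub("\\.[0-9]+$", "", fl["left"]),
      target_right = sub("\\.[0-9]+$", "", fl["right"]))
    dtok <- dtok[-i]; dsgn <- dsgn[-i]
  }
  repeat {
    base_rr <- sub("\\.[0-9]+$", "", rtok)
    base_d <- sub("\\.[0-9]+$", "", dtok)
    lv <- unique(c(base_rr, base_d))
    cnt_r <- table(factor(base_rr, levels = lv))
    cnt_d <- table(factor(base_d, levels = lv))
    deficit <- names(cnt_r)[cnt_r > cnt_d]
    if (length(deficit) == 0) break
    i <- which(base_rr == deficit[1])
    i <- i[length(i)]
    fl <- .flanks(rtok, i)
    losses[[length(losses) + 1L]] <- rearrangement_event(
      "loss", rtok[i],
      source_left = sub("\\.[0-9]+$", "", fl["left"]),
      source_right = sub("\\.[0-9]+$", "", fl["right"]))
    rtok <- rtok[-i]; rsgn <- rsgn[-i]
  }
  # re-suffix after removals so both sides agree
  rtok <- .suffix_dups(rtok); dtok <- .suffix_dups(dtok)
  rw <- gene_order(rtok, rsgn, include_cr = ref$include_cr)
  dw <- gene_order(dtok, dsgn, include_cr = der$include_cr)

  core <- list()
  n <- length(rw$tokens)
  d0 <- breakpoint_distance(rw, dw)
  # small orders: bounded exact search over single events first, so the
  # reported scenario is minimal whenever a short one exists
  if (d0 > 0L && n <= 12L) {
    depth <- if (n <= 6L) 3L else 2L
    exact <- .exact_event_search(rw, dw, depth)
    if (!is.null(exact)) return(c(losses, exact, dups))
  }
  iter <- 0L
  seen <- character(0)
  while (d0 > 0L) {
    iter <- iter + 1L
    if (iter > 4L * n) {
      cnd <- structure(class = c("mitocomp_infer_error", "error", "condition"),
                       list(message = "event inference did not converge",
                            call = sys.call(-1),
                            events = c(losses, core, dups)))
      stop(cnd)
    }
    seen <- c(seen, .canonical_key(rw))
    step <- .best_inversion(rw, dw, d0)
    if (is.null(step)) step <- .best_move(rw, dw, d0)
    if (is.null(step)) step <- .best_ref_inversion(rw, dw, d0)
    # strict local optimum of the breakpoint count: take a zero-cost
    # reversal into an unvisited configuration (one always exists short of
    # genuine non-linearizable input) and keep going
    if (is.null(step)) step <- .best_ref_inversion(rw, dw, d0,
                                                   allow_zero = TRUE,
                                                   seen = seen)
    if (is.null(step)) {
      cnd <- structure(class = c("mitocomp_infer_error", "error", "condition"),
                       list(message = "no single event reduces the breakpoint distance",
                            call = sys.call(-1),
                            events = c(losses, core, dups)))
      stop(cnd)
    }
    core[[length(core) + 1L]] <- step$event
    rw <- step$order
    d0 <- step$dist
  }
  c(losses, core, dups)
}

# breadth-first search over single events (block inversions and signed
# single-gene translocations) for a minimal event sequence; NULL if none
# within max_depth. Only used for small orders.
.exact_event_search <- function(rw, dw, max_depth) {
  target <- .canonical_key(dw)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(.canonical_key(rw), TRUE, envir = visited)
  frontier <- list(list(tok = rw$tokens, sgn = rw$signs, events = list()))
  inc <- rw$include_cr
  for (depth in seq_len(max_depth)) {
    nxt <- vector("list", 0L)
    for (st in frontier) {
      tok <- st$tok; sgn <- st$sgn
      n <- length(tok)
      cand <- list()
      for (i in seq_len(n)) for (L in seq_len(n - 1L)) {
        idx <- ((i - 1L + 0:(L - 1L)) %% n) + 1L
        t2 <- tok; s2 <- sgn
        t2[idx] <- rev(t2[idx]); s2[idx] <- rev(-s2[idx])
        cand[[length(cand) + 1L]] <- list(
          tok = t2, sgn = s2,
          ev = rearrangement_event(if (L >= 2L) "block-inversion"
                                   else "inversion", tok[idx]))
      }
      for (j in seq_len(n)) for (k in seq_len(n - 1L)) for (sg in c(-1L, 1L)) {
        t0 <- tok[-j]; s0 <- sgn[-j]
        cand[[length(cand) + 1L]] <- list(
          tok = append(t0, tok[j], after = k),
          sgn = append(s0, sg, after = k),
          ev = rearrangement_event(
            if (sg == sgn[j]) "translocation" else "translocation+inversion",
            tok[j], sign = sg, target_left = t0[k]))
      }
      for (cd in cand) {
        o <- gene_order(cd$tok, cd$sgn, include_cr = inc)
        key <- .canonical_key(o)
        evs <- c(st$events, list(cd$ev))
        if (key == target) return(evs)
        if (depth < max_depth &&
            !exists(key, envir = visited, inherits = FALSE)) {
          assign(key, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- list(tok = cd$tok, sgn = cd$sgn,
                                          events = evs)
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  NULL
}

# best in-place (block) inversion: maximal runs of derived found
# strand-reversed in reference; choose max distance reduction, then longest,
# then leftmost in derived
.best_inversion <- function(rw, dw, d0) {
  dt <- dw$tokens; ds <- dw$signs
  rt <- rw$tokens; rs <- rw$signs
  n <- length(dt)
  rkey <- paste0(ifelse(rs < 0, "-", "+"), rt)
  # doubled, space-delimited haystack covers circular occurrences
  hay <- paste0(" ", paste(c(rkey, rkey), collapse = " "), " ")
  best <- NULL
  for (i in seq_len(n)) {
    # extend run starting at derived position i
    maxlen <- 0L
    for (L in seq_len(n - 1L)) {
      idx <- ((i - 1L + 0:(L - 1L)) %% n) + 1L
      seg_rev <- paste0(ifelse(rev(-ds[idx]) < 0, "-", "+"), rev(dt[idx]))
      needle <- paste0(" ", paste(seg_rev, collapse = " "), " ")
      if (grepl(needle, hay, fixed = TRUE)) maxlen <- L else break
    }
    if (maxlen == 0L) next
    idx <- ((i - 1L + 0:(maxlen - 1L)) %% n) + 1L
    ev <- rearrangement_event(
      if (maxlen >= 2L) "block-inversion" else "inversion",
      dt[idx])
    cand <- tryCatch(apply_events(rw, ev), error = function(e) NULL)
    if (is.null(cand)) next
    dd <- breakpoint_distance(cand, dw)
    red <- d0 - dd
    if (red > 0 && (is.null(best) || red > best$red ||
                    (red == best$red && maxlen > length(best$event$genes))))
      best <- list(event = ev, order = cand, dist = dd, red = red)
  }
  best
}

# best single-gene relocation to its derived context (anchored on the
# derived left or right neighbour, whichever works out better)
.best_move <- function(rw, dw, d0) {
  rt <- rw$tokens; rs <- rw$signs
  dt <- dw$tokens; ds <- dw$signs
  n <- length(rt)
  best <- NULL
  for (j in seq_len(n)) {
    g <- rt[j]
    p <- match(g, dt)
    if (is.na(p)) next
    tfl <- .flanks(dt, p)
    sfl <- .flanks(rt, j)
    kind <- if (ds[p] != rs[j]) "translocation+inversion" else "translocation"
    for (anchor in c("left", "right")) {
      ev <- rearrangement_event(
        kind, g, sign = ds[p],
        target_left = if (anchor == "left") tfl["left"] else NA_character_,
        target_right = tfl["right"],
        source_left = sfl["left"], source_right = sfl["right"])
      cand <- tryCatch(apply_events(rw, ev), error = function(e) NULL)
      if (is.null(cand)) next
      dd <- tryCatch(breakpoint_distance(cand, dw), error = function(e) NA)
      if (is.na(dd)) next
      red <- d0 - dd
      if (red > 0 && (is.null(best) || red > best$red)) {
        # keep both contexts on the recorded event for reporting
        ev$target_left <- unname(tfl["left"])
        best <- list(event = ev, order = cand, dist = dd, red = red,
                     anchor = anchor)
        # re-apply with full context must give the same order; if the two
        # anchors disagree the right-anchored application is kept via order
        if (anchor == "right") best$event$target_left <- NA_character_
      }
    }
  }
  best
}

# fallback: invert any contiguous run of the reference whose reversal
# reduces the breakpoint distance (greedy sorting-by-reversals step); used
# when no derived-run inversion and no single-gene move makes progress
.best_ref_inversion <- function(rw, dw, d0, allow_zero = FALSE,
                                seen = character(0)) {
  rt <- rw$tokens; rs <- rw$signs
  n <- length(rt)
  dadj <- .adjacencies(dw)
  best <- NULL
  for (L in seq_len(n - 1L)) {
    for (i in seq_len(n)) {
      idx <- ((i - 1L + 0:(L - 1L)) %% n) + 1L
      tok2 <- rt; sgn2 <- rs
      tok2[idx] <- rev(tok2[idx]); sgn2[idx] <- rev(-sgn2[idx])
      cand <- gene_order(tok2, sgn2, include_cr = rw$include_cr)
      dd <- sum(!(.adjacencies(cand) %in% dadj))
      red <- d0 - dd
      take <- red > 0 || (allow_zero && red == 0 &&
                            !(.canonical_key(cand) %in% seen))
      if (take && (is.null(best) || red > best$red)) {
        ev <- rearrangement_event(
          if (L >= 2L) "block-inversion" else "inversion", rt[idx])
        best <- list(event = ev, order = cand, dist = dd, red = red)
      }
    }
    if (!is.null(best) && best$red > 0) break  # shortest helpful run wins
    if (!is.null(best) && allow_zero) break
  }
  best
}

# --- pattern grouping -----------------------------------------------------

#' Group identical gene orders into named patterns
#'
#' Partitions records by canonical-form equality. The class matching the
#' reference (by default the pancrustacean ground pattern) is labelled `Gr`;
#' other classes take the label supplied for their members, or `P1`, `P2`,
#' ... assigned in order of each class's smallest member id (so the result
#' does not depend on input ordering). Each derived class carries the event
#' list inferred against the reference.
#'
#' @param orders named list of [gene_order] objects (names = record ids).
#' @param labels optional named character vector mapping record id to a
#'   pattern label.
#' @param reference reference [gene_order]; default [ground_pattern()] with
#'   `include_cr` taken from the first order.
#' @return list of `gene_order_pattern` objects with fields `label`,
#'   `canonical_order`, `members`, `events_vs_ground`, `breakpoints_vs_ground`.
#' @export
group_patterns <- function(orders, labels = NULL, reference = NULL) {
  if (length(orders) == 0) .stopf("no orders supplied")
  if (is.null(names(orders)) || anyNA(names(orders)) ||
      any(!nzchar(names(orders))))
    .stopf("orders must be a named list (names are record ids)")
  if (is.null(reference))
    reference <- ground_pattern(include_cr = orders[[1]]$include_cr)
  ref_key <- .canonical_key(reference)
  keys <- vapply(orders, .canonical_key, character(1))
  classes <- split(names(orders), keys)
  # deterministic class ordering: by smallest member id
  classes <- classes[order(vapply(classes, function(m) min(m), character(1)))]
  auto <- 0L
  out <- list()
  for (key in names(classes)) {
    members <- sort(classes[[key]])
    canon <- canonicalize(orders[[members[1]]])
    if (identical(key, ref_key)) {
      label <- "Gr"
      events <- list()
      bp <- 0L
    } else {
      lab <- unique(stats::na.omit(labels[members]))
      if (length(lab) == 1) label <- unname(lab)
      else { auto <- auto + 1L; label <- paste0("P", auto) }
      events <- tryCatch(infer_events(reference, canon),
                         error = function(e) {
                           if (!is.null(e$events)) e$events else list()
                         })
      bp <- tryCatch(.bp_vs_reference(reference, canon),
                     error = function(e) NA_integer_)
    }
    out[[length(out) + 1L]] <- structure(
      list(label = label, canonical_order = canon, members = members,
           events_vs_ground = events, breakpoints_vs_ground = bp),
      class = "gene_order_pattern")
  }
  if (anyDuplicated(vapply(out, `[[`, character(1), "label")))
    .stopf("duplicate pattern labels; check the supplied label map")
  out
}

# breakpoint count vs reference, tolerating duplications/losses by reducing
# to the common token multiset first
.bp_vs_reference <- function(reference, order) {
  rt <- canonicalize(reference); dt <- canonicalize(order)
  a <- rt$tokens; as <- rt$signs
  b <- dt$tokens; bs <- dt$signs
  drop_a <- setdiff(a, b); drop_b <- setdiff(b, a)
  for (g in drop_a) { i <- which(a == g)[1]; a <- a[-i]; as <- as[-i] }
  for (g in drop_b) { i <- which(b == g)[1]; b <- b[-i]; bs <- bs[-i] }
  breakpoint_distance(gene_order(.suffix_dups(a), as, rt$include_cr),
                      gene_order(.suffix_dups(b), bs, dt$include_cr))
}

#' @export
print.gene_order_pattern <- function(x, ...) {
  cat(sprintf("<pattern %s> %d member(s), %d event(s) vs ground, %s breakpoints\n",
              x$label, length(x$members), length(x$events_vs_ground),
              x$breakpoints_vs_ground))
  invisible(x)
}
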