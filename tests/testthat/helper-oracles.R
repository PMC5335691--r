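# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own canonical-form and distance code paths.

# -- random event scripts on a gene order (used by replay + acceptance) ----
rand_event_script <- function(order, n_ev = sample(1:4, 1)) {
  evs <- list()
  cur <- order
  for (k in seq_len(n_ev)) {
    type <- sample(c("transloc", "inv", "blockinv"), 1,
                   prob = c(0.5, 0.25, 0.25))
    tk <- cur$tokens
    ev <- if (type == "transloc") {
      g <- sample(tk[tk != "cox1"], 1)
      rearrangement_event("translocation", g, sign = sample(c(-1L, 1L), 1),
                          target_left = sample(setdiff(tk, g), 1))
    } else if (type == "inv") {
      rearrangement_event("inversion", sample(tk[tk != "cox1"], 1))
    } else {
      i <- sample(seq_along(tk), 1)
      L <- sample(2:5, 1)
      idx <- ((i - 1 + 0:(L - 1)) %% length(tk)) + 1
      rearrangement_event("block-inversion", tk[idx])
    }
    evs[[k]] <- ev
    cur <- apply_events(cur, ev)
  }
  list(events = evs, derived = cur)
}

# -- toy signed circular orders for the brute-force suite ------------------
toy_order <- function(n, shuffle = TRUE) {
  tok <- c("cox1", paste0("g", seq_len(n - 1) + 1))
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  if (shuffle) {
    perm <- sample(n)
    tok <- tok[perm]
  }
  gene_order(tok, sgn, include_cr = FALSE)
}

# independent canonical key: lexicographic minimum over all rotations of the
# order and of its mirror (reverse, signs flipped) -- no anchor gene needed
oracle_key <- function(tok, sgn) {
  n <- length(tok)
  variants <- character(2 * n)
  mt <- rev(tok); ms <- rev(-sgn)
  for (r in seq_len(n)) {
    idx <- c(r:n, seq_len(r - 1))[seq_len(n)]
    variants[r] <- paste(ifelse(sgn[idx] < 0, "-", "+"), tok[idx],
                         sep = "", collapse = " ")
    variants[n + r] <- paste(ifelse(ms[idx] < 0, "-", "+"), mt[idx],
                             sep = "", collapse = " ")
  }
  min(variants)
}

# all single-event neighbours of a state: every block inversion and every
# single-gene translocation (both signs)
oracle_neighbours <- function(tok, sgn) {
  n <- length(tok)
  out <- list()
  for (i in seq_len(n)) for (L in seq_len(n - 1)) {
    idx <- ((i - 1 + 0:(L - 1)) %% n) + 1
    t2 <- tok; s2 <- sgn
    t2[idx] <- rev(t2[idx]); s2[idx] <- rev(-s2[idx])
    out[[length(out) + 1]] <- list(tok = t2, sgn = s2)
  }
  for (j in seq_len(n)) {
    t0 <- tok[-j]; s0 <- sgn[-j]
    for (k in 0:(n - 2)) for (sg in c(-1L, 1L)) {
      out[[length(out) + 1]] <- list(tok = append(t0, tok[j], after = k),
                                     sgn = append(s0, sg, after = k))
    }
  }
  out
}

# breadth-first search for the minimum number of single events turning `a`
# into `b` (up to rotation/mirror); NA if beyond max_depth
oracle_min_events <- function(a, b, max_depth = 3) {
  target <- oracle_key(b$tokens, b$signs)
  if (oracle_key(a$tokens, a$signs) == target) return(0L)
  frontier <- list(list(tok = a$tokens, sgn = a$signs))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(oracle_key(a$tokens, a$signs), TRUE, envir = visited)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) {
      for (nb in oracle_neighbours(st$tok, st$sgn)) {
        key <- oracle_key(nb$tok, nb$sgn)
        if (key == target) return(depth)
        if (!exists(key, envir = visited, inherits = FALSE)) {
          assign(key, TRUE, envir = visited)
          nxt[[length(nxt) + 1]] <- nb
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  NA_integer_
}

# -- small GenBank fixture text -------------------------------------------
tiny_genbank_text <- function() {
  c("LOCUS       TEST0001         400 bp    DNA     circular MIT",
    "ACCESSION   TEST0001",
    "VERSION     TEST0001",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..100",
    "                     /gene=\"COI\"",
    "     tRNA            101..200",
    "                     /gene=\"tRNA-Asp\"",
    "     rRNA            complement(290..355)",
    "                     /gene=\"srRNA\"",
    "//")
}

# nearest-centroid classification accuracy in an MDS configuration
centroid_accuracy <- function(coords, groups) {
  cent <- apply(coords, 2, function(x) tapply(x, groups, mean))
  pred <- apply(coords, 1, function(x)
    rownames(cent)[which.min(colSums((t(cent) - x)^2))])
  mean(pred == groups)
}
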