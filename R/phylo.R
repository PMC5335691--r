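# Phylogenetic consistency of gene-order patterns: Newick input, Fitch
# parsimony on a single unordered multistate character, per-pattern
# monophyly.

#' Parse a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contracts the rest
#' of the pipeline relies on: a single tree, unique leaf labels. Branch
#' lengths are retained but ignored downstream.
#'
#' @param text Newick string (terminating semicolon required) or path to a
#'   file containing one.
#' @return an [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  tr <- if (length(text) == 1 && !grepl(";", text) && file.exists(text))
    ape::read.tree(file = text)
  else ape::read.tree(text = text)
  if (is.null(tr)) .stopf("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) .stopf("expected exactly one tree, got %d", length(tr))
    tr <- tr[[1]]
  }
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup) > 0)
    .stopf("duplicate leaf label(s): %s", paste(unique(dup), collapse = ", "))
  tr
}

# Fitch parsimony step count for one unordered multistate character.
# Post-order pass over the (arbitrarily rooted) tree: a node's state set is
# the intersection of its children's sets if non-empty, else their union
# with one step added.
.fitch_steps <- function(tree, states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- states[tree$tip.label[i]]
  steps <- 0L
  for (r in seq_len(nrow(tree$edge))) {
    # postorder guarantees children visited before parents; accumulate
    parent <- tree$edge[r, 1]; child <- tree$edge[r, 2]
    if (is.null(sets[[parent]])) {
      sets[[parent]] <- sets[[child]]
    } else {
      inter <- intersect(sets[[parent]], sets[[child]])
      if (length(inter) > 0) sets[[parent]] <- inter
      else {
        sets[[parent]] <- union(sets[[parent]], sets[[child]])
        steps <- steps + 1L
      }
    }
  }
  steps
}

#' Phylogenetic consistency of a pattern assignment
#'
#' Treats the gene-order pattern label as a single unordered multistate
#' character on the leaves and asks whether it could have arisen without
#' homoplasy: the Fitch parsimony step count equals its minimum possible
#' value (number of distinct labels - 1) iff every derived pattern arose
#' exactly once on the tree. Additionally reports, per pattern, whether its
#' members form an exact clade.
#'
#' @param tree an [ape::phylo] tree (or Newick string, parsed on the fly).
#' @param assignment named character vector mapping every leaf label to a
#'   pattern label.
#' @return list with `steps` (Fitch step count), `min_steps`, `consistent`
#'   (steps == min_steps), and `patterns`: a data.frame with columns
#'   `pattern`, `n_members`, `monophyletic`.
#' @export
pattern_tree_consistency <- function(tree, assignment) {
  if (is.character(tree)) tree <- parse_newick(tree)
  leaves <- tree$tip.label
  missing <- setdiff(leaves, names(assignment))
  if (length(missing) > 0)
    .stopf("leaf/leaves without a pattern assignment: %s",
           paste(missing, collapse = ", "))
  states <- assignment[leaves]
  labs <- sort(unique(unname(states)))
  min_steps <- length(labs) - 1L
  steps <- if (min_steps == 0L) 0L else .fitch_steps(tree, states)
  mono <- vapply(labs, function(p) {
    tips <- leaves[states == p]
    if (length(tips) <= 1 || length(tips) == length(leaves)) return(TRUE)
    ape::is.monophyletic(tree, tips)
  }, logical(1))
  list(steps = steps, min_steps = min_steps,
       consistent = steps == min_steps,
       patterns = data.frame(pattern = labs,
                             n_members = as.integer(table(factor(unname(states),
                                                                 levels = labs))),
                             monophyletic = unname(mono),
                             stringsAsFactors = FALSE))
}
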