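# Helpers for the phylogeny-aware gap-pattern and robustness properties.

# Leaves descending from the child end of a branch (branch = child node id).
branch_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node]
  else ape::extract.clade(tree, node)$tip.label
}

# Single clean insertion events of a simulation: contiguous in the true
# alignment, not overlapping any other indel event, flanking columns present
# in every leaf and conserved within the clade where the indel decision is
# made (the event's descendants plus their sibling clade), and with boundary
# residues differing from the flanks (identical neighbours make the left or
# right placement score-equivalent, which no aligner can resolve).
clean_insertion_events <- function(sim) {
  tree <- sim$tree
  cols_of <- function(ids) {
    cc <- match(ids, sim$columns)
    cc[!is.na(cc)]
  }
  indels <- Filter(function(e) e$type != "sub", sim$events)
  spans <- lapply(indels, function(e) cols_of(e$ids))
  rows <- lapply(strsplit(sim$msa, ""), identity)
  nc <- length(sim$columns)
  out <- list()
  for (k in seq_along(indels)) {
    ev <- indels[[k]]
    if (ev$type != "ins") next
    cc <- spans[[k]]
    if (length(cc) != ev$length || length(cc) == 0L) next  # partially lost
    if (any(diff(sort(cc)) != 1L)) next
    lo <- min(cc) - 1L; hi <- max(cc) + 1L
    if (lo < 1L || hi > nc) next
    overlap <- vapply(spans[-k], function(s) {
      length(s) && min(s) <= hi && max(s) >= lo
    }, logical(1L))
    if (any(overlap)) next
    par <- tree$edge[match(ev$branch, tree$edge[, 2L]), 1L]
    sibs <- tree$edge[tree$edge[, 1L] == par, 2L]
    nb <- unique(unlist(lapply(sibs, function(s) branch_leaves(tree, s))))
    flank_ok <- all(vapply(c(lo, hi), function(c_) {
      ch <- vapply(rows, `[[`, character(1L), c_)
      all(ch != "-") && length(unique(ch[nb])) == 1L
    }, logical(1L)))
    if (!flank_ok) next
    ins_aa <- graphmsa:::AA[ev$aa]
    anchor <- rows[[branch_leaves(tree, ev$branch)[1L]]]
    if (ins_aa[1L] == anchor[lo] || ins_aa[length(ins_aa)] == anchor[hi]) next
    out[[length(out) + 1L]] <- ev
  }
  out
}

# TRUE if, in the test alignment, every column holding the event's inserted
# residues is gapped in all rows outside the branch's descendant leaves.
insertion_pattern_ok <- function(ev, sim, test_msa) {
  desc <- branch_leaves(sim$tree, ev$branch)
  others <- setdiff(names(test_msa), desc)
  rows <- strsplit(test_msa, "")
  test_cols <- integer(0L)
  for (leaf in desc) {
    st <- sim$node_states[[match(leaf, sim$tree$tip.label)]]
    pos <- match(ev$ids, st$ids)
    pos <- pos[!is.na(pos)]
    if (!length(pos)) next
    non_gap <- which(rows[[leaf]] != "-")
    test_cols <- union(test_cols, non_gap[pos])
  }
  length(test_cols) > 0L &&
    all(vapply(others, function(o) all(rows[[o]][test_cols] == "-"),
               logical(1L)))
}

# Swap the labels of two tips on opposite sides of the root (deterministic).
swap_two_leaves <- function(tree) {
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  t1 <- sort(branch_leaves(tree, kids[1L]))[1L]
  t2 <- sort(branch_leaves(tree, kids[2L]))[1L]
  i <- match(t1, tree$tip.label); j <- match(t2, tree$tip.label)
  tree$tip.label[c(i, j)] <- tree$tip.label[c(j, i)]
  tree
}
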