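# Residue identity keys: every residue is (row name, index in the degapped
# sequence); columns are sets of such keys, pairs are unordered key pairs.
msa_keys <- function(msa) {
  ids <- names(msa)
  rows <- lapply(msa, function(s) strsplit(s, "")[[1L]])
  nc <- unique(lengths(rows))
  if (length(nc) != 1L) stop("ragged alignment rows")
  lapply(seq_len(nc), function(c_) {
    ks <- character(0L)
    for (r in ids) {
      ch <- rows[[r]][c_]
      if (ch != "-") {
        ks <- c(ks, paste0(r, ":", sum(rows[[r]][seq_len(c_)] != "-")))
      }
    }
    sort(ks)
  })
}

msa_pairs <- function(cols) {
  out <- character(0L)
  for (ks in cols) {
    if (length(ks) >= 2L) {
      cmb <- utils::combn(ks, 2L)
      out <- c(out, paste(cmb[1L, ], cmb[2L, ]))
    }
  }
  out
}

check_same_sequences <- function(test, reference) {
  if (!setequal(names(test), names(reference))) {
    stop("test and reference alignments contain different sequences")
  }
  for (id in names(reference)) {
    if (gsub("-", "", test[[id]]) != gsub("-", "", reference[[id]])) {
      stop("sequence ", id, " differs between test and reference alignments")
    }
  }
}

#' Developer and modeler scores of a test alignment
#'
#' The developer score fD is the fraction of homologous residue pairs of
#' the reference alignment that are reproduced in the test alignment; the
#' modeler score fM divides the same number of shared pairs by the number
#' of pairs in the test alignment instead.
#'
#' @param test,reference Alignments (named character vectors of equal-length
#'   rows) over the same sequences.
#' @return List with `fD` and `fM`.
#' @export
developer_modeler_scores <- function(test, reference) {
  check_same_sequences(test, reference)
  pr <- msa_pairs(msa_keys(reference))
  pt <- msa_pairs(msa_keys(test))
  shared <- length(intersect(pr, pt))
  list(fD = if (length(pr)) shared / length(pr) else NA_real_,
       fM = if (length(pt)) shared / length(pt) else NA_real_)
}

#' True column score
#'
#' Fraction of reference columns whose residue content (the set of
#' sequence positions present, i.e. the column with its gap pattern) is
#' reproduced exactly by some test column.
#'
#' @inheritParams developer_modeler_scores
#' @return Scalar in `[0, 1]`.
#' @export
column_score <- function(test, reference) {
  check_same_sequences(test, reference)
  sig <- function(cols) vapply(cols, paste, character(1L), collapse = "|")
  ref_sig <- sig(msa_keys(reference))
  test_sig <- sig(msa_keys(test))
  mean(ref_sig %in% test_sig)
}

#' Relative alignment length
#'
#' @inheritParams developer_modeler_scores
#' @return Test columns divided by reference columns.
#' @export
relative_length <- function(test, reference) {
  nchar(test[[1L]]) / nchar(reference[[1L]])
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartitions, with a normalized
#' variant dividing by the maximum `2 (n - 3)`.
#'
#' @param tree1,tree2 `phylo` objects over the same taxa.
#' @return List with `distance` and `normalized`.
#' @export
robinson_foulds <- function(tree1, tree2) {
  n <- length(tree1$tip.label)
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees are over different taxa")
  }
  if (n < 4L) return(list(distance = 0, normalized = 0))
  d <- phangorn::RF.dist(ape::unroot(tree1), ape::unroot(tree2))
  list(distance = d, normalized = d / (2 * (n - 3)))
}

# presence matrix (tree nodes x alignment columns) of the reconstruction
reconstruction_presence <- function(result) {
  tree <- result$tree
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  node_ids <- attr(result$msa, "node_ids")
  nc <- length(node_ids)
  pres <- matrix(FALSE, nn, nc)
  for (i in seq_len(ntip)) {
    pres[i, ] <- strsplit(result$msa[[tree$tip.label[i]]], "")[[1L]] != "-"
  }
  for (v in (ntip + 1L):nn) {
    pres[v, ] <- node_ids %in% result$anc_sets[[v]]
  }
  pres
}

# maximal runs of inserted/deleted columns along one branch
branch_runs <- function(pres_par, pres_ch) {
  rel <- which(pres_par | pres_ch)
  state <- ifelse(pres_par[rel] & !pres_ch[rel], "del",
                  ifelse(!pres_par[rel] & pres_ch[rel], "ins", "same"))
  runs <- list()
  k <- 1L
  while (k <= length(rel)) {
    if (state[k] != "same") {
      j <- k
      while (j < length(rel) && state[j + 1L] == state[k]) j <- j + 1L
      runs[[length(runs) + 1L]] <- list(type = state[k],
                                        cols = rel[k:j],
                                        length = j - k + 1L)
      k <- j + 1L
    } else k <- k + 1L
  }
  runs
}

clade_key <- function(tree, node) {
  ntip <- length(tree$tip.label)
  tips <- if (node <= ntip) tree$tip.label[node]
          else ape::extract.clade(tree, node)$tip.label
  paste(sort(tips), collapse = ",")
}

#' Indel-event statistics of a reconstruction against the simulated truth
#'
#' Events are inferred by diffing the presence/absence rows of each
#' branch's parent and child ancestral sequences in the reconstructed
#' alignment.  An inferred event is counted correct if it starts at the
#' correct column, has the right length, and sits on the correct branch of
#' the guide tree; columns of the two alignments are matched through the
#' residues they contain (never through column indices), so no parsimony
#' reconstruction of the truth is involved.
#'
#' @param result A `graphmsa_result` aligned on the simulation's true tree.
#' @param sim The `sim_result` ground truth.
#' @return List with inferred/true event counts, their ratio, the inferred
#'   insertion/deletion ratio, the relative alignment length, and the
#'   fraction of correctly inferred events.
#' @export
indel_event_stats <- function(result, sim) {
  tree_r <- result$tree
  tree_s <- sim$tree
  if (robinson_foulds(tree_r, tree_s)$distance != 0) {
    stop("reconstruction and simulation trees differ in topology")
  }
  # residue -> true column lookup
  ref_keys <- msa_keys(sim$msa)
  res2true <- new.env(parent = emptyenv())
  for (c_ in seq_along(ref_keys)) {
    for (kk in ref_keys[[c_]]) assign(kk, c_, envir = res2true)
  }
  test_keys <- msa_keys(result$msa)

  # true events, visible in the true MSA
  col_of <- setNames(seq_along(sim$columns), sim$columns)
  true_events <- list()
  for (ev in sim$events) {
    if (ev$type == "sub") next
    cols <- col_of[as.character(ev$ids)]
    cols <- cols[!is.na(cols)]
    if (!length(cols)) next
    true_events[[length(true_events) + 1L]] <-
      list(type = ev$type, branch = clade_key(tree_s, ev$branch),
           start = min(cols), length = ev$length, used = FALSE)
  }

  # inferred events from the reconstruction's ancestral presence rows
  pres <- reconstruction_presence(result)
  ntip <- length(tree_r$tip.label)
  inferred <- list()
  for (k in seq_len(nrow(tree_r$edge))) {
    par <- tree_r$edge[k, 1L]; ch <- tree_r$edge[k, 2L]
    for (run in branch_runs(pres[par, ], pres[ch, ])) {
      inferred[[length(inferred) + 1L]] <-
        list(type = run$type, branch = clade_key(tree_r, ch),
             cols = run$cols, length = run$length)
    }
  }

  n_correct <- 0L
  for (ev in inferred) {
    # map the event's start column into the truth via any contained residue
    start_keys <- test_keys[[ev$cols[1L]]]
    mapped <- vapply(start_keys, function(kk) {
      get0(kk, envir = res2true, ifnotfound = NA_integer_)
    }, integer(1L))
    mapped <- mapped[!is.na(mapped)]
    if (!length(mapped)) next
    for (t_ in seq_along(true_events)) {
      te <- true_events[[t_]]
      if (!te$used && te$type == ev$type && te$branch == ev$branch &&
          te$length == ev$length && te$start %in% mapped) {
        true_events[[t_]]$used <- TRUE
        n_correct <- n_correct + 1L
        break
      }
    }
  }
  types <- vapply(inferred, `[[`, character(1L), "type")
  n_ins <- sum(types == "ins"); n_del <- sum(types == "del")
  list(n_inferred = length(inferred), n_true = length(true_events),
       event_count_ratio = if (length(true_events))
         length(inferred) / length(true_events) else NA_real_,
       ins_del_ratio = if (n_del) n_ins / n_del else NA_real_,
       relative_length = relative_length(result$msa, sim$msa),
       fraction_correct = if (length(inferred))
         n_correct / length(inferred) else NA_real_)
}
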