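#' Alignment run options
#'
#' Collects every tunable of the aligner.  Defaults reproduce the standard
#' configuration: WAG model, maximum-likelihood distance re-estimation, one
#' re-estimation round, terminal-gap probability 0.1, forced alignment of
#' initial methionines, and edge-reuse penalty lifetime 1.
#'
#' @param model `"WAG"` or `"GONNET"`.
#' @param estimate_aafreqs Estimate equilibrium frequencies from the input
#'   (+F).
#' @param cs_profile Optional path to a context profile library, or a
#'   [context_profile_library()] object; `NULL` disables context-specific
#'   profiles.
#' @param distance `"mldist"` (maximum-likelihood) or `"pdist"`
#'   (p-distance, Kimura-transformed) for re-estimated guide-tree distances.
#' @param end_indel_prob Terminal gap probability `alpha`; `-1` disables the
#'   terminal/internal gap distinction.
#' @param force_align_m Add a bonus for matching the two initial
#'   methionines.
#' @param lifetime Edge reuse penalty e-folding distance `l`; `0` keeps
#'   insertions forever, `Inf` disables the penalty.
#' @param iters Maximum number of alignment iterations (guide-tree
#'   re-estimation rounds + 1).
#' @param tree Optional guide tree (`phylo` or path to a Newick file);
#'   bypasses guide-tree estimation.
#' @param ancestral Keep per-node ancestral information for
#'   [ancestral_msa()].
#' @param delta,epsilon,omega,g Pair-HMM parameters (see
#'   [pairhmm_params()]).
#' @param m_bonus Bonus (nats) for the forced methionine match.
#' @param kmer_k Word length of the alignment-free distance.
#' @return A list of class `msa_options`.
#' @export
msa_options <- function(model = c("WAG", "GONNET"), estimate_aafreqs = FALSE,
                        cs_profile = NULL, distance = c("mldist", "pdist"),
                        end_indel_prob = 0.1, force_align_m = TRUE,
                        lifetime = 1, iters = 2L, tree = NULL,
                        ancestral = FALSE, delta = 0.03, epsilon = 0.6,
                        omega = 0.005, g = 1, m_bonus = 10, kmer_k = 6L) {
  model <- match.arg(model)
  distance <- match.arg(distance)
  structure(list(model = model, estimate_aafreqs = estimate_aafreqs,
                 cs_profile = cs_profile, distance = distance,
                 end_indel_prob = end_indel_prob,
                 force_align_m = force_align_m, lifetime = lifetime,
                 iters = as.integer(iters), tree = tree,
                 ancestral = ancestral,
                 params = pairhmm_params(delta, epsilon, omega,
                                         alpha = end_indel_prob, g = g),
                 m_bonus = m_bonus, kmer_k = kmer_k),
            class = "msa_options")
}

#' Build leaf sequence graphs
#'
#' Without context-specific profiles, leaves carry indicator likelihood
#' vectors.  With a profile library, each leaf's context-specific profile is
#' computed, its divergence adjusted to the leaf's terminal branch length
#' (tau interpolation), and converted to probabilistic-leaf likelihood
#' vectors; the terminal branch is then treated as length 0 by the
#' substitution model, since its expected evolution is already encoded in
#' the leaf vectors.
#'
#' @param records Named character vector of sequences.
#' @param model An [aa_model()].
#' @param options An [msa_options()].
#' @param tree Guide tree (needed for terminal branch lengths when profiles
#'   are active).
#' @return Named list of leaf `seq_graph`s.
#' @export
prepare_leaves <- function(records, model, options, tree = NULL) {
  lib <- options$cs_profile
  if (is.null(lib)) {
    return(lapply(setNames(names(records), names(records)), function(id) {
      from_sequence(id, records[[id]], model = model)
    }))
  }
  if (is.character(lib)) lib <- read_profile_library(lib, guess_dialect(lib))
  cons <- library_conservation(lib, model$pi)
  tbl <- terminal_branch_lengths(tree, names(records))
  out <- lapply(setNames(names(records), names(records)), function(id) {
    prof <- context_profile(records[[id]], lib)
    prof <- adjust_tau(prof, tbl[[id]], conservation = cons)
    from_sequence(id, records[[id]],
                  L = to_probabilistic_leaf(prof, model$pi), model = model)
  })
  out
}

guess_dialect <- function(path) {
  first <- readLines(path, n = 5L, warn = FALSE)
  if (any(grepl("^(K|width|alphabet)\t|graphmsa", first))) "native_tsv" else "cs_blast"
}

terminal_branch_lengths <- function(tree, ids) {
  if (is.null(tree)) return(setNames(rep(0, length(ids)), ids))
  bl <- tree$edge.length[match(seq_along(tree$tip.label), tree$edge[, 2L])]
  names(bl) <- tree$tip.label
  bl[ids]
}

#' Progressive alignment over a guide tree
#'
#' Post-order traversal: at each internal node the two child graphs are
#' aligned (match scores from probabilistic ancestral sequences, transition
#' scores from the combined branch distance, edge penalties from the reuse
#' history at the current height), the children's pending indels are
#' resolved using this alignment as the closest outgroup, and the graphs
#' are merged.  At the root, remaining pending indels resolve as
#' insertions.
#'
#' @param tree Rooted binary guide tree (`phylo`).
#' @param graphs Named list of leaf `seq_graph`s (one per tip label).
#' @param model An [aa_model()].
#' @param options An [msa_options()].
#' @return List with the root `seq_graph`, per-tree-node ancestral node-id
#'   sets (`anc_sets`, in root-graph id space), the indel `decisions`, and
#'   the per-node alignment scores.
#' @export
progressive_align <- function(tree, graphs, model, options = msa_options()) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  h <- node_heights(tree)
  cs_on <- !is.null(options$cs_profile)
  glist <- vector("list", nn)
  anc_sets <- vector("list", nn)
  desc <- vector("list", nn)
  decisions <- list()
  scores_log <- numeric(0L)
  for (i in seq_len(ntip)) {
    g <- graphs[[tree$tip.label[i]]]
    if (is.null(g)) stop("no sequence for guide-tree leaf ", tree$tip.label[i])
    glist[[i]] <- g
    anc_sets[[i]] <- setdiff(seq_len(g$n), c(g$start, g$end))
    desc[[i]] <- i
  }
  po <- ape::reorder.phylo(tree, "postorder")
  internal <- unique(po$edge[, 1L])
  for (v in internal) {
    ch <- po$edge[po$edge[, 1L] == v, 2L]
    bl <- po$edge.length[po$edge[, 1L] == v]
    c1 <- ch[1L]; c2 <- ch[2L]
    d1 <- bl[1L]; d2 <- bl[2L]
    ds1 <- if (cs_on && c1 <= ntip) 0 else d1   # substitution-model distances
    ds2 <- if (cs_on && c2 <= ntip) 0 else d2
    g1 <- glist[[c1]]; g2 <- glist[[c2]]
    S <- match_scores(g1$L, g2$L, ds1, ds2, model)
    scs <- transition_scores(options$params, d1 + d2)
    pen1 <- graph_penalties(g1, h[v], options$lifetime)
    pen2 <- graph_penalties(g2, h[v], options$lifetime)
    ares <- align_graphs(g1, g2, S, scs, pen1, pen2,
                         force_align_m_bonus =
                           if (options$force_align_m) options$m_bonus else 0)
    scores_log[as.character(v)] <- ares$score
    g1 <- resolve_pending_indels(g1, ares$matched[, 1L])
    for (dc in attr(g1, "decisions") %||% list()) {
      if (dc$decision == "deletion") {
        anc_sets[[c1]] <- union(anc_sets[[c1]], dc$chars)
      }
      decisions[[length(decisions) + 1L]] <- c(dc, node = c1)
    }
    g2 <- resolve_pending_indels(g2, ares$matched[, 2L])
    for (dc in attr(g2, "decisions") %||% list()) {
      if (dc$decision == "deletion") {
        anc_sets[[c2]] <- union(anc_sets[[c2]], dc$chars)
      }
      decisions[[length(decisions) + 1L]] <- c(dc, node = c2)
    }
    merged <- merge_graphs(g1, g2, ares, ds1, ds2, model, height = h[v])
    map_a <- attr(merged, "map_a"); map_b <- attr(merged, "map_b")
    for (u in desc[[c1]]) anc_sets[[u]] <- map_a[anc_sets[[u]]]
    for (u in desc[[c2]]) anc_sets[[u]] <- map_b[anc_sets[[u]]]
    sent <- c(1L, merged$end)
    anc_sets[[v]] <- setdiff(map_a[ares$matched[, 1L]], sent)
    desc[[v]] <- c(desc[[c1]], desc[[c2]], v)
    glist[c1] <- list(NULL); glist[c2] <- list(NULL)
    glist[[v]] <- merged
  }
  root <- ntip + 1L
  g <- resolve_pending_indels(glist[[root]], NULL)
  for (dc in attr(g, "decisions") %||% list()) {
    decisions[[length(decisions) + 1L]] <- c(dc, node = root)
  }
  list(graph = g, anc_sets = anc_sets, decisions = decisions,
       scores = scores_log)
}

#' Align protein sequences
#'
#' The main entry point: reads or takes unaligned sequences, estimates a
#' BioNJ guide tree from alignment-free k-mer distances (unless a tree is
#' supplied), aligns progressively along it, and iterates guide-tree
#' estimation from maximum-likelihood (or p-) distances on the induced
#' pairwise alignments until the tree topology stabilizes or the iteration
#' limit is reached.  The aligner is deterministic: identical inputs give
#' identical outputs.
#'
#' @param records Named character vector of sequences, or a FASTA path.
#' @param options An [msa_options()].
#' @return Object of class `graphmsa_result` with elements `msa`, `tree`,
#'   `graph`, `anc_sets`, `decisions`, `iterations`, `converged`,
#'   `rf_trace`.
#' @export
align_sequences <- function(records, options = msa_options()) {
  if (is.character(records) && length(records) == 1L && file.exists(records)) {
    records <- read_fasta(records)
  }
  if (length(records) < 2L) stop("need at least two sequences")
  model <- aa_model(options$model,
                    freqs = if (options$estimate_aafreqs)
                      estimate_aafreqs(records) else NULL)
  user_tree <- !is.null(options$tree)
  tree <- if (user_tree) {
    tr <- options$tree
    if (is.character(tr)) tr <- read_newick(tr, taxa = names(records))
    as_guide_tree(tr, taxa = names(records))
  } else {
    km <- kmer_distance_matrix(records, k = options$kmer_k)
    bionj_tree(km$D, km$V)
  }
  iters <- if (user_tree || length(records) == 2L) 1L
           else max(1L, options$iters)
  converged <- FALSE
  rf_trace <- integer(0L)
  res <- NULL
  msa <- NULL
  for (it in seq_len(iters)) {
    leaves <- prepare_leaves(records, model, options, tree)
    res <- progressive_align(tree, leaves, model, options)
    msa <- extract_msa(res$graph, leaf_order = names(records))
    check_degap_identity(msa, records)
    if (it == iters) break
    dm <- induced_distances(msa, model, options)
    new_tree <- bionj_tree(dm$D, dm$V)
    rf <- robinson_foulds(tree, new_tree)$distance
    rf_trace <- c(rf_trace, rf)
    if (rf == 0) { converged <- TRUE; tree <- new_tree; break }
    tree <- new_tree
  }
  structure(list(msa = msa, tree = tree, graph = res$graph,
                 anc_sets = res$anc_sets, decisions = res$decisions,
                 records = records, model = model, options = options,
                 iterations = it, converged = converged,
                 rf_trace = rf_trace, scores = res$scores),
            class = "graphmsa_result")
}

induced_distances <- function(msa, model, options) {
  ids <- names(msa)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  V <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (options$distance == "mldist") {
        est <- suppressWarnings(ml_pairwise_distance(msa[[i]], msa[[j]], model))
        d <- est$distance; v <- est$variance
      } else {
        p <- suppressWarnings(p_distance(msa[[i]], msa[[j]]))
        d <- suppressWarnings(kimura_distance(p))
        v <- max(d, 1e-6)
      }
      D[i, j] <- D[j, i] <- d
      V[i, j] <- V[j, i] <- v
    }
  }
  list(D = D, V = V)
}

check_degap_identity <- function(msa, records) {
  for (id in names(records)) {
    if (gsub("-", "", msa[[id]]) != records[[id]]) {
      stop("degap identity violated for sequence ", id)
    }
  }
  invisible(TRUE)
}

#' @export
print.graphmsa_result <- function(x, ...) {
  cat("Graph-based progressive alignment\n")
  cat("  sequences:", length(x$msa), " columns:", nchar(x$msa[[1L]]), "\n")
  cat("  model:", x$model$name,
      if (x$options$estimate_aafreqs) "+F" else "", "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(guide tree converged)" else "", "\n")
  invisible(x)
}

#' @export
summary.graphmsa_result <- function(object, ...) {
  print(object)
  cat("  guide tree:", ape::write.tree(object$tree), "\n")
  ndec <- length(object$decisions)
  if (ndec) {
    tab <- table(vapply(object$decisions, `[[`, character(1L), "decision"))
    cat("  indel decisions:", paste(names(tab), tab, collapse = ", "), "\n")
  }
  invisible(object)
}

#' Ancestral rows of the final alignment
#'
#' For every internal guide-tree node, emits a row over the final alignment
#' columns: the most likely ancestral amino acid (equilibrium-weighted
#' maximum of the node's likelihood vector) where the column is part of the
#' node's reconstructed ancestral sequence, and a gap elsewhere.
#'
#' @param result A `graphmsa_result`.
#' @return Named character vector of internal-node rows (`node<k>` in ape
#'   numbering; `node<ntip+1>` is the root).
#' @export
ancestral_msa <- function(result) {
  g <- result$graph
  node_ids <- attr(result$msa, "node_ids")
  ntip <- length(result$tree$tip.label)
  nn <- ntip + result$tree$Nnode
  chars <- vapply(node_ids, function(nd) {
    AA[which.max(result$model$pi * g$L[, nd])]
  }, character(1L))
  out <- character(0L)
  for (v in (ntip + 1L):nn) {
    present <- node_ids %in% result$anc_sets[[v]]
    out[paste0("node", v)] <- paste(ifelse(present, chars, "-"), collapse = "")
  }
  out
}

#' Run the full pipeline with file outputs
#'
#' @param input FASTA path or named character vector of sequences.
#' @param msa_out Path for the aligned FASTA output.
#' @param tree_out Optional path for the guide tree (Newick).
#' @param ancestral_out Optional path for ancestral sequences (aligned
#'   FASTA of internal-node rows).
#' @param options An [msa_options()].
#' @return The `graphmsa_result`, invisibly.
#' @export
run_pipeline <- function(input, msa_out, tree_out = NULL,
                         ancestral_out = NULL, options = msa_options()) {
  res <- align_sequences(input, options)
  write_msa(res$msa, msa_out)
  if (!is.null(tree_out)) write_newick(res$tree, tree_out)
  if (!is.null(ancestral_out)) write_fasta(ancestral_msa(res), ancestral_out)
  invisible(res)
}
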