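# Independent oracles and small fixture builders used across the suite.

# Random amino-acid sequences (uses the session RNG; callers set seeds).
random_records <- function(n, len_range = c(5L, 30L), prefix = "s") {
  lens <- len_range[1L] - 1L +
    sample.int(len_range[2L] - len_range[1L] + 1L, n, replace = TRUE)
  out <- vapply(lens, function(l) {
    paste(sample(graphmsa:::AA, l, replace = TRUE), collapse = "")
  }, character(1L))
  setNames(out, paste0(prefix, seq_len(n)))
}

# Brute-force affine-gap alignment score by exhaustive enumeration of every
# global alignment (move sequences), entirely independent of the DP.
# Scoring: each match column costs match_init + S[i, j]; each gap run costs
# gap_init + (len - 1) * gap_ext regardless of which sequence it is in.
oracle_affine_score <- function(S, match_init, gap_init, gap_ext) {
  na <- nrow(S); nb <- ncol(S)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == na && j == nb) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i < na && j < nb) {
      rec(i + 1L, j + 1L, "M", acc + match_init + S[i + 1L, j + 1L])
    }
    if (j < nb) {
      rec(i, j + 1L, "X", acc + if (identical(last, "X")) gap_ext else gap_init)
    }
    if (i < na) {
      rec(i + 1L, j, "Y", acc + if (identical(last, "Y")) gap_ext else gap_init)
    }
  }
  rec(0L, 0L, "", 0)
  best
}

# Brute-force column likelihood on a small rooted binary tree by summing
# over every assignment of ancestral states (no pruning).  The tree is a
# nested list: leaf = list(res = "A"); internal = list(left =, right =,
# dl =, dr =).
oracle_tree_likelihood <- function(tree, model) {
  nodes <- list(); edges <- list()
  walk <- function(nd) {    # returns node index
    k <- length(nodes) + 1L
    nodes[[k]] <<- if (!is.null(nd$res)) nd$res else NA_character_
    if (is.null(nd$res)) {
      kl <- walk(nd$left)
      edges[[length(edges) + 1L]] <<- list(par = k, ch = kl, d = nd$dl)
      kr <- walk(nd$right)
      edges[[length(edges) + 1L]] <<- list(par = k, ch = kr, d = nd$dr)
    }
    k
  }
  walk(tree)
  internal <- which(is.na(unlist(nodes)))
  P <- lapply(edges, function(e) transition_matrix(model, e$d))
  states <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  total <- 0
  for (r in seq_len(nrow(states))) {
    st <- integer(length(nodes))
    st[internal] <- states[r, ]
    for (k in seq_along(nodes)) {
      if (!is.na(nodes[[k]])) st[k] <- graphmsa:::AA_INDEX[[nodes[[k]]]]
    }
    pr <- model$pi[st[1L]]
    for (ei in seq_along(edges)) {
      e <- edges[[ei]]
      pr <- pr * P[[ei]][st[e$par], st[e$ch]]
    }
    total <- total + pr
  }
  unname(total)
}

# Pruning likelihood of the same nested-list tree through the package's
# combine/column operations.
package_tree_likelihood <- function(tree, model) {
  lik <- function(nd) {
    if (!is.null(nd$res)) return(leaf_likelihood(nd$res, model))
    combine_likelihoods(lik(nd$left), lik(nd$right), nd$dl, nd$dr, model)
  }
  column_likelihood(lik(tree), model$pi)
}

random_small_tree <- function(n_leaves, residues = NULL) {
  stopifnot(n_leaves >= 2L, n_leaves <= 4L)
  residues <- residues %||% sample(graphmsa:::AA, n_leaves, replace = TRUE)
  leaves <- lapply(residues, function(r) list(res = r))
  while (length(leaves) > 1L) {
    i <- sample.int(length(leaves), 2L)
    nd <- list(left = leaves[[i[1L]]], right = leaves[[i[2L]]],
               dl = runif(1L, 0.01, 1.5), dr = runif(1L, 0.01, 1.5))
    leaves <- c(leaves[-i], list(nd))
  }
  leaves[[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random additive distance matrix from a random tree with strictly positive
# branch lengths; returns the tree and its cophenetic matrix.
additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.15, 0.8))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# simulate an aligned residue pair at distance d under a model
simulate_pair <- function(n_sites, d, model) {
  P <- transition_matrix(model, d)
  x <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
  y <- vapply(x, function(a) sample.int(20L, 1L, prob = P[a, ]), integer(1L))
  list(a = paste(graphmsa:::AA[x], collapse = ""),
       b = paste(graphmsa:::AA[y], collapse = ""))
}
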