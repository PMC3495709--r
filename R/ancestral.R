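#' Probabilistic ancestral sequences
#'
#' A likelihood vector stores, for one alignment column, the conditional
#' likelihood of the sub-tree given each possible ancestral amino acid.
#' Vectors are kept scaled so that their maximum entry is 1, with the
#' accumulated natural-log scale tracked separately; scaling never changes
#' any likelihood ratio.
#'
#' `leaf_likelihood` returns the indicator vector of an observed residue
#' (ambiguity codes are spread per their expansion, `X` over the model's
#' equilibrium distribution).
#'
#' @param residue Single residue character.
#' @param model An [aa_model()] (used for the `X` expansion).
#' @return Numeric vector of length 20 with attribute `logscale`.
#' @export
leaf_likelihood <- function(residue, model = NULL) {
  if (length(residue) != 1L || is.na(residue)) stop("unknown residue code")
  v <- numeric(20L)
  i <- unname(AA_INDEX[residue])
  if (!is.na(i)) {
    v[i] <- 1
  } else if (residue == "X") {
    v <- if (is.null(model)) rep(1, 20L) else model$pi / max(model$pi)
  } else if (!is.null(AMBIGUITY[[residue]])) {
    v[AA_INDEX[names(AMBIGUITY[[residue]])]] <- AMBIGUITY[[residue]]
    v <- v / max(v)
  } else {
    stop("unknown residue code: ", residue)
  }
  attr(v, "logscale") <- 0
  v
}

rescale_lik <- function(v, logscale = 0) {
  m <- max(v)
  if (m <= 0) stop("all-zero likelihood vector")
  out <- v / m
  attr(out, "logscale") <- logscale + log(m)
  out
}

#' Combine child likelihood vectors by the pruning recursion
#'
#' Computes `L(x) = [sum_y P_dl(y|x) L_left(y)] * [sum_y P_dr(y|x) L_right(y)]`
#' and rescales, accumulating the log-scale of both children.
#'
#' @param l_left,l_right Child likelihood vectors (length 20).
#' @param d_left,d_right Child branch lengths, `>= 0`.
#' @param model An [aa_model()].
#' @return A rescaled likelihood vector with attribute `logscale`.
#' @export
combine_likelihoods <- function(l_left, l_right, d_left, d_right, model) {
  stopifnot(d_left >= 0, d_right >= 0)
  pl <- transition_matrix(model, d_left)
  pr <- transition_matrix(model, d_right)
  v <- as.numeric(pl %*% l_left) * as.numeric(pr %*% l_right)
  rescale_lik(v, (attr(l_left, "logscale") %||% 0) + (attr(l_right, "logscale") %||% 0))
}

#' Total likelihood of a column
#'
#' `sum_x pi_x L(x)`, with the accumulated scale applied.
#'
#' @param l Likelihood vector.
#' @param pi Equilibrium frequencies.
#' @param log Return the natural log instead of the raw likelihood.
#' @return Scalar likelihood (or its log).
#' @export
column_likelihood <- function(l, pi, log = FALSE) {
  ll <- base::log(sum(pi * l)) + (attr(l, "logscale") %||% 0)
  if (log) ll else exp(ll)
}

#' Match scores between the nodes of two sequence graphs
#'
#' For every pair of non-sentinel nodes `(i, j)` the score is the log-odds of
#' common ancestry against independence:
#' `S(i,j) = log L_joint(i,j) - log L(i) - log L(j)`, where `L_joint` applies
#' the pruning recursion to the two nodes' likelihood vectors at the given
#' branch distances and sums over the root state under `pi`, and `L(i)`,
#' `L(j)` are the nodes' own `pi`-summed likelihoods.  Because the score is a
#' ratio, the per-node scale factors cancel exactly.
#'
#' @param la,lb 20 x n matrices of node likelihood vectors (columns indexed
#'   by node id; sentinel columns are ignored).
#' @param d_left,d_right Branch lengths from the new ancestor to graph A and
#'   graph B.
#' @param model An [aa_model()].
#' @return An `nA x nB` matrix of natural-log scores.
#' @export
match_scores <- function(la, lb, d_left, d_right, model) {
  pl <- transition_matrix(model, d_left)
  pr <- transition_matrix(model, d_right)
  ea <- pl %*% la                       # 20 x nA: evolved child vectors
  eb <- pr %*% lb
  joint <- crossprod(ea * model$pi, eb) # nA x nB: sum_x pi_x ea[x,i] eb[x,j]
  li <- as.numeric(model$pi %*% la)
  lj <- as.numeric(model$pi %*% lb)
  log(pmax(joint, .Machine$double.xmin)) - outer(log(li), log(lj), "+")
}
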