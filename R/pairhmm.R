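#' Pair-HMM parameters
#'
#' The alignment pair-HMM has a match state M emitting aligned node pairs,
#' gap states X and Y with affine penalties, a silent transient state H, and
#' terminal transitions.  `delta` is the base gap-opening probability (at
#' the calibration distance d = 1), `epsilon` the gap-extension probability,
#' `omega` the probability of changing to the terminal state, and `alpha`
#' the terminal-gap probability (set to `-1` to disable the terminal-gap
#' distinction).  `g` controls the distance dependence of the gap-opening
#' probability.
#'
#' @param delta,epsilon,omega,alpha,g See description.
#' @return An object of class `pairhmm_params`.
#' @export
pairhmm_params <- function(delta = 0.03, epsilon = 0.6, omega = 0.005,
                           alpha = 0.1, g = 1) {
  stopifnot(delta >= 0, delta < 1, epsilon >= 0, epsilon < 1,
            omega >= 0, omega < 1, 2 * delta + omega < 1, g > 0)
  if (alpha >= 0) stopifnot(alpha < 1)
  structure(list(delta = delta, epsilon = epsilon, omega = omega,
                 alpha = alpha, g = g),
            class = "pairhmm_params")
}

SCORE_FLOOR <- log(1e-6)

#' Distance-dependent pair-HMM transition scores
#'
#' The gap-opening probability grows with the combined evolutionary distance
#' `d` separating the aligned graphs,
#' `delta(d) = delta * (1 - exp(-g d)) / (1 - exp(-g))` (so `delta(1) =
#' delta`), capped at 0.45.  Scores are natural logs:
#' `match_init = log(1 - 2 delta(d) - omega)`, `gap_init = log(delta(d))`
#' (floored at `log(1e-6)`), `gap_ext = log(epsilon)`.
#'
#' @param params A [pairhmm_params()].
#' @param d Combined branch distance, `>= 0`.
#' @return List with `match_init`, `gap_init`, `gap_ext`, `log_omega`,
#'   `log_alpha` (`NULL` when terminal gaps are disabled) and `delta_d`.
#' @export
transition_scores <- function(params, d) {
  stopifnot(d >= 0)
  dd <- params$delta * (1 - exp(-params$g * d)) / (1 - exp(-params$g))
  if (dd > 0.45) {
    if (!isTRUE(get0("delta_cap_warned", envir = pkg_cache))) {
      warning("distance-dependent gap opening capped at 0.45")
      assign("delta_cap_warned", TRUE, envir = pkg_cache)
    }
    dd <- 0.45
  }
  list(match_init = log(1 - 2 * dd - params$omega),
       gap_init = max(log(dd), SCORE_FLOOR),
       gap_ext = log(params$epsilon),
       log_omega = log(params$omega),
       log_alpha = if (params$alpha >= 0) max(log(params$alpha), SCORE_FLOOR) else NULL,
       delta_d = dd)
}

#' Align two sequence graphs by Viterbi dynamic programming
#'
#' Implements the four-layer recursion over node pairs in
#' topological-order product: the match layer maximizes over all pairs of
#' predecessors, the two gap layers over one graph's predecessors, and the
#' silent layer is the running maximum.  Edge reuse penalties enter every
#' transition along their edge; terminal gap runs (opened from the start
#' pair or held at a predecessor of the end sentinel) open with the
#' terminal-gap score when enabled.  Backtracking selects one homologous
#' path per graph plus the matched node pairs, with deterministic
#' tie-breaking (M over X over Y, then smallest predecessor pair in
#' topological order).
#'
#' @param ga,gb `seq_graph`s.
#' @param S Match score matrix over node pairs (natural log), as from
#'   [match_scores()], indexed by node ids.
#' @param scores Transition scores from [transition_scores()].
#' @param pen_a,pen_b Per-edge penalty vectors (defaults to zero).
#' @param force_align_m_bonus Bonus (nats) added to the match score of the
#'   two graphs' initial all-methionine nodes, or 0 to disable.
#' @return List with `score`, `matched` (2-column matrix of node ids),
#'   `path_a`, `path_b` (homologous paths including sentinels), `edges_a`,
#'   `edges_b` (traversed edge rows) and `steps` (the move list from start
#'   to end).
#' @export
align_graphs <- function(ga, gb, S, scores, pen_a = NULL, pen_b = NULL,
                         force_align_m_bonus = 0) {
  topo_a <- topological_order(ga)
  topo_b <- topological_order(gb)
  pa <- pred_structure(ga, topo_a)
  pb <- pred_structure(gb, topo_b)
  pen_a <- pen_a %||% numeric(nrow(ga$edges))
  pen_b <- pen_b %||% numeric(nrow(gb$edges))
  if (force_align_m_bonus > 0) {
    fa <- initial_met_nodes(ga)
    fb <- initial_met_nodes(gb)
    if (length(fa) && length(fb)) {
      S[fa, fb] <- S[fa, fb] + force_align_m_bonus
    }
  }
  # S in topological-position space
  St <- S[topo_a, topo_b, drop = FALSE]
  pre_end_a <- logical(ga$n)
  pre_end_a[pa$pos[ga$edges$from[ga$edges$to == ga$end]]] <- TRUE
  pre_end_b <- logical(gb$n)
  pre_end_b[pb$pos[gb$edges$from[gb$edges$to == gb$end]]] <- TRUE

  res <- align_graphs_cpp(
    ga$n, gb$n, pa$ptr, pa$pred - 1L, pen_a[pa$edge], pb$ptr, pb$pred - 1L,
    pen_b[pb$edge], St, scores$match_init, scores$gap_init, scores$gap_ext,
    scores$log_omega, scores$log_alpha %||% scores$gap_init, pre_end_a,
    pre_end_b)

  a_ids <- rep(NA_integer_, length(res$ai))
  a_ids[res$ai >= 0L] <- topo_a[res$ai[res$ai >= 0L] + 1L]
  b_ids <- rep(NA_integer_, length(res$bi))
  b_ids[res$bi >= 0L] <- topo_b[res$bi[res$bi >= 0L] + 1L]
  steps <- data.frame(type = res$type, a = a_ids, b = b_ids)
  # map flat predecessor-slot indices back to edge rows
  edges_a <- pa$edge[res$ea[res$ea > 0L]]
  edges_b <- pb$edge[res$eb[res$eb > 0L]]
  matched <- cbind(steps$a[steps$type == 1L], steps$b[steps$type == 1L])
  list(score = res$score,
       matched = matched,
       path_a = steps$a[steps$type %in% c(0L, 1L, 3L, 4L)],
       path_b = steps$b[steps$type %in% c(0L, 1L, 2L, 4L)],
       edges_a = edges_a, edges_b = edges_b,
       steps = steps)
}

# character nodes directly after the start sentinel whose residues are all M
initial_met_nodes <- function(g) {
  first <- g$edges$to[g$edges$from == g$start & g$edges$to != g$end]
  first[vapply(first, function(i) all(g$columns[[i]] == "M"), logical(1L))]
}
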