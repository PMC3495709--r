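#' Simulation parameters
#'
#' Defaults reproduce the reference simulation conditions: 10 taxa, WAG with
#' discrete-gamma rate variation among sites (4 categories), gamma
#' distributed root sequence lengths with mean 300 amino acids, a maximum
#' pairwise distance of 2 expected substitutions per site, and insertions
#' and deletions each at a rate of 0.005 per expected substitution with
#' Zipfian lengths of mean 3.5 truncated at 50.
#'
#' @param n_taxa Number of leaves (ignored when `tree` is given).
#' @param tree Optional guide tree (`phylo`); otherwise a random topology is
#'   drawn and scaled to `max_pairwise`.
#' @param max_pairwise Maximum pairwise leaf distance (expected
#'   substitutions/site) used to scale the random tree.
#' @param root_length_mean,root_length_shape Gamma law of the root sequence
#'   length (scale set so the mean is `root_length_mean`).
#' @param gamma_shape,n_rate_categories Discrete-gamma rate variation among
#'   sites.
#' @param indel_rate Per-expected-substitution rate of insertions (and,
#'   separately, deletions).
#' @param indel_length_mean,indel_length_max Truncated Zipf law of indel
#'   lengths; the exponent is solved numerically so the truncated mean
#'   matches.
#' @param model Substitution model name.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_taxa = 10L, tree = NULL, max_pairwise = 2,
                       root_length_mean = 300, root_length_shape = 2,
                       gamma_shape = 1, n_rate_categories = 4L,
                       indel_rate = 0.005, indel_length_mean = 3.5,
                       indel_length_max = 50L, model = "WAG") {
  stopifnot(indel_rate >= 0, indel_length_mean > 1,
            indel_length_mean < (1 + indel_length_max) / 2)
  structure(as.list(environment()), class = "sim_params")
}

#' Truncated Zipf indel-length distribution
#'
#' `P(L = k) ∝ k^(-s)` for `k = 1..max`, with the exponent `s` solved by
#' bisection so that the truncated mean equals `mean`.
#'
#' @param mean Target mean length.
#' @param max Truncation point.
#' @return Probability vector over lengths `1..max`.
#' @export
zipf_length_probs <- function(mean = 3.5, max = 50L) {
  k <- seq_len(max)
  mean_of <- function(s) { w <- k^(-s); sum(w * k) / sum(w) }
  s <- uniroot(function(s) mean_of(s) - mean, c(1e-6, 20), tol = 1e-12)$root
  w <- k^(-s)
  w / sum(w)
}

#' @param n Number of draws.
#' @param probs Length distribution from [zipf_length_probs()].
#' @rdname zipf_length_probs
#' @export
rindel_length <- function(n, probs = zipf_length_probs()) {
  sample.int(length(probs), n, replace = TRUE, prob = probs)
}

#' Root sequence length draws
#'
#' Gamma with the given shape and scale chosen for the target mean, rounded
#' to the nearest positive integer.
#'
#' @param n Number of draws.
#' @param mean,shape Gamma parameters.
#' @export
rroot_length <- function(n, mean = 300, shape = 2) {
  pmax(1L, as.integer(round(rgamma(n, shape = shape, scale = mean / shape))))
}

# Mean rates of the equal-probability discrete-gamma categories
discrete_gamma_rates <- function(shape, ncat) {
  q <- qgamma(seq_len(ncat - 1L) / ncat, shape = shape, rate = shape)
  p1 <- pgamma(c(q, Inf), shape = shape + 1, rate = shape)
  p0 <- pgamma(c(0, q), shape = shape + 1, rate = shape)
  ncat * (p1 - p0)
}

# Exact Gillespie simulation of substitutions and indels along one branch.
# state: list(ids, aa (integer codes), rate (per-site category rates)).
# Substitution jumps occur at rate rate_i * (-Q[a_i, a_i]); insertions and
# deletions each at indel_rate * sum(rate_i), the expected-substitution rate
# scale.  Returns the evolved state, the event list, and the integrated
# expected substitution count.
sim_branch_gillespie <- function(state, d, model, cat_rates, zipf_probs,
                                 indel_rate, env, branch,
                                 target_subs = Inf) {
  qdiag <- -diag(model$Q)
  jump_rows <- lapply(1:20, function(a) {
    r <- model$Q[a, ]; r[a] <- 0; r / sum(r)
  })
  ids <- state$ids; aa <- state$aa; rate <- state$rate
  events <- list()
  t <- 0; exp_subs <- 0
  qd <- qdiag[aa] * rate
  sjump <- sum(qd); sr <- sum(rate)
  maxlen <- length(zipf_probs)
  repeat {
    rtot <- sjump + 2 * indel_rate * sr
    if (rtot <= 0) { break }
    dt <- rexp(1L, rtot)
    if (t + dt > d) { exp_subs <- exp_subs + sr * (d - t); break }
    if (exp_subs + sr * dt > target_subs) { exp_subs <- target_subs; break }
    t <- t + dt
    exp_subs <- exp_subs + sr * dt
    u <- runif(1L) * rtot
    L <- length(ids)
    if (u < sjump) {
      i <- sample.int(L, 1L, prob = qd)
      old <- aa[i]
      aa[i] <- sample.int(20L, 1L, prob = jump_rows[[old]])
      sjump <- sjump - qd[i]
      qd[i] <- qdiag[aa[i]] * rate[i]
      sjump <- sjump + qd[i]
      events[[length(events) + 1L]] <-
        list(type = "sub", branch = branch, site = ids[i], to = aa[i])
    } else if (u < sjump + indel_rate * sr) {
      len <- sample.int(maxlen, 1L, prob = zipf_probs)
      pos <- sample.int(L + 1L, 1L) - 1L       # insert after position pos
      new_ids <- env$next_id + seq_len(len) - 1L
      env$next_id <- env$next_id + len
      new_aa <- sample.int(20L, len, replace = TRUE, prob = model$pi)
      new_rate <- sample(cat_rates, len, replace = TRUE)
      # global column registry: place right of the left neighbour
      reg_at <- if (pos == 0L) {
        if (L == 0L) length(env$registry) else match(ids[1L], env$registry) - 1L
      } else match(ids[pos], env$registry)
      env$registry <- append(env$registry, new_ids, after = reg_at)
      ids <- append(ids, new_ids, after = pos)
      aa <- append(aa, new_aa, after = pos)
      rate <- append(rate, new_rate, after = pos)
      qd <- append(qd, qdiag[new_aa] * new_rate, after = pos)
      sjump <- sum(qd); sr <- sum(rate)
      events[[length(events) + 1L]] <-
        list(type = "ins", branch = branch, after = if (pos == 0L) 0L else ids[pos],
             ids = new_ids, aa = new_aa, rates = new_rate, length = len)
    } else {
      if (L == 0L) next
      len <- sample.int(maxlen, 1L, prob = zipf_probs)
      start <- sample.int(L, 1L)
      span <- start:min(L, start + len - 1L)
      events[[length(events) + 1L]] <-
        list(type = "del", branch = branch, ids = ids[span],
             length = length(span))
      ids <- ids[-span]; aa <- aa[-span]; rate <- rate[-span]
      qd <- qdiag[aa] * rate
      sjump <- sum(qd); sr <- sum(rate)
    }
  }
  list(state = list(ids = ids, aa = aa, rate = rate),
       events = events, expected_subs = exp_subs)
}

#' Simulate one branch of sequence evolution
#'
#' Evolves a stationary sequence of the requested length along a single
#' branch under the full substitution + indel model; used for calibration
#' checks of the event rates.
#'
#' @param params A [sim_params()].
#' @param d Branch length (expected substitutions per site at rate 1); may
#'   be `Inf` when `target_subs` is given.
#' @param length0 Initial sequence length.
#' @param target_subs Optional stopping rule: evolve until the integrated
#'   expected substitution count reaches this value.
#' @return List with the evolved `state`, the `events` ledger, the
#'   integrated `expected_subs`, and the insertion/deletion event counts.
#' @export
simulate_branch <- function(params = sim_params(), d, length0 = 300L,
                            target_subs = Inf) {
  model <- aa_model(params$model)
  cat_rates <- discrete_gamma_rates(params$gamma_shape, params$n_rate_categories)
  zp <- zipf_length_probs(params$indel_length_mean, params$indel_length_max)
  env <- new.env()
  env$next_id <- length0 + 1L
  env$registry <- seq_len(length0)
  state <- list(ids = seq_len(length0),
                aa = sample.int(20L, length0, replace = TRUE, prob = model$pi),
                rate = sample(cat_rates, length0, replace = TRUE))
  out <- sim_branch_gillespie(state, d, model, cat_rates, zp,
                              params$indel_rate, env, branch = 1L,
                              target_subs = target_subs)
  types <- vapply(out$events, `[[`, character(1L), "type")
  out$n_insertions <- sum(types == "ins")
  out$n_deletions <- sum(types == "del")
  out
}

#' Simulate a protein family along a tree
#'
#' Evolves a root sequence along a (random or supplied) guide tree under
#' WAG with discrete-gamma rate variation and the Zipf indel process,
#' tracking the true alignment: every residue ever created receives a
#' unique site id placed in a global column registry, so the true MSA
#' columns record all homologies including inserted residues.  The event
#' ledger records every substitution, insertion, and deletion per branch;
#' replaying the ledger from the root sequence reproduces the leaves
#' exactly.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed; the simulation is deterministic per seed.
#' @return Object of class `sim_result`: `tree`, leaf `records`, true `msa`
#'   (leaf rows), `anc_msa` (internal-node rows over the same columns),
#'   `events`, per-branch `expected_subs`, `root_state`, `node_states`,
#'   `columns` (site ids of the true MSA columns).
#' @export
simulate_msa <- function(params = sim_params(), seed = 1L) {
  with_local_seed(seed, simulate_msa_impl(params))
}

simulate_msa_impl <- function(params) {
  model <- aa_model(params$model)
  cat_rates <- discrete_gamma_rates(params$gamma_shape, params$n_rate_categories)
  zp <- zipf_length_probs(params$indel_length_mean, params$indel_length_max)
  tree <- params$tree
  if (is.null(tree)) {
    tree <- ape::rtree(params$n_taxa)
    coph <- max(ape::cophenetic.phylo(tree))
    tree$edge.length <- tree$edge.length * params$max_pairwise / coph
  }
  tree <- as_guide_tree(tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  L0 <- rroot_length(1L, params$root_length_mean, params$root_length_shape)
  env <- new.env()
  env$next_id <- L0 + 1L
  env$registry <- seq_len(L0)
  root_state <- list(ids = seq_len(L0),
                     aa = sample.int(20L, L0, replace = TRUE, prob = model$pi),
                     rate = sample(cat_rates, L0, replace = TRUE))
  node_states <- vector("list", nn)
  node_states[[ntip + 1L]] <- root_state
  events <- list()
  expected_subs <- numeric(nn)
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    par <- pre$edge[k, 1L]; ch <- pre$edge[k, 2L]
    out <- sim_branch_gillespie(node_states[[par]], pre$edge.length[k], model,
                                cat_rates, zp, params$indel_rate, env,
                                branch = ch)
    node_states[[ch]] <- out$state
    events <- c(events, out$events)
    expected_subs[ch] <- out$expected_subs
  }
  leaf_ids <- lapply(seq_len(ntip), function(i) node_states[[i]]$ids)
  present <- env$registry[env$registry %in% unlist(leaf_ids)]
  col_of <- setNames(seq_along(present), present)
  row_of <- function(st) {
    r <- rep("-", length(present))
    keep <- st$ids %in% present
    r[col_of[as.character(st$ids[keep])]] <- AA[st$aa[keep]]
    paste(r, collapse = "")
  }
  msa <- setNames(vapply(seq_len(ntip), function(i) row_of(node_states[[i]]),
                         character(1L)), tree$tip.label)
  anc <- setNames(vapply((ntip + 1L):nn, function(i) row_of(node_states[[i]]),
                         character(1L)), paste0("node", (ntip + 1L):nn))
  records <- setNames(gsub("-", "", msa), names(msa))
  structure(list(tree = tree, params = params, records = records, msa = msa,
                 anc_msa = anc, events = events,
                 expected_subs = expected_subs, root_state = root_state,
                 node_states = node_states, columns = present),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  types <- vapply(x$events, `[[`, character(1L), "type")
  cat("Simulated protein family:", length(x$records), "taxa,",
      length(x$columns), "true columns\n")
  cat("  events:", sum(types == "sub"), "substitutions,",
      sum(types == "ins"), "insertions,", sum(types == "del"), "deletions\n")
  invisible(x)
}

#' Replay a simulation's event ledger
#'
#' Applies the recorded events branch by branch starting from the root
#' sequence; used to verify ledger consistency (the replayed leaves must
#' equal the simulated leaves exactly).
#'
#' @param sim A `sim_result`.
#' @return Named character vector of replayed leaf sequences.
#' @export
replay_events <- function(sim) {
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- vector("list", nn)
  states[[ntip + 1L]] <- sim$root_state[c("ids", "aa")]
  by_branch <- split(sim$events,
                     vapply(sim$events, `[[`, integer(1L), "branch"))
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    par <- pre$edge[k, 1L]; ch <- pre$edge[k, 2L]
    st <- states[[par]]
    for (ev in by_branch[[as.character(ch)]] %||% list()) {
      if (ev$type == "sub") {
        st$aa[match(ev$site, st$ids)] <- ev$to
      } else if (ev$type == "ins") {
        pos <- if (ev$after == 0L) 0L else match(ev$after, st$ids)
        st$ids <- append(st$ids, ev$ids, after = pos)
        st$aa <- append(st$aa, ev$aa, after = pos)
      } else {
        drop <- match(ev$ids, st$ids)
        st$ids <- st$ids[-drop]; st$aa <- st$aa[-drop]
      }
    }
    states[[ch]] <- st
  }
  setNames(vapply(seq_len(ntip),
                  function(i) paste(AA[states[[i]]$aa], collapse = ""),
                  character(1L)), tree$tip.label)
}
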