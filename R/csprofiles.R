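#' Posterior profile weights for one sequence window
#'
#' Matches the window centred at position `i` against every profile in the
#' library: `P(p_k | X_i) ∝ P(p_k) * prod_j p_k(j, x_{i+j})^{w_j}` with
#' window weights `w_j = 1.3 * 0.9^|j|`.  Window positions outside the
#' sequence are skipped (they contribute a factor of 1).  Computed in log
#' space and normalized over profiles.
#'
#' @param sequence Residue string.
#' @param i Position within the sequence.
#' @param library A [context_profile_library()].
#' @return Numeric vector of K posterior weights summing to 1.
#' @export
match_profiles <- function(sequence, i, library) {
  chars <- strsplit(sequence, "")[[1L]]
  match_profiles_chars(chars, i, library)
}

match_profiles_chars <- function(chars, i, library) {
  n <- length(chars)
  stopifnot(i >= 1L, i <= n)
  h <- (library$width - 1L) %/% 2L
  offs <- -h:h
  pos <- i + offs
  ok <- pos >= 1L & pos <= n
  logp <- log(library$priors)
  w <- 1.3 * 0.9^abs(offs)
  for (jj in which(ok)) {
    a <- AA_INDEX[chars[pos[jj]]]
    if (is.na(a)) next  # ambiguity codes contribute factor 1
    col <- offs[jj] + h + 1L
    pk <- vapply(library$profiles, function(p) p[a, col], numeric(1L))
    logp <- logp + w[jj] * log(pmax(pk, 1e-300))
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p / sum(p)
}

#' Context-specific profile of a sequence
#'
#' Applies the library posterior at every position and averages the profiles'
#' centre columns: `P(y | X_i) ∝ sum_k p_k(0, y) P(p_k | X_i)`.
#'
#' @param sequence Residue string.
#' @param library A [context_profile_library()].
#' @return An object of class `site_profile`: a `20 x n` matrix whose columns
#'   are per-position substitution distributions, with the input residues as
#'   attribute `residues`.
#' @export
context_profile <- function(sequence, library) {
  chars <- strsplit(sequence, "")[[1L]]
  h <- (library$width - 1L) %/% 2L
  centers <- vapply(library$profiles, function(p) p[, h + 1L], numeric(20L)) # 20 x K
  out <- matrix(0, 20L, length(chars), dimnames = list(AA, NULL))
  for (i in seq_along(chars)) {
    post <- match_profiles_chars(chars, i, library)
    v <- as.numeric(centers %*% post)
    out[, i] <- v / sum(v)
  }
  structure(out, residues = chars, class = "site_profile")
}

#' Expected conservation of a profile library
#'
#' The expected probability that the centre residue is predicted unchanged
#' when the library is matched with a window of width one, averaged over
#' equilibrium frequencies: the window posterior
#' `P(p_k | c) ∝ P(p_k) p_k(0, c)^w0` is combined with the centre-column
#' mixture `P(y | c) ∝ sum_k p_k(0, y) P(p_k | c)` and the conservation is
#' `sum_c pi_c P(c | c)`.  A single fully conserved (delta) profile gives
#' `1/20` under uniform frequencies, as does a library of uniform profiles.
#'
#' @param library A [context_profile_library()].
#' @param pi Equilibrium amino-acid frequencies.
#' @return Scalar expected conservation.
#' @export
library_conservation <- function(library, pi) {
  h <- (library$width - 1L) %/% 2L
  centers <- vapply(library$profiles, function(p) p[, h + 1L], numeric(20L)) # 20 x K
  w0 <- 1.3
  cons <- 0
  for (ci in 1:20) {
    post <- library$priors * centers[ci, ]^w0
    if (sum(post) == 0) post <- library$priors else post <- post / sum(post)
    pyc <- as.numeric(centers %*% post)
    pyc <- pyc / sum(pyc)
    cons <- cons + pi[ci] * pyc[ci]
  }
  unname(cons)
}

#' Adjust a context-specific profile for terminal branch length
#'
#' Interpolates each position between full conservation and the library's
#' average divergence: `P'(y|X_i) = (1 - tau) * 1[x_i = y] + tau * P(y|X_i)`
#' with `tau = min(1, delta / (1 - conservation))` and `delta` the expected
#' divergence at branch length `d` (inverse Kimura transform).
#'
#' @param profile A `site_profile`.
#' @param d Terminal branch length, `>= 0`.
#' @param conservation Library conservation (see [library_conservation()]).
#' @return The adjusted `site_profile`.
#' @export
adjust_tau <- function(profile, d, conservation = 0.2) {
  stopifnot(d >= 0)
  delta <- expected_divergence(d)
  tau <- min(1, delta / (1 - conservation))
  chars <- attr(profile, "residues")
  out <- tau * unclass(profile)
  idx <- AA_INDEX[chars]
  for (i in seq_along(chars)) {
    if (!is.na(idx[i])) {
      out[idx[i], i] <- out[idx[i], i] + (1 - tau)
    } else {
      # ambiguity: spread the conserved mass over the code's expansion
      v <- leaf_likelihood(chars[i])
      out[, i] <- out[, i] + (1 - tau) * v / sum(v)
    }
  }
  structure(out, residues = chars, tau = tau, class = "site_profile")
}

#' Convert a site profile to probabilistic-leaf likelihood vectors
#'
#' By Bayes' theorem the leaf's conditional likelihood of ancestral state `y`
#' is proportional to `P(y|X_i) / pi_y` (the observed residue's equilibrium
#' factor is constant per column and absorbed by the scaling).  Vectors are
#' scaled so the maximum entry is 1.
#'
#' @param profile A `site_profile`.
#' @param pi Equilibrium frequencies.
#' @return A `20 x n` matrix of likelihood vectors (max entry 1 per column).
#' @export
to_probabilistic_leaf <- function(profile, pi) {
  m <- unclass(profile) / pi
  attr(m, "residues") <- NULL
  sweep(m, 2L, apply(m, 2L, max), "/")
}
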