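#' Amino-acid substitution models
#'
#' Builds a reversible 20-state substitution model: a rate generator `Q`
#' scaled to one expected substitution per unit distance, its equilibrium
#' frequencies `pi`, and a cached spectral decomposition used for fast
#' transition matrices.
#'
#' `WAG` uses the published WAG exchangeabilities and frequencies (as carried
#' by phangorn).  `GONNET` is constructed from the published Gonnet (1992)
#' log-odds matrix bundled with the package: the implied equilibrium
#' frequencies are solved from the odds matrix, the PAM250-scale conditional
#' matrix is formed, its matrix logarithm taken, off-diagonal negatives
#' clamped, and the result symmetrized and rescaled.
#'
#' @param name `"WAG"` or `"GONNET"`.
#' @param freqs Optional replacement equilibrium frequencies (the `+F`
#'   option); the generator is rebuilt from the model's exchangeabilities
#'   with these frequencies and rescaled.
#' @return An object of class `aa_model` with elements `name`, `S`
#'   (symmetric exchangeabilities), `pi`, `Q`, and the spectral cache.
#' @export
aa_model <- function(name = c("WAG", "GONNET"), freqs = NULL) {
  name <- match.arg(name)
  base <- if (name == "WAG") wag_components() else gonnet_components()
  pi <- if (is.null(freqs)) base$pi else {
    stopifnot(length(freqs) == 20L)
    freqs / sum(freqs)
  }
  build_model(name, base$S, pi)
}

build_model <- function(name, S, pi) {
  names(pi) <- AA
  dimnames(S) <- list(AA, AA)
  Q <- S * rep(pi, each = 20L)     # Q[x,y] = S[x,y] * pi[y]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # symmetric similarity transform: B = D Q D^-1 with D = diag(sqrt(pi))
  d2 <- sqrt(pi)
  B <- Q * (d2 %o% (1 / d2))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(name = name, S = S, pi = pi, Q = Q,
                 eig = list(vectors = e$vectors, values = e$values,
                            d2 = d2)),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name, "\n")
  cat("  scaled to 1 expected substitution per unit distance\n")
  invisible(x)
}

wag_components <- function() {
  wag <- get(".WAG", envir = asNamespace("phangorn"))
  S <- matrix(0, 20L, 20L)
  S[lower.tri(S)] <- wag$Q
  S <- S + t(S)
  pi <- as.numeric(wag$bf)
  list(S = S, pi = pi)
}

gonnet_components <- function() {
  cached <- get0("gonnet_cache", envir = pkg_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "gonnet1992_logodds.txt", package = "graphmsa")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  alphabet <- strsplit(lines[[1L]], "\t")[[1L]]
  M <- do.call(rbind, lapply(lines[-1L], function(l) as.numeric(strsplit(l, "\t")[[1L]])))
  perm <- match(AA, alphabet)
  M <- M[perm, perm]
  A <- 10^(M / 10)                       # odds ratios P(a,b)/(pi_a pi_b)
  pi <- solve(A, rep(1, 20L))            # marginal consistency: A %*% pi = 1
  pi <- pi / sum(pi)
  P <- A * rep(pi, each = 20L)           # conditional matrix at the matrix's PAM scale
  P <- P / rowSums(P)
  # matrix logarithm through the reversible symmetrization
  d2 <- sqrt(pi)
  B <- P * (d2 %o% (1 / d2))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  if (any(e$values <= 0)) stop("GONNET conditional matrix is not embeddable")
  Qr <- (e$vectors %*% (log(e$values) * t(e$vectors))) * ((1 / d2) %o% d2)
  Qr[Qr < 0 & row(Qr) != col(Qr)] <- 0   # clamp spurious negatives
  S <- Qr / rep(pi, each = 20L)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  out <- list(S = S, pi = pi)
  assign("gonnet_cache", out, envir = pkg_cache)
  out
}

pkg_cache <- new.env(parent = emptyenv())

#' Transition probability matrix at a given distance
#'
#' `P_d = exp(d * Q)`, computed from the model's cached spectral
#' decomposition.  Rows are the ancestral state `x`, columns the derived
#' state `y`, so `P[x, y] = P_d(y | x)`.
#'
#' @param model An [aa_model()].
#' @param d Evolutionary distance (expected substitutions per site), `>= 0`.
#' @return A 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, d) {
  if (d < 0) stop("distance must be non-negative")
  if (d == 0) {
    P0 <- diag(20L)
    dimnames(P0) <- list(AA, AA)
    return(P0)
  }
  e <- model$eig
  P <- (e$vectors %*% (exp(d * e$values) * t(e$vectors))) * ((1 / e$d2) %o% e$d2)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA, AA)
  P
}

#' Estimate amino-acid frequencies from input sequences
#'
#' Counts the 20 standard residues over all sequences with one pseudocount
#' per amino acid (ambiguity codes are ignored in the counts).
#'
#' @param records Named character vector of residue strings.
#' @return Frequency vector over the 20 amino acids, summing to 1.
#' @export
estimate_aafreqs <- function(records) {
  stopifnot(length(records) >= 1L)
  chars <- unlist(strsplit(paste(records, collapse = ""), ""))
  counts <- as.numeric(table(factor(chars, levels = AA)))
  setNames((counts + 1) / (sum(counts) + 20), AA)
}

#' Kimura-style distance from observed divergence, and its inverse
#'
#' `kimura_distance` maps an observed proportion of differing sites `p` to an
#' evolutionary distance `d = -log(1 - p - 0.2 p^2)`; `expected_divergence`
#' is the exact algebraic inverse, the positive root of
#' `0.2 delta^2 + delta = 1 - exp(-d)`.
#'
#' @param p Observed divergence in `[0, 1)`.
#' @param max_distance Distance returned (with a warning) when `p` is beyond
#'   saturation.
#' @return Evolutionary distance (`kimura_distance`) or expected divergence
#'   (`expected_divergence`).
#' @export
kimura_distance <- function(p, max_distance = 2.2) {
  stopifnot(all(p >= 0), all(p < 1))
  arg <- 1 - p - 0.2 * p^2
  out <- ifelse(arg > 0, -log(pmax(arg, .Machine$double.xmin)), NA_real_)
  if (any(!is.finite(out) | is.na(out) | out > max_distance)) {
    warning("saturated divergence; returning maximum distance ", max_distance)
    out[is.na(out) | out > max_distance] <- max_distance
  }
  out
}

#' @param d Evolutionary distance, `>= 0`.
#' @rdname kimura_distance
#' @export
expected_divergence <- function(d) {
  stopifnot(all(d >= 0))
  (-1 + sqrt(1 + 0.8 * (1 - exp(-d)))) / 0.4
}

#' Maximum-likelihood distance between two aligned rows
#'
#' Maximizes the independent-sites likelihood
#' `sum log(pi_x * P_d(y|x))` over `d` in `[1e-5, 10]`.  Columns gapped (or
#' carrying a non-standard code) in either row are ignored.
#'
#' @param row_a,row_b Aligned residue strings of equal length (`-` for gaps).
#' @param model An [aa_model()].
#' @param max_distance Distance returned when no ungapped columns exist.
#' @return List with elements `distance` and `variance` (inverse curvature of
#'   the log-likelihood, floored at 1e-6).
#' @export
ml_pairwise_distance <- function(row_a, row_b, model, max_distance = 2.2) {
  counts <- pair_counts(row_a, row_b)
  if (sum(counts) == 0) {
    warning("no ungapped columns; returning maximum distance")
    return(list(distance = max_distance, variance = 100))
  }
  logpi <- log(model$pi)
  ll <- function(d) {
    P <- transition_matrix(model, d)
    sum(counts * (logpi + log(pmax(P, 1e-300))))
  }
  opt <- optimize(ll, c(1e-5, 10), maximum = TRUE, tol = 1e-8)
  d <- opt$maximum
  h <- 1e-4
  d0 <- max(d, 1e-5 + h)
  curv <- (ll(d0 + h) - 2 * ll(d0) + ll(d0 - h)) / h^2
  v <- if (is.finite(curv) && curv < 0) -1 / curv else 100
  list(distance = d, variance = max(v, 1e-6))
}

# 20x20 ancestral-by-derived counts over ungapped standard-residue columns
pair_counts <- function(row_a, row_b, chars_a = NULL, chars_b = NULL) {
  a <- chars_a %||% strsplit(row_a, "")[[1L]]
  b <- chars_b %||% strsplit(row_b, "")[[1L]]
  if (length(a) != length(b)) stop("aligned rows differ in length")
  ia <- AA_INDEX[a]
  ib <- AA_INDEX[b]
  ok <- !is.na(ia) & !is.na(ib)
  m <- matrix(0, 20L, 20L)
  if (any(ok)) {
    t <- table(factor(ia[ok], levels = 1:20), factor(ib[ok], levels = 1:20))
    m <- matrix(as.numeric(t), 20L, 20L)
  }
  m
}

#' Proportion of mismatching ungapped columns (p-distance)
#'
#' @inheritParams ml_pairwise_distance
#' @param cap Value returned (with a warning) when no ungapped columns exist.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(row_a, row_b, cap = 0.75) {
  counts <- pair_counts(row_a, row_b)
  n <- sum(counts)
  if (n == 0) {
    warning("no ungapped columns; returning capped divergence")
    return(cap)
  }
  (n - sum(diag(counts))) / n
}
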