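# Dayhoff's six amino-acid classes, used to compress sequences before
# k-mer counting so that distant homologs still share words.
DAYHOFF6 <- c(C = "1",
              S = "2", T = "2", P = "2", A = "2", G = "2",
              N = "3", D = "3", E = "3", Q = "3",
              H = "4", R = "4", K = "4",
              M = "5", I = "5", L = "5", V = "5",
              F = "6", Y = "6", W = "6",
              X = "2", B = "3", Z = "3", U = "1", O = "4")

#' Alignment-free k-mer distance matrix
#'
#' Sequences are compressed to the six Dayhoff classes and the fraction of
#' shared distinct k-mers `F = |A ∩ B| / min(|A|, |B|)` is computed for
#' every pair.  The fraction is corrected for the random background share
#' and log-transformed, `d = -log((F - F_rand) / (1 - F_rand))`, then
#' clipped to `[1e-5, max_distance]`.  Variances are taken proportional to
#' the distances (`V = d`), the simple proxy used for the initial BioNJ
#' tree.
#'
#' @param records Named character vector of sequences.
#' @param k Word length on the compressed alphabet.
#' @param max_distance Distance cap.
#' @return List with matrices `D` (distances) and `V` (variances).
#' @export
kmer_distance_matrix <- function(records, k = 6L, max_distance = 2.2) {
  n <- length(records)
  stopifnot(n >= 2L)
  ids <- names(records)
  kmers <- lapply(records, function(s) {
    cls <- DAYHOFF6[strsplit(s, "")[[1L]]]
    if (length(cls) < k) return(character(0L))
    w <- vapply(seq_len(length(cls) - k + 1L),
                function(i) paste(cls[i:(i + k - 1L)], collapse = ""),
                character(1L))
    unique(w)
  })
  short <- lengths(kmers) == 0L
  if (any(short)) warning("sequence shorter than k: ", paste(ids[short], collapse = ", "))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- max_distance
      if (!short[i] && !short[j]) {
        na <- length(kmers[[i]]); nb <- length(kmers[[j]])
        f <- length(intersect(kmers[[i]], kmers[[j]])) / min(na, nb)
        f_rand <- 1 - (1 - 6^(-k))^min(na, nb)
        if (f > f_rand) {
          d <- -log((f - f_rand) / (1 - f_rand))
        }
      }
      D[i, j] <- D[j, i] <- min(max(d, 1e-5), max_distance)
    }
  }
  list(D = D, V = D)
}

#' BioNJ tree from a distance matrix with variances
#'
#' Neighbor-joining agglomeration in which each reduction step weights the
#' two merged rows to minimize the variance of the reduced distances
#' (lambda chosen per BioNJ, clamped to `[0, 1]`), given a matrix of
#' first-order variances of the pairwise distance estimates.  The unrooted
#' result is rooted at the midpoint of its longest leaf-to-leaf path, and
#' negative estimated branch lengths are clamped to zero.
#'
#' @param D Symmetric distance matrix with row/column names.
#' @param V Variance matrix of the same shape (positive off-diagonal).
#' @return A rooted binary `phylo`.
#' @export
bionj_tree <- function(D, V = D) {
  n <- nrow(D)
  stopifnot(ncol(D) == n, all(dim(V) == dim(D)))
  ids <- rownames(D)
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g);",
                                        ids[1L], D[1L, 2L] / 2,
                                        ids[2L], D[1L, 2L] / 2))
    return(tr)
  }
  nwk <- rep(ids, length.out = n)      # growing newick fragments per cluster
  Dm <- D; Vm <- V
  act <- seq_len(n)
  while (length(act) > 3L) {
    m <- length(act)
    Da <- Dm[act, act]
    R <- rowSums(Da)
    Qc <- (m - 2) * Da - outer(R, R, "+")
    diag(Qc) <- Inf
    ij <- arrayInd(which.min(Qc), dim(Qc))
    a <- act[ij[1L]]; b <- act[ij[2L]]
    others <- setdiff(act, c(a, b))
    la <- Da[ij[1L], ij[2L]] / 2 + (R[ij[1L]] - R[ij[2L]]) / (2 * (m - 2))
    lb <- Da[ij[1L], ij[2L]] - la
    la <- max(la, 0); lb <- max(lb, 0)
    # BioNJ reduction weight
    vab <- Vm[a, b]
    lam <- if (vab > 0) {
      0.5 + sum(Vm[b, others] - Vm[a, others]) / (2 * (m - 2) * vab)
    } else 0.5
    lam <- min(max(lam, 0), 1)
    newD <- lam * Dm[a, others] + (1 - lam) * Dm[b, others] - lam * la - (1 - lam) * lb
    newV <- lam * Vm[a, others] + (1 - lam) * Vm[b, others] - lam * (1 - lam) * vab
    u <- a                              # reuse slot a for the new cluster
    Dm[u, others] <- newD; Dm[others, u] <- newD
    Vm[u, others] <- pmax(newV, 0); Vm[others, u] <- pmax(newV, 0)
    nwk[u] <- sprintf("(%s:%.17g,%s:%.17g)", nwk[a], la, nwk[b], lb)
    act <- c(u, others)
  }
  # closing star of three
  a <- act[1L]; b <- act[2L]; c_ <- act[3L]
  la <- (Dm[a, b] + Dm[a, c_] - Dm[b, c_]) / 2
  lb <- (Dm[a, b] + Dm[b, c_] - Dm[a, c_]) / 2
  lc <- (Dm[a, c_] + Dm[b, c_] - Dm[a, b]) / 2
  txt <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);", nwk[a], max(la, 0),
                 nwk[b], max(lb, 0), nwk[c_], max(lc, 0))
  tr <- ape::read.tree(text = txt)
  tr$edge.length[tr$edge.length < 0] <- 0
  midpoint_root(tr)
}

midpoint_root <- function(tr) {
  out <- phangorn::midpoint(tr)
  if (!ape::is.binary(out)) out <- ape::multi2di(out, random = FALSE)
  out
}

# Cumulative heights (distance from the leaves) of every node in a rooted
# tree: height(v) = max over descendant leaves of the path length.
node_heights <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  h <- numeric(nn)
  # postorder over edges
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    h[par] <- max(h[par], h[ch] + po$edge.length[k])
  }
  h
}
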