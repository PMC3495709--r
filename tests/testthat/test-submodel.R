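models <- list(WAG = aa_model("WAG"), GONNET = aa_model("GONNET"))

test_that("generators are reversible, scaled, and produce stochastic matrices", {
  for (m in models) {
    expect_equal(rowSums(m$Q), rep(0, 20L), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
    flux <- m$pi * m$Q   # detailed balance
    expect_equal(flux, t(flux), tolerance = 1e-9, ignore_attr = TRUE)
    for (d in c(0, 0.1, 2)) {
      P <- transition_matrix(m, d)
      expect_equal(rowSums(P), rep(1, 20L), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
    expect_equal(transition_matrix(m, 0), diag(20L), ignore_attr = TRUE)
    # stationarity and the semigroup property
    expect_equal(as.numeric(m$pi %*% transition_matrix(m, 2)), unname(m$pi),
                 tolerance = 1e-9)
    expect_equal(transition_matrix(m, 0.3) %*% transition_matrix(m, 0.7),
                 transition_matrix(m, 1), tolerance = 1e-9)
    expect_error(transition_matrix(m, -0.1), "non-negative")
  }
})

test_that("matrix exponential agrees with an independent implementation", {
  m <- models$WAG
  for (d in c(0.05, 0.5, 1.7)) {
    expect_equal(transition_matrix(m, d), ape::matexpo(m$Q * d),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("WAG pruning likelihood matches phangorn on a small alignment", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  tr <- ape::rtree(4L)
  recs <- random_records(4L, c(30L, 30L))
  names(recs) <- tr$tip.label
  m <- models$WAG
  ll <- 0
  chars <- lapply(recs, function(s) strsplit(s, "")[[1L]])
  for (c_ in seq_len(30L)) {
    lik <- local({
      build <- function(node) {
        ntip <- length(tr$tip.label)
        if (node <= ntip) {
          return(leaf_likelihood(chars[[tr$tip.label[node]]][c_], m))
        }
        ch <- tr$edge[tr$edge[, 1L] == node, 2L]
        bl <- tr$edge.length[tr$edge[, 1L] == node]
        combine_likelihoods(build(ch[1L]), build(ch[2L]), bl[1L], bl[2L], m)
      }
      build(length(tr$tip.label) + 1L)
    })
    ll <- ll + column_likelihood(lik, m$pi, log = TRUE)
  }
  dat <- phangorn::phyDat(t(vapply(chars, identity, character(30L))),
                          type = "AA")
  fit <- phangorn::pml(tr, dat, model = "WAG")
  expect_equal(ll, as.numeric(fit$logLik), tolerance = 1e-6)
})

test_that("frequency estimation uses one pseudocount per amino acid", {
  f <- estimate_aafreqs(c(x = "AAAA"))
  expect_equal(unname(f[["A"]]), 5 / 24)
  expect_equal(unname(f[["W"]]), 1 / 24)
  set.seed(5)
  f2 <- estimate_aafreqs(random_records(3L))
  expect_equal(sum(f2), 1)
  mf <- aa_model("WAG", freqs = f2)
  expect_equal(mf$pi, f2, tolerance = 1e-12)
  expect_equal(-sum(mf$pi * diag(mf$Q)), 1, tolerance = 1e-12)
})

test_that("Kimura transform and its inverse are exact and monotone", {
  expect_equal(kimura_distance(0), 0)
  expect_equal(expected_divergence(0), 0)
  expect_equal(kimura_distance(0.5), -log(1 - 0.5 - 0.2 * 0.25))
  p <- seq(0.1, 0.7, 0.1)
  expect_equal(expected_divergence(kimura_distance(p)), p, tolerance = 1e-9)
  expect_true(all(diff(kimura_distance(seq(0, 0.75, 0.05))) > 0))
  expect_true(all(diff(expected_divergence(seq(0, 3, 0.1))) > 0))
  expect_warning(ds <- kimura_distance(0.95), "saturated")
  expect_equal(ds, 2.2)
})

test_that("ML pairwise distance matches a grid-search oracle and is consistent", {
  m <- models$WAG
  id <- paste(rep("A", 100L), collapse = "")
  expect_equal(ml_pairwise_distance(id, id, m)$distance, 1e-5,
               tolerance = 1e-4)

  set.seed(33)
  pr <- simulate_pair(2000L, 0.5, m)
  est <- ml_pairwise_distance(pr$a, pr$b, m)
  expect_lt(abs(est$distance - 0.5), 3 * sqrt(est$variance))

  # brute-force grid oracle (coarse scan then 1e-4 grid around the peak)
  counts <- graphmsa:::pair_counts(pr$a, pr$b)
  ll <- function(d) sum(counts * log(m$pi * transition_matrix(m, d)))
  coarse <- seq(0.01, 3, by = 0.01)
  c0 <- coarse[which.max(vapply(coarse, ll, numeric(1L)))]
  fine <- seq(max(1e-5, c0 - 0.02), c0 + 0.02, by = 1e-4)
  d_grid <- fine[which.max(vapply(fine, ll, numeric(1L)))]
  expect_lt(abs(est$distance - d_grid), 1e-3)

  # consistency: bias shrinks with more sites
  err <- vapply(c(500L, 5000L), function(n) {
    set.seed(n)
    mean(vapply(1:5, function(i) {
      pr <- simulate_pair(n, 0.5, m)
      abs(ml_pairwise_distance(pr$a, pr$b, m)$distance - 0.5)
    }, numeric(1L)))
  }, numeric(1L))
  expect_lt(err[2L], err[1L])
})

test_that("gap columns are excluded from pairwise estimates", {
  expect_equal(p_distance("MKV", "MKV"), 0)
  expect_equal(p_distance("MKV", "MAV"), 1 / 3)
  expect_equal(p_distance("M-K", "MEK"), 0)
  expect_warning(pd <- p_distance("---", "AC-"), "no ungapped")
  expect_equal(pd, 0.75)
  expect_warning(ml <- ml_pairwise_distance("--", "A-", models$WAG),
                 "no ungapped")
  expect_equal(ml$distance, 2.2)
})
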