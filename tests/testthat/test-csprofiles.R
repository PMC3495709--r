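m <- aa_model("WAG")

test_that("profile posterior follows the weighted window product", {
  lib1 <- context_profile_library(1, list(matrix(1 / 20, 20L, 3L)))
  expect_equal(match_profiles("MKVLM", 3L, lib1), 1)

  # one uniform and one profile concentrated on the window's letters
  conc <- matrix(1e-3, 20L, 3L)
  for (j in 1:3) conc[graphmsa:::AA_INDEX[c("M", "K", "V")][j], j] <- 1
  conc <- sweep(conc, 2L, colSums(conc), "/")
  lib2 <- context_profile_library(c(0.5, 0.5),
                                  list(matrix(1 / 20, 20L, 3L), conc))
  post <- match_profiles("MKVLM", 2L, lib2)
  expect_gt(post[2L], 0.5)
  expect_equal(sum(post), 1)

  # direct evaluation of the weighted product for a full window
  w <- 1.3 * 0.9^abs(-1:1)
  num <- c(0.5 * prod((1 / 20)^w),
           0.5 * prod(conc[graphmsa:::AA_INDEX[c("M", "K", "V")], ][cbind(1:3, 1:3)]^w))
  expect_equal(post, num / sum(num), tolerance = 1e-12)

  # window positions outside the sequence contribute factor 1
  post_edge <- match_profiles("MK", 1L, lib2)
  w2 <- 1.3 * 0.9^c(0, 1)
  num2 <- c(0.5 * prod((1 / 20)^w2),
            0.5 * conc[graphmsa:::AA_INDEX[["M"]], 2L]^w2[1L] *
              conc[graphmsa:::AA_INDEX[["K"]], 3L]^w2[2L])
  expect_equal(post_edge, num2 / sum(num2), tolerance = 1e-12)

  # invariance to global prior rescaling
  lib2b <- lib2
  expect_message(
    lib2b <- context_profile_library(c(5, 5), list(matrix(1 / 20, 20L, 3L), conc)),
    "renormalizing")
  expect_equal(match_profiles("MKVLM", 2L, lib2b), post, tolerance = 1e-12)
})

test_that("context profiles mix centre columns and normalize", {
  lib1 <- generate_test_library(seed = 2L, K = 1L + 1L, width = 5L)
  # single-profile library reduces to its centre column everywhere
  single <- context_profile_library(1, lib1$profiles[1L])
  prof <- context_profile("MKVL", single)
  for (i in 1:4) {
    expect_equal(unname(prof[, i]), unname(single$profiles[[1L]][, 3L]),
                 tolerance = 1e-12)
  }
  set.seed(8)
  lib <- generate_test_library(seed = 3L, K = 6L, width = 5L)
  p2 <- context_profile(paste(sample(graphmsa:::AA, 15, TRUE), collapse = ""), lib)
  expect_equal(unname(colSums(p2)), rep(1, 15L), tolerance = 1e-12)

  # hand-computed two-profile width-1 case
  d <- matrix(0, 20L, 1L); d[1L, 1L] <- 1   # delta on A
  u <- matrix(1 / 20, 20L, 1L)
  lib3 <- context_profile_library(c(0.3, 0.7), list(d, u))
  pr <- context_profile("A", lib3)
  w0 <- 1.3
  post <- c(0.3 * 1^w0, 0.7 * (1 / 20)^w0)
  post <- post / sum(post)
  expected <- (post[1L] * d + post[2L] * u)[, 1L]
  expect_equal(unname(pr[, 1L]), expected / sum(expected), tolerance = 1e-12)
})

test_that("tau interpolation matches the divergence-adjustment contract", {
  lib <- generate_test_library(seed = 5L, K = 4L, width = 3L)
  prof <- context_profile("MKV", lib)
  p0 <- adjust_tau(prof, 0, conservation = 0.2)
  expect_equal(attr(p0, "tau"), 0)
  expect_equal(unname(p0[, 1L]),
               as.numeric(graphmsa:::AA == "M"), tolerance = 1e-12)

  # tau arithmetic: delta 0.4, conservation 0.2 -> tau 0.5
  d_for <- kimura_distance(0.4)
  p5 <- adjust_tau(prof, d_for, conservation = 0.2)
  expect_equal(attr(p5, "tau"), 0.5, tolerance = 1e-9)
  expect_equal(unname(p5[, 2L]),
               unname(0.5 * (graphmsa:::AA == "K") + 0.5 * prof[, 2L]),
               tolerance = 1e-12)

  # tau capped at 1: profile returned unchanged
  p1 <- adjust_tau(prof, 10, conservation = 0.9)
  expect_equal(attr(p1, "tau"), 1)
  expect_equal(unclass(p1), unclass(prof), ignore_attr = TRUE,
               tolerance = 1e-12)

  # monotone entrywise in tau towards the profile
  taus <- c(0.2, 0.5, 0.8)
  ps <- lapply(taus, function(tt) {
    dd <- -log(1 - (tt * 0.8) - 0.2 * (tt * 0.8)^2)  # delta = tt*(1-0.2)
    adjust_tau(prof, dd, conservation = 0.2)
  })
  for (i in 1:2) {
    diff1 <- unclass(ps[[i + 1L]]) - unclass(ps[[i]])
    diff0 <- unclass(prof) - unclass(ps[[i]])
    expect_true(all(sign(diff1) * sign(diff0) >= 0))
  }
})

test_that("probabilistic-leaf conversion divides by equilibrium frequencies", {
  u <- structure(matrix(1 / 20, 20L, 2L), residues = c("A", "C"),
                 class = "site_profile")
  lv <- to_probabilistic_leaf(u, rep(1 / 20, 20L))
  expect_equal(unname(lv), matrix(1, 20L, 2L))

  d <- matrix(0, 20L, 1L); d[1L, 1L] <- 1
  dp <- structure(d, residues = "A", class = "site_profile")
  lv2 <- to_probabilistic_leaf(dp, m$pi)
  expect_equal(which(lv2[, 1L] > 0), 1L)

  set.seed(13)
  pr <- matrix(rgamma(20L, 1), 20L, 1L); pr <- pr / sum(pr)
  sp <- structure(pr, residues = "A", class = "site_profile")
  lv3 <- to_probabilistic_leaf(sp, m$pi)
  expect_equal(order(lv3[, 1L]), order(pr[, 1L] / m$pi))
})

test_that("the synthetic test library is valid, deterministic, and informative", {
  lib <- generate_test_library(seed = 1L, K = 8L, width = 13L)
  expect_equal(lib$K, 8L)
  expect_equal(lib$width, 13L)
  expect_equal(sum(lib$priors), 1)
  for (p in lib$profiles) {
    expect_equal(colSums(p), rep(1, 13L), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_identical(generate_test_library(seed = 1L, K = 8L, width = 13L), lib)
  cons <- library_conservation(lib, m$pi)
  expect_gt(cons, 1 / 20)
  expect_lt(cons, 1)
})

test_that("library conservation has the exact symmetric limits", {
  u <- context_profile_library(1, list(matrix(1 / 20, 20L, 1L)))
  expect_equal(library_conservation(u, rep(1 / 20, 20L)), 1 / 20,
               tolerance = 1e-12)
  d <- matrix(0, 20L, 1L); d[3L, 1L] <- 1
  dl <- context_profile_library(1, list(d))
  expect_equal(library_conservation(dl, rep(1 / 20, 20L)), 1 / 20,
               tolerance = 1e-12)
})
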