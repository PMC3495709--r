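m <- aa_model("WAG")

# Recompute the score of a backtracked move list independently of the DP.
path_score <- function(ares, S, sc, pen_a, pen_b, ga, gb) {
  steps <- ares$steps
  total <- 0
  last <- ""
  ea <- eb <- 0L
  for (s in seq_len(nrow(steps))) {
    type <- steps$type[s]
    if (type == 1L) {
      total <- total + sc$match_init + S[steps$a[s], steps$b[s]]
      last <- "M"
    } else if (type == 2L) {
      total <- total + if (last == "X") sc$gap_ext else sc$gap_init
      last <- "X"
    } else if (type == 3L) {
      total <- total + if (last == "Y") sc$gap_ext else sc$gap_init
      last <- "Y"
    } else if (type == 4L) {
      total <- total + sc$log_omega
    }
  }
  pa <- if (length(ares$edges_a)) sum(pen_a[ares$edges_a]) else 0
  pb <- if (length(ares$edges_b)) sum(pen_b[ares$edges_b]) else 0
  total + pa + pb
}

test_that("transition scores follow the distance-dependent gap model", {
  p <- pairhmm_params()
  s1 <- transition_scores(p, 1)
  expect_equal(s1$delta_d, p$delta)
  expect_equal(s1$match_init, log(1 - 2 * p$delta - p$omega))
  expect_equal(s1$gap_init, log(p$delta))
  expect_equal(s1$gap_ext, log(p$epsilon))

  s0 <- transition_scores(p, 0)
  expect_equal(s0$gap_init, log(1e-6))

  ds <- seq(0.05, 3, 0.05)
  gi <- vapply(ds, function(d) transition_scores(p, d)$gap_init, numeric(1L))
  expect_true(all(diff(gi) > 0))

  expect_error(pairhmm_params(delta = 0.5, omega = 0.2), "2 \\* delta")
  expect_error(transition_scores(p, -1), "d >= 0")
})

test_that("identical linear graphs align all-matched with the expected score", {
  ga <- from_sequence("a", "MKV", model = m)
  gb <- from_sequence("b", "MKV", model = m)
  S <- match_scores(ga$L, gb$L, 0.1, 0.1, m)
  sc <- transition_scores(pairhmm_params(alpha = -1), 0.2)
  ares <- align_graphs(ga, gb, S, sc)
  expect_equal(nrow(ares$matched), 3L)
  expect_equal(ares$score,
               3 * sc$match_init + sum(diag(S[2:4, 2:4])) + sc$log_omega,
               tolerance = 1e-12)
})

test_that("graph DP equals brute-force affine alignment enumeration", {
  set.seed(303)
  for (rep in 1:40) {
    la <- sample.int(6L, 1L); lb <- sample.int(6L, 1L)
    sa <- paste(sample(c("A", "C", "D", "E"), la, TRUE), collapse = "")
    sb <- paste(sample(c("A", "C", "D", "E"), lb, TRUE), collapse = "")
    ga <- from_sequence("a", sa, model = m)
    gb <- from_sequence("b", sb, model = m)
    d <- runif(1L, 0.1, 2)
    S <- match_scores(ga$L, gb$L, d / 2, d / 2, m)
    sc <- transition_scores(pairhmm_params(alpha = -1), d)
    ares <- align_graphs(ga, gb, S, sc)
    oracle <- oracle_affine_score(S[2:(la + 1L), 2:(lb + 1L), drop = FALSE],
                                  sc$match_init, sc$gap_init, sc$gap_ext)
    expect_equal(ares$score - sc$log_omega, oracle, tolerance = 1e-9)
  }
})

test_that("backtracked path score equals the DP score", {
  set.seed(42)
  for (rep in 1:25) {
    recs <- random_records(2L, c(3L, 10L))
    ga <- from_sequence("a", recs[[1L]], model = m)
    gb <- from_sequence("b", recs[[2L]], model = m)
    d <- runif(1L, 0.1, 2)
    S <- match_scores(ga$L, gb$L, d / 2, d / 2, m)
    sc <- transition_scores(pairhmm_params(alpha = -1), d)
    pen_a <- numeric(nrow(ga$edges)); pen_b <- numeric(nrow(gb$edges))
    ares <- align_graphs(ga, gb, S, sc, pen_a, pen_b)
    expect_equal(path_score(ares, S, sc, pen_a, pen_b, ga, gb), ares$score,
                 tolerance = 1e-9)
  }
})

test_that("alignment is symmetric under swapping the graphs", {
  set.seed(99)
  recs <- random_records(2L, c(6L, 12L))
  ga <- from_sequence("a", recs[[1L]], model = m)
  gb <- from_sequence("b", recs[[2L]], model = m)
  S <- match_scores(ga$L, gb$L, 0.3, 0.3, m)
  sc <- transition_scores(pairhmm_params(alpha = -1), 0.6)
  f <- align_graphs(ga, gb, S, sc)
  r <- align_graphs(gb, ga, t(S), sc)
  expect_equal(f$score, r$score, tolerance = 1e-12)
  expect_equal(unname(f$matched), unname(r$matched[, 2:1]))
})

test_that("an unusable alternative edge never changes the optimal score", {
  ga <- from_sequence("a", "MKVLI", model = m)
  gb <- from_sequence("b", "MKLI", model = m)
  S <- match_scores(ga$L, gb$L, 0.2, 0.2, m)
  sc <- transition_scores(pairhmm_params(), 0.4)
  base <- align_graphs(ga, gb, S, sc)
  ga2 <- ga
  ga2$edges <- rbind(ga$edges, data.frame(from = 2L, to = 5L, introduced = 0,
                                          last_used = 0, main = FALSE))
  pen <- c(numeric(nrow(ga$edges)), -Inf)
  with_alt <- align_graphs(ga2, gb, S, sc, pen_a = pen)
  expect_equal(with_alt$score, base$score, tolerance = 1e-12)
})

test_that("a zero-penalty alternative path is selected over a costly indel", {
  # graphA carries an old deletion (skip edge around C); graphB has a new T.
  ga0 <- from_sequence("x", "AWGD", model = m)
  gb0 <- from_sequence("y", "AGD", model = m)
  S0 <- match_scores(ga0$L, gb0$L, 0.05, 0.05, m)
  sc0 <- transition_scores(pairhmm_params(alpha = -1), 0.1)
  a0 <- align_graphs(ga0, gb0, S0, sc0)
  ga <- merge_graphs(ga0, gb0, a0, 0.05, 0.05, m, height = 0.05)
  expect_length(ga$pending, 1L)
  skip_edge <- ga$pending[[1L]]$skip
  ga <- resolve_pending_indels(ga, NULL)  # treat W as an insertion

  gb <- from_sequence("z", "ATGD", model = m)
  S <- match_scores(ga$L, gb$L, 0.05, 0.05, m)
  sc <- transition_scores(pairhmm_params(alpha = -1), 0.1)
  w_node <- which(vapply(ga$columns, function(cl) !is.null(cl) &&
                           identical(unname(cl), "W"), logical(1L)))
  t_node <- which(vapply(gb$columns, function(cl) !is.null(cl) &&
                           identical(unname(cl), "T"), logical(1L)))
  S[w_node, t_node] <- -20   # W and T are clearly not homologous
  # zero penalties: the skip path around W is free
  ares <- align_graphs(ga, gb, S, sc)
  expect_false(w_node %in% ares$path_a)        # deletion: skip path chosen
  expect_false(t_node %in% ares$matched[, 2L]) # insertion: T unmatched
  expect_true(t_node %in% ares$path_b)
  # with the skip edge forbidden the W path must be used
  pen <- numeric(nrow(ga$edges))
  pen[skip_edge] <- -Inf
  ares2 <- align_graphs(ga, gb, S, sc, pen_a = pen)
  expect_true(w_node %in% ares2$path_a)
})

test_that("the forced methionine bonus changes only M-initial alignments", {
  ga <- from_sequence("a", "MC", model = m)
  gb <- from_sequence("b", "MC", model = m)
  sc <- transition_scores(pairhmm_params(alpha = -1), 0.4)
  # misleading profile evidence against the initial M-M match
  S <- match_scores(ga$L, gb$L, 0.2, 0.2, m)
  S[2L, 2L] <- -12
  off <- align_graphs(ga, gb, S, sc)
  on <- align_graphs(ga, gb, S, sc, force_align_m_bonus = 10)
  expect_false(any(off$matched[, 1L] == 2L & off$matched[, 2L] == 2L))
  expect_true(any(on$matched[, 1L] == 2L & on$matched[, 2L] == 2L))
  expect_equal(on$score,
               off$score - 2 * sc$gap_init + sc$match_init + S[2L, 2L] + 10,
               tolerance = 1e-9)

  # flag on but no initial methionine in one graph: no effect
  gc_ <- from_sequence("c", "KC", model = m)
  S2 <- match_scores(gc_$L, gb$L, 0.2, 0.2, m)
  off2 <- align_graphs(gc_, gb, S2, sc)
  on2 <- align_graphs(gc_, gb, S2, sc, force_align_m_bonus = 10)
  expect_equal(on2$score, off2$score, tolerance = 1e-12)
  expect_equal(on2$matched, off2$matched)
})
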