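m <- aa_model("WAG")

align_pair <- function(ga, gb, d = 0.3, params = pairhmm_params(),
                       lifetime = 1, height = NULL) {
  S <- match_scores(ga$L, gb$L, d / 2, d / 2, m)
  sc <- transition_scores(params, d)
  h <- height %||% d / 2
  ares <- align_graphs(ga, gb, S, sc,
                       graphmsa:::graph_penalties(ga, h, lifetime),
                       graphmsa:::graph_penalties(gb, h, lifetime))
  list(ares = ares,
       merged = merge_graphs(ga, gb, ares, d / 2, d / 2, m, height = h))
}

test_that("leaf graphs are linear chains with single predecessors", {
  g <- from_sequence("a", "MKV", model = m)
  expect_equal(g$n, 5L)
  expect_equal(nrow(g$edges), 4L)
  expect_equal(g$start, 1L)
  expect_equal(g$end, 5L)
  npred <- tabulate(g$edges$to, nbins = g$n)
  expect_equal(npred[setdiff(seq_len(g$n), g$start)], rep(1L, 4L))
  expect_equal(unname(unlist(g$columns[2:4])), c("M", "K", "V"))
  expect_error(from_sequence("a", "", model = m), "empty sequence")
})

test_that("topological order is deterministic and respects edges", {
  g <- from_sequence("a", "MKVL", model = m)
  expect_equal(topological_order(g), 1:6)
  # same graph with permuted edge rows and an extra skip edge
  g2 <- g
  g2$edges <- rbind(g$edges[c(3, 1, 4, 2), ],
                    data.frame(from = 2L, to = 4L, introduced = 0,
                               last_used = 0, main = FALSE))
  topo <- topological_order(g2)
  expect_equal(topo, 1:6)  # character path nodes before skip continuation
  pos <- match(seq_len(g2$n), topo)
  expect_true(all(pos[g2$edges$from] < pos[g2$edges$to]))
})

test_that("edge penalties decay with distance since last use", {
  expect_equal(edge_penalty(0.5, 0.5, lifetime = 1), 0)
  expect_equal(edge_penalty(0.2, 0.7, lifetime = 1), -0.5)
  expect_equal(edge_penalty(0.2, 0.7, lifetime = Inf), 0)
  expect_equal(edge_penalty(0.2, 0.7, lifetime = 0), -Inf)
  expect_equal(edge_penalty(0.2, 0.7, lifetime = 0, main = TRUE), 0)
  expect_error(edge_penalty(0.7, 0.2, 1), "below")
})

test_that("merging two identical graphs fuses all nodes", {
  ga <- from_sequence("a", "MKV", model = m)
  gb <- from_sequence("b", "MKV", model = m)
  out <- align_pair(ga, gb)
  mg <- out$merged
  expect_equal(mg$n, 5L)
  expect_equal(nrow(out$ares$matched), 3L)
  for (i in 2:4) expect_length(mg$columns[[i]], 2L)
  expect_length(mg$pending, 0L)
  msa <- extract_msa(mg)
  expect_equal(unname(msa), c("MKV", "MKV"), ignore_attr = TRUE)
})

test_that("an unmatched node creates a pending indel with a skip edge", {
  ga <- from_sequence("a", "ACGD", model = m)
  gb <- from_sequence("b", "ACTGD", model = m)   # T insertion in b
  out <- align_pair(ga, gb)
  mg <- out$merged
  expect_length(mg$pending, 1L)
  pe <- mg$pending[[1L]]
  expect_length(pe$chars, 1L)
  expect_equal(unname(mg$columns[[pe$chars]]), "T")
  sk <- mg$edges[pe$skip, ]
  # the skip edge bypasses the character path
  expect_true(sk$from < min(pe$chars) || sk$to > max(pe$chars))
  msa <- extract_msa(mg)
  expect_equal(nchar(msa[[1L]]), 5L)
  expect_equal(unname(msa["a"]), "AC-GD")
})

test_that("pending indels resolve by outgroup matching", {
  ga <- from_sequence("a", "ACGD", model = m)
  gb <- from_sequence("b", "ACTGD", model = m)
  mg <- align_pair(ga, gb)$merged
  pe <- mg$pending[[1L]]

  del <- resolve_pending_indels(mg, matched_ids = pe$chars)
  expect_equal(attr(del, "decisions")[[1L]]$decision, "deletion")
  expect_false(del$edges$main[pe$skip])
  expect_length(del$pending, 0L)

  ins <- resolve_pending_indels(mg, matched_ids = setdiff(3:4, pe$chars))
  expect_equal(attr(ins, "decisions")[[1L]]$decision, "insertion")
  char_edges <- which(mg$edges$from %in% pe$chars | mg$edges$to %in% pe$chars)
  expect_true(all(!ins$edges$main[char_edges]))

  root <- resolve_pending_indels(mg, NULL)
  expect_equal(attr(root, "decisions")[[1L]]$decision, "insertion")
})

test_that("merged graphs stay acyclic and connected over random merges", {
  set.seed(77)
  for (rep in 1:120) {
    recs <- random_records(2L, c(2L, 8L))
    ga <- from_sequence("a", recs[[1L]], model = m)
    gb <- from_sequence("b", recs[[2L]], model = m)
    mg <- align_pair(ga, gb, d = runif(1L, 0.05, 2))$merged
    expect_silent(graphmsa:::check_acyclic(mg))
    # indel history is never deleted
    expect_gte(mg$n, max(ga$n, gb$n))
    expect_gte(nrow(mg$edges), max(nrow(ga$edges), nrow(gb$edges)))
    # second-level merge with a third sequence
    gc_ <- from_sequence("c", random_records(1L, c(2L, 8L))[[1L]], model = m)
    mg <- resolve_pending_indels(mg, NULL)
    mg2 <- align_pair(mg, gc_, d = runif(1L, 0.05, 2), height = 2)$merged
    expect_silent(graphmsa:::check_acyclic(mg2))
    msa <- extract_msa(mg2)
    expect_equal(gsub("-", "", msa[["a"]]), recs[[1L]])
    expect_equal(gsub("-", "", msa[["b"]]), recs[[2L]])
  }
})

test_that("non-monotone matchings are rejected", {
  ga <- from_sequence("a", "AC", model = m)
  gb <- from_sequence("b", "AC", model = m)
  out <- align_pair(ga, gb)
  bad <- out$ares
  bad$matched <- bad$matched[2:1, , drop = FALSE]
  expect_error(merge_graphs(ga, gb, bad, 0.1, 0.1, m), "non-monotone")
})
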