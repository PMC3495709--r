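#' Sequence graphs
#'
#' A sequence graph is a directed acyclic graph with explicit start and end
#' sentinel nodes.  Every non-sentinel node corresponds to one alignment
#' column (a mapping leaf -> residue plus a likelihood vector over ancestral
#' amino acids); every path from start to end is a candidate ancestral
#' sequence.  Edges record the indel history: when they were introduced and
#' when a selected homologous path last traversed them, which drives the
#' phylogeny-aware reuse penalties.
#'
#' @name seq_graph
NULL

new_seq_graph <- function(columns, L, logscale, edges, leaves,
                          start = 1L, end = length(columns)) {
  structure(list(n = length(columns), start = start, end = end,
                 columns = columns, L = L, logscale = logscale,
                 edges = edges, pending = list(), leaves = leaves),
            class = "seq_graph")
}

#' Build a linear sequence graph from one leaf sequence
#'
#' The leaves of the guide tree carry linear chains
#' `start -> x_1 -> ... -> x_n -> end`; every node but the start has exactly
#' one predecessor.
#'
#' @param id Leaf identifier.
#' @param residues Residue string.
#' @param L Optional `20 x n` matrix of leaf likelihood vectors (one column
#'   per residue); defaults to indicator vectors.
#' @param model Optional [aa_model()] used for ambiguity-code expansion.
#' @return A `seq_graph`.
#' @export
from_sequence <- function(id, residues, L = NULL, model = NULL) {
  chars <- strsplit(residues, "")[[1L]]
  nc <- length(chars)
  if (nc == 0L) stop("empty sequence for leaf ", id)
  n <- nc + 2L
  columns <- vector("list", n)
  for (i in seq_len(nc)) columns[[i + 1L]] <- setNames(chars[i], id)
  Lm <- matrix(1, 20L, n)
  if (is.null(L)) {
    for (i in seq_len(nc)) Lm[, i + 1L] <- leaf_likelihood(chars[i], model)
  } else {
    stopifnot(ncol(L) == nc)
    Lm[, seq_len(nc) + 1L] <- L
  }
  edges <- data.frame(from = seq_len(n - 1L), to = seq_len(n - 1L) + 1L,
                      introduced = 0, last_used = 0, main = TRUE)
  new_seq_graph(columns, Lm, numeric(n), edges, leaves = id,
                start = 1L, end = n)
}

#' @export
print.seq_graph <- function(x, ...) {
  cat("Sequence graph:", x$n - 2L, "character nodes,", nrow(x$edges), "edges,",
      length(x$leaves), "leaves (", paste(head(x$leaves, 5L), collapse = ", "),
      if (length(x$leaves) > 5L) "..." else "", ")\n")
  if (length(x$pending)) cat("  pending indels:", length(x$pending), "\n")
  invisible(x)
}

#' Deterministic topological order of a sequence graph
#'
#' Kahn's algorithm with a smallest-node-id tie-break, so that permuting the
#' node insertion order never changes the output.  The start node comes
#' first and the end node last.
#'
#' @param graph A `seq_graph`.
#' @return Integer vector of node ids in topological order.
#' @export
topological_order <- function(graph) {
  n <- graph$n
  indeg <- tabulate(graph$edges$to, nbins = n)
  succ <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(n)))
  ready <- which(indeg == 0L)
  out <- integer(0L)
  while (length(ready)) {
    v <- min(ready)
    ready <- ready[ready != v]
    out <- c(out, v)
    for (w in succ[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(out) != n) stop("graph contains a cycle")
  if (out[1L] != graph$start || out[n] != graph$end) {
    stop("start/end sentinels are not extremal in the graph")
  }
  out
}

#' Phylogeny-aware edge reuse penalty
#'
#' An edge off the current ancestral path is penalized in natural-log space
#' by `-(current_height - last_used) / lifetime`: the probability of reusing
#' the path declines exponentially with the evolutionary distance since its
#' last use.  Edges on the current ancestral path (and undecided pending
#' alternatives) have penalty 0.  `lifetime = 0` forbids reuse entirely
#' (keep-insertions-forever mode); `lifetime = Inf` disables the penalty.
#'
#' @param last_used Height (cumulative distance from the leaves) at which the
#'   edge was last traversed by a selected homologous path.
#' @param current_height Height of the guide-tree node being aligned; must
#'   not be below `last_used`.
#' @param lifetime Penalty e-folding distance `l`, `>= 0`.
#' @param main Logical; `TRUE` for edges on the current ancestral path.
#' @return Non-positive penalty (vectorized over edges).
#' @export
edge_penalty <- function(last_used, current_height, lifetime = 1, main = FALSE) {
  dd <- current_height - last_used
  if (any(dd < -1e-9)) stop("current height below an edge's last use")
  dd <- pmax(dd, 0)
  out <- ifelse(main | dd == 0, 0,
                if (lifetime == 0) -Inf else -dd / lifetime)
  out
}

graph_penalties <- function(graph, current_height, lifetime) {
  edge_penalty(graph$edges$last_used, current_height, lifetime,
               main = graph$edges$main)
}

# Flat predecessor structure for the DP: for each node (in topological
# position space) the list of incoming edges as (pred position, edge row).
pred_structure <- function(graph, topo) {
  n <- graph$n
  pos <- integer(n)
  pos[topo] <- seq_len(n)
  ord <- order(pos[graph$edges$to], pos[graph$edges$from])
  e_to <- pos[graph$edges$to][ord]
  ptr <- c(0L, cumsum(tabulate(e_to, nbins = n)))
  list(ptr = ptr,                       # 0-based offsets per topo position
       pred = pos[graph$edges$from][ord],
       edge = ord,                      # edge row in graph$edges
       pos = pos)
}

#' Merge two aligned sequence graphs
#'
#' Matched node pairs are fused into single nodes whose column is the union
#' of both columns and whose likelihood vector is the pruning combination of
#' the children's vectors.  All nodes and edges of both graphs are retained
#' (the indel history is never deleted).  Unmatched nodes along the
#' homologous paths create pending indels: a skip edge is added around each
#' unmatched run and the insertion/deletion decision is postponed to the
#' next alignment towards the root.  Edges traversed by the homologous paths
#' have their last-use height updated and form the new ancestral (main)
#' path; all other edges become penalized alternatives.
#'
#' @param ga,gb The two `seq_graph`s.
#' @param ares Alignment result from [align_graphs()].
#' @param d_left,d_right Branch lengths from the new ancestor to `ga`, `gb`.
#' @param model An [aa_model()].
#' @param height Height (cumulative distance from the leaves) of the
#'   guide-tree node where the merge happens.
#' @return A `seq_graph` with attributes `map_a`, `map_b` giving the new id
#'   of every old node.
#' @export
merge_graphs <- function(ga, gb, ares, d_left, d_right, model, height = 0) {
  steps <- ares$steps
  matched_a <- ares$matched[, 1L]
  matched_b <- ares$matched[, 2L]
  check_monotone_matching(ga, gb, ares)
  map_a <- rep(NA_integer_, ga$n)
  map_b <- rep(NA_integer_, gb$n)
  nid <- 0L
  for (s in seq_len(nrow(steps))) {
    type <- steps$type[s]
    nid <- nid + 1L
    if (type %in% c(0L, 1L, 4L)) {      # start, match, end
      map_a[steps$a[s]] <- nid
      map_b[steps$b[s]] <- nid
    } else if (type == 2L) {            # gap in A: node from B
      map_b[steps$b[s]] <- nid
    } else {                            # gap in B: node from A
      map_a[steps$a[s]] <- nid
    }
  }
  off_a <- which(is.na(map_a))
  map_a[off_a] <- nid + seq_along(off_a)
  nid <- nid + length(off_a)
  off_b <- which(is.na(map_b))
  map_b[off_b] <- nid + seq_along(off_b)
  nid <- nid + length(off_b)

  n <- nid
  end_id <- map_a[ga$end]

  # columns
  columns <- vector("list", n)
  for (i in seq_len(ga$n)) columns[map_a[i]] <- list(ga$columns[[i]])
  for (j in seq_len(gb$n)) {
    columns[map_b[j]] <- list(c(columns[[map_b[j]]], gb$columns[[j]]))
  }

  # likelihood vectors: evolve both children, multiply where fused
  ea <- transition_matrix(model, d_left) %*% ga$L
  eb <- transition_matrix(model, d_right) %*% gb$L
  L <- matrix(1, 20L, n)
  logscale <- numeric(n)
  L[, map_a] <- ea
  logscale[map_a] <- ga$logscale
  fused_b <- !is.na(match(map_b, map_a))
  L[, map_b[!fused_b]] <- eb[, !fused_b, drop = FALSE]
  logscale[map_b[!fused_b]] <- gb$logscale[!fused_b]
  if (any(fused_b)) {
    jb <- which(fused_b)
    L[, map_b[jb]] <- L[, map_b[jb], drop = FALSE] * eb[, jb, drop = FALSE]
    logscale[map_b[jb]] <- logscale[map_b[jb]] + gb$logscale[jb]
  }
  mx <- apply(L, 2L, max)
  L <- sweep(L, 2L, mx, "/")
  logscale <- logscale + log(mx)

  # edges: remap, mark traversal, dedupe parallel duplicates
  ea_df <- ga$edges
  ea_df$from <- map_a[ea_df$from]; ea_df$to <- map_a[ea_df$to]
  ea_df$trav <- seq_len(nrow(ea_df)) %in% ares$edges_a
  eb_df <- gb$edges
  eb_df$from <- map_b[eb_df$from]; eb_df$to <- map_b[eb_df$to]
  eb_df$trav <- seq_len(nrow(eb_df)) %in% ares$edges_b
  ed <- rbind(ea_df, eb_df)
  key <- paste(ed$from, ed$to)
  grp <- match(key, unique(key))
  agg <- function(v, f) as.numeric(tapply(v, grp, f))
  edges <- data.frame(
    from = as.integer(agg(ed$from, function(x) x[1L])),
    to = as.integer(agg(ed$to, function(x) x[1L])),
    introduced = agg(ed$introduced, min),
    last_used = agg(ed$last_used, max),
    main = as.logical(agg(ed$trav, any))
  )
  edges$last_used[edges$main] <- height

  out <- new_seq_graph(columns, L, logscale, edges,
                       leaves = c(ga$leaves, gb$leaves),
                       start = 1L, end = end_id)

  # pending indels: unmatched runs along each graph's homologous path
  # (the sentinels are always matched and anchor terminal runs)
  out$pending <- c(
    find_pending(out, ares$path_a, c(ga$start, ga$end, matched_a), map_a,
                 height, "A"),
    find_pending(out, ares$path_b, c(gb$start, gb$end, matched_b), map_b,
                 height, "B")
  )
  for (p in seq_along(out$pending)) {
    pe <- out$pending[[p]]
    if (is.na(pe$skip)) {  # add the skip edge around the run
      out$edges <- rbind(out$edges,
                         data.frame(from = pe$anchor_l, to = pe$anchor_r,
                                    introduced = height, last_used = height,
                                    main = TRUE))
      out$pending[[p]]$skip <- nrow(out$edges)
    }
  }
  check_acyclic(out)
  attr(out, "map_a") <- map_a
  attr(out, "map_b") <- map_b
  out
}

find_pending <- function(merged, path, matched, map, height, source) {
  on_path_matched <- path %in% matched
  pend <- list()
  run <- integer(0L)
  last_anchor <- NA_integer_
  for (k in seq_along(path)) {
    if (on_path_matched[k]) {
      if (length(run)) {
        new_ids <- map[run]
        anchor_l <- map[last_anchor]
        anchor_r <- map[path[k]]
        skip <- which(merged$edges$from == anchor_l & merged$edges$to == anchor_r)
        pend[[length(pend) + 1L]] <- list(
          chars = new_ids, anchor_l = anchor_l, anchor_r = anchor_r,
          skip = if (length(skip)) skip[1L] else NA_integer_,
          height = height, source = source)
        run <- integer(0L)
      }
      last_anchor <- path[k]
    } else {
      run <- c(run, path[k])
    }
  }
  pend
}

check_monotone_matching <- function(ga, gb, ares) {
  m <- ares$matched
  if (nrow(m) < 2L) return(invisible(TRUE))
  pa <- ares$path_a; pb <- ares$path_b
  if (any(diff(match(m[, 1L], pa)) <= 0) || any(diff(match(m[, 2L], pb)) <= 0)) {
    stop("non-monotone matching: alignment DP invariant violated")
  }
  invisible(TRUE)
}

check_acyclic <- function(graph) {
  topological_order(graph)  # errors on a cycle
  # connectivity: every node reachable from start and reaching end
  n <- graph$n
  succ <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(n)))
  pred <- split(graph$edges$from, factor(graph$edges$to, levels = seq_len(n)))
  reach <- function(root, adj) {
    seen <- logical(n)
    stack <- root
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]])
    }
    seen
  }
  if (!all(reach(graph$start, succ))) stop("node unreachable from start")
  if (!all(reach(graph$end, pred))) stop("node cannot reach end")
  invisible(TRUE)
}

#' Resolve pending indels of a child graph using its parent alignment
#'
#' A pending indel's character path is declared a deletion if any of its
#' nodes was matched in the alignment at the next guide-tree node towards
#' the root (the closest outgroup confirms the characters were ancestral);
#' otherwise it is an insertion and the skip edge is the ancestral route.
#' At the root, where no outgroup exists, remaining pending indels resolve
#' as insertions.
#'
#' @param graph The child `seq_graph` whose pendings are to be resolved.
#' @param matched_ids Ids of this graph's nodes matched in the parent
#'   alignment, or `NULL` at the root.
#' @return The graph with pendings cleared, plus a `decisions` attribute:
#'   a list of `list(chars, decision, height)`.
#' @export
resolve_pending_indels <- function(graph, matched_ids = NULL) {
  decisions <- list()
  for (pe in graph$pending) {
    del <- !is.null(matched_ids) && any(pe$chars %in% matched_ids)
    decision <- if (del) "deletion" else "insertion"
    loser <- if (del) {
      pe$skip
    } else {
      which(graph$edges$to %in% pe$chars | graph$edges$from %in% pe$chars)
    }
    graph$edges$main[loser] <- FALSE
    decisions[[length(decisions) + 1L]] <-
      list(chars = pe$chars, decision = decision, height = pe$height,
           source = pe$source)
  }
  graph$pending <- list()
  attr(graph, "decisions") <- decisions
  graph
}

#' Extract the multiple sequence alignment from a root graph
#'
#' Emits one column per non-sentinel node in deterministic topological
#' order.  Row `r` carries its residue wherever the node's column contains
#' leaf `r` and `-` elsewhere; degapping any row recovers the input
#' sequence exactly (checked).
#'
#' @param graph The root `seq_graph`.
#' @param leaf_order Optional row order (defaults to the graph's leaf
#'   order).
#' @return Named character vector of aligned rows.
#' @export
extract_msa <- function(graph, leaf_order = graph$leaves) {
  topo <- topological_order(graph)
  cols <- topo[!(topo %in% c(graph$start, graph$end))]
  m <- matrix("-", length(leaf_order), length(cols),
              dimnames = list(leaf_order, NULL))
  for (k in seq_along(cols)) {
    col <- graph$columns[[cols[k]]]
    m[names(col), k] <- col
  }
  rows <- apply(m, 1L, paste, collapse = "")
  structure(setNames(rows, leaf_order), node_ids = cols)
}

#' Write a sequence graph in DOT format (for debugging and figures)
#'
#' @param graph A `seq_graph`.
#' @param path Output path.
#' @export
write_dot <- function(graph, path) {
  lab <- vapply(seq_len(graph$n), function(i) {
    if (i == graph$start) "start"
    else if (i == graph$end) "end"
    else paste0(i, ":", paste0(graph$columns[[i]], collapse = ""))
  }, character(1L))
  lines <- c("digraph seqgraph {", "  rankdir=LR;",
             sprintf("  n%d [label=\"%s\"];", seq_len(graph$n), lab),
             sprintf("  n%d -> n%d [style=%s];", graph$edges$from,
                     graph$edges$to,
                     ifelse(graph$edges$main, "solid", "dotted")),
             "}")
  writeLines(lines, path)
  invisible(path)
}
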