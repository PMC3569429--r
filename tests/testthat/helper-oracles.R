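# Independent oracles used across the suite. These deliberately avoid the
# package's production code paths: definability is decided by exhaustive
# search over integer labelings, subgraph counts by direct enumeration of
# injective role maps.

# Exhaustive-labeling definability oracle: does any assignment of potentials
# in {0..max_p}^nodes satisfy p[from] = p[to] + 1 for every arc? Depth-first
# over the full box, pruning branches as soon as an arc between two assigned
# nodes is violated. Sufficient for graphs with at most max_p + 1 nodes:
# within a weak component the potential spread is at most n - 1, so a
# min-normalized witness fits the box.
oracle_definable <- function(g, max_p = 7L) {
  nodes <- graph_nodes(g)
  n <- length(nodes)
  if (n == 0L) {
    return(TRUE)
  }
  fi <- match(g$from, nodes)
  ti <- match(g$to, nodes)
  search <- function(pot, k) {
    if (k > n) {
      return(TRUE)
    }
    for (v in 0:max_p) {
      pot[k] <- v
      touching <- which((fi == k & ti < k) | (ti == k & fi < k) | (fi == k & ti == k))
      ok <- all(pot[fi[touching]] == pot[ti[touching]] + 1L)
      if (ok && search(pot, k + 1L)) {
        return(TRUE)
      }
    }
    FALSE
  }
  search(integer(n), 1L)
}

# cycle-space oracle: definable iff every cycle of the underlying undirected
# graph traverses equal numbers of forward and backward arcs. Uses a cycle
# basis from a spanning forest (igraph for the forest only).
oracle_definable_cycle_basis <- function(g) {
  nodes <- graph_nodes(g)
  n <- length(nodes)
  if (nrow(g) == 0L) {
    return(TRUE)
  }
  fi <- match(g$from, nodes)
  ti <- match(g$to, nodes)
  # reciprocal pair = 2-cycle with one forward, one backward arc -> imbalance
  if (any(paste(fi, ti) %in% paste(ti, fi))) {
    return(FALSE)
  }
  # signed distances to component roots over a BFS spanning forest
  dist_sign <- rep(NA_real_, n)
  parent_edge <- rep(NA_integer_, n)
  for (root in seq_len(n)) {
    if (!is.na(dist_sign[root])) next
    dist_sign[root] <- 0
    queue <- root
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      inc_edges <- which(fi == u | ti == u)
      for (e in inc_edges) {
        v <- if (fi[e] == u) ti[e] else fi[e]
        d <- if (fi[e] == u) -1 else 1 # following u->v drops one unit
        if (is.na(dist_sign[v])) {
          dist_sign[v] <- dist_sign[u] + d
          parent_edge[v] <- e
          queue <- c(queue, v)
        }
      }
    }
  }
  # every non-tree arc closes a basis cycle; balance <=> implied diff equals 1
  tree_edges <- parent_edge[!is.na(parent_edge)]
  for (e in setdiff(seq_along(fi), tree_edges)) {
    if (dist_sign[fi[e]] - dist_sign[ti[e]] != 1) {
      return(FALSE)
    }
  }
  TRUE
}

# Brute-force count of pattern occurrences in a digraph: injective role maps
# whose every pattern arc is present, divided by the automorphism order.
oracle_count_occurrences <- function(g, pattern) {
  nodes <- graph_nodes(g)
  n <- length(nodes)
  ord <- pattern$order
  if (n < ord) {
    return(0)
  }
  fi <- match(g$from, nodes)
  ti <- match(g$to, nodes)
  A <- matrix(FALSE, n, n)
  A[cbind(fi, ti)] <- TRUE
  tuples <- as.matrix(expand.grid(rep(list(seq_len(n)), ord)))
  distinct_rows <- apply(tuples, 1L, function(r) length(unique(r)) == ord)
  tuples <- tuples[distinct_rows, , drop = FALSE]
  arcs <- pattern$arcs
  ok <- rep(TRUE, nrow(tuples))
  for (e in seq_len(nrow(arcs))) {
    ok <- ok & A[cbind(tuples[, arcs[e, 1L]], tuples[, arcs[e, 2L]])]
  }
  sum(ok) / length(pattern$automorphisms)
}

# Brute-force candidate score: occurrences of the parent pattern in
# train + candidate where the candidate plays the probe-arc role, counted
# directly from injective role maps (stabilizer of the probe arc is trivial).
oracle_score <- function(train, candidate, spec) {
  nodes <- graph_nodes(train)
  n <- length(nodes)
  fi <- match(train$from, nodes)
  ti <- match(train$to, nodes)
  A <- matrix(FALSE, n, n)
  A[cbind(fi, ti)] <- TRUE
  x <- match(candidate[[1L]], nodes)
  y <- match(candidate[[2L]], nodes)
  A[x, y] <- TRUE
  ord <- spec$order
  res <- rbind(spec$residual[[1L]], c(spec$probe_from, spec$probe_to))
  tuples <- as.matrix(expand.grid(rep(list(seq_len(n)), ord)))
  keep <- tuples[, spec$probe_from] == x & tuples[, spec$probe_to] == y &
    apply(tuples, 1L, function(r) length(unique(r)) == ord)
  tuples <- tuples[keep, , drop = FALSE]
  ok <- rep(TRUE, nrow(tuples))
  for (e in seq_len(nrow(res))) {
    ok <- ok & A[cbind(tuples[, res[e, 1L]], tuples[, res[e, 2L]])]
  }
  sum(ok)
}

rand_graph_for_tests <- function(n, m, seed, allow_reciprocal = TRUE) {
  random_digraph(n, m, allow_reciprocal = allow_reciprocal, seed = seed)
}
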