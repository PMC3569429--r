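# Subgraph-completion link scoring.
#
# The score of a non-observed candidate arc under predictor Sk is the number
# of occurrences of Sk's parent pattern that the candidate's addition would
# create with the candidate playing the removed-arc role. An occurrence is an
# injective map of pattern roles to distinct graph nodes such that every
# pattern arc maps to a present arc; extra arcs among the image nodes
# (including reciprocal partners) are ignored, per the generalized
# (non-induced) subgraph definition. Because the automorphism subgroup
# fixing the probe arc is trivial for all twelve predictors, counting
# reduces to counting distinct assignments of the free roles.

resolve_spec <- function(predictor) {
  if (is.data.frame(predictor)) {
    stopifnot(nrow(predictor) == 1L, all(c("probe_from", "probe_to", "residual", "order") %in% names(predictor)))
    return(predictor)
  }
  spec <- expand_predictors(predictor)
  if (nrow(spec) != 1L) {
    abort("Expected a single predictor; got a grouping. Use hybrid_score() or score_all().")
  }
  spec
}

check_candidate <- function(train, from, to) {
  if (from == to) {
    abort("Candidate must not be a self-loop.")
  }
  if (has_arc(train, from, to)) {
    abort(sprintf("Candidate %s -> %s is already an observed arc.", from, to))
  }
  nodes <- graph_nodes(train)
  if (!(from %in% nodes) || !(to %in% nodes)) {
    abort("Candidate endpoints must belong to the training graph's node set.")
  }
}

#' Score a candidate link by brute-force subgraph counting
#'
#' Reference implementation that enumerates every injective assignment of the
#' free pattern roles over all nodes and checks the residual arcs directly.
#' Exponential in the (at most two) free roles; intended as the oracle that
#' [score_link_fast()] must match, and for small graphs.
#'
#' @param train A `digraph` of observed (training) arcs.
#' @param candidate The candidate arc: length-2 character vector
#'   `c(from, to)` or a one-row data frame with `from`/`to` columns. Must not
#'   be observed and must not be a self-loop.
#' @param predictor A predictor id ("S1".."S12") or one row of
#'   [derive_predictors()].
#' @return Non-negative integer count of parent-pattern occurrences created
#'   by the candidate in the removed-arc role.
#' @export
score_link <- function(train, candidate, predictor) {
  stopifnot(is_digraph(train))
  cand <- as_arc_tbl(candidate, "candidate")
  stopifnot(nrow(cand) == 1L)
  check_candidate(train, cand$from, cand$to)
  spec <- resolve_spec(predictor)
  idx <- adjacency_index(train)
  A <- dense_adjacency(idx)
  score_link_brute_idx(A, idx$n, match(cand$from, idx$nodes), match(cand$to, idx$nodes), spec)
}

score_link_brute_idx <- function(A, n, x, y, spec) {
  ord <- spec$order
  free <- setdiff(seq_len(ord), c(spec$probe_from, spec$probe_to))
  res <- spec$residual[[1L]]
  assign_roles <- function(free_nodes) {
    m <- integer(ord)
    m[spec$probe_from] <- x
    m[spec$probe_to] <- y
    m[free] <- free_nodes
    m
  }
  others <- setdiff(seq_len(n), c(x, y))
  if (length(free) == 1L) {
    if (length(others) == 0L) {
      return(0L)
    }
    grid <- matrix(others, ncol = 1L)
  } else {
    if (length(others) < 2L) {
      return(0L)
    }
    grid <- as.matrix(expand.grid(others, others))
    grid <- grid[grid[, 1L] != grid[, 2L], , drop = FALSE]
  }
  ok <- rep(TRUE, nrow(grid))
  for (e in seq_len(nrow(res))) {
    r_from <- res[e, 1L]
    r_to <- res[e, 2L]
    node_of <- function(role) {
      if (role == spec$probe_from) {
        rep(x, nrow(grid))
      } else if (role == spec$probe_to) {
        rep(y, nrow(grid))
      } else {
        grid[, match(role, free)]
      }
    }
    ok <- ok & A[cbind(node_of(r_from), node_of(r_to))]
  }
  sum(ok)
}

#' Score a candidate link by neighbourhood counting
#'
#' Fast path returning exactly the same value as [score_link()], computed by
#' constraint propagation over adjacency lists: the probe arc pins two
#' pattern roles to the candidate endpoints, each free role's admissible
#' nodes are intersections of in/out neighbour lists of already-bound roles,
#' and the count is the number of injective completions. Worst-case cost is
#' bounded by the product of at most two adjacency-list sizes.
#'
#' @inheritParams score_link
#' @param .index Optional precomputed `adjacency_index(train)` to amortize
#'   over many candidates (used by [score_all()]).
#' @return Non-negative integer count.
#' @export
score_link_fast <- function(train, candidate, predictor, .index = NULL) {
  stopifnot(is_digraph(train))
  cand <- as_arc_tbl(candidate, "candidate")
  stopifnot(nrow(cand) == 1L)
  check_candidate(train, cand$from, cand$to)
  spec <- resolve_spec(predictor)
  idx <- .index %||% adjacency_index(train)
  score_link_fast_idx(idx, match(cand$from, idx$nodes), match(cand$to, idx$nodes), spec)
}

score_link_fast_idx <- function(idx, x, y, spec) {
  ord <- spec$order
  a <- spec$probe_from
  b <- spec$probe_to
  free <- setdiff(seq_len(ord), c(a, b))
  res <- spec$residual[[1L]]
  bound <- integer(ord)
  bound[a] <- x
  bound[b] <- y
  # admissible nodes for `role` given currently bound roles; NULL = unconstrained
  candidates_for <- function(role, bound) {
    cand <- NULL
    for (e in seq_len(nrow(res))) {
      rf <- res[e, 1L]
      rt <- res[e, 2L]
      if (rf == role && bound[rt] > 0L) {
        s <- idx$inc[[bound[rt]]] # need node -> bound[rt]
      } else if (rt == role && bound[rf] > 0L) {
        s <- idx$out[[bound[rf]]] # need bound[rf] -> node
      } else {
        next
      }
      cand <- if (is.null(cand)) s else intersect(cand, s)
      if (length(cand) == 0L) {
        return(integer())
      }
    }
    cand
  }
  if (length(free) == 1L) {
    cand <- candidates_for(free, bound)
    if (is.null(cand)) cand <- seq_len(idx$n)
    return(length(setdiff(cand, c(x, y))))
  }
  # two free roles: bind first the one with more constraints to bound roles
  n_bound_constraints <- function(role) {
    sum((res[, 1L] == role & bound[res[, 2L]] > 0L) |
      (res[, 2L] == role & bound[res[, 1L]] > 0L))
  }
  free <- free[order(-vapply(free, n_bound_constraints, 1L))]
  f1 <- free[1L]
  f2 <- free[2L]
  cand1 <- candidates_for(f1, bound)
  if (is.null(cand1)) cand1 <- seq_len(idx$n)
  cand1 <- setdiff(cand1, c(x, y))
  total <- 0L
  for (c1 in cand1) {
    bound[f1] <- c1
    cand2 <- candidates_for(f2, bound)
    if (is.null(cand2)) cand2 <- seq_len(idx$n)
    total <- total + length(setdiff(cand2, c(x, y, c1)))
    bound[f1] <- 0L
  }
  total
}

#' Hybrid predictor score
#'
#' Sum of the member predictors' scores; with all predictors of one parent
#' pattern this equals the total number of parent occurrences created by the
#' candidate (e.g. `c("S1","S2","S3")` counts all created 3-FFLs).
#'
#' @inheritParams score_link
#' @param predictors Character vector of predictor ids and/or parent pattern
#'   names (expanded to their members); must be non-empty.
#' @export
hybrid_score <- function(train, candidate, predictors) {
  if (length(predictors) == 0L) {
    abort("`predictors` must name at least one predictor.")
  }
  specs <- expand_predictors(predictors)
  idx <- adjacency_index(train)
  sum(vapply(
    seq_len(nrow(specs)),
    function(i) score_link_fast(train, candidate, specs[i, ], .index = idx),
    1L
  ))
}

#' Score a set of candidate links
#'
#' @param train A `digraph` of observed arcs.
#' @param predictors Predictor ids / parent names; multiple entries are
#'   summed (hybrid semantics).
#' @param candidates Data frame of candidate arcs (`from`, `to`) disjoint
#'   from the training arcs, or `NULL` for every non-observed ordered pair of
#'   training-graph nodes.
#' @param verbose Emit progress messages for large candidate sets.
#' @return A `score_table`: tibble with columns `from`, `to`, `score`,
#'   sorted by candidate, with the predictor set recorded in the
#'   `predictors` attribute.
#' @export
score_all <- function(train, predictors, candidates = NULL, verbose = FALSE) {
  stopifnot(is_digraph(train))
  specs <- expand_predictors(predictors)
  if (is.null(candidates)) {
    candidates <- non_observed_pairs(train)
  } else {
    candidates <- as_arc_tbl(candidates, "candidates")
  }
  seen <- arc_key(candidates$from, candidates$to) %in% arc_key(train$from, train$to)
  if (any(seen)) {
    abort(sprintf(
      "Candidates overlap observed arcs: %s",
      paste(sprintf("%s->%s", candidates$from[seen], candidates$to[seen])[
        seq_len(min(5L, sum(seen)))
      ], collapse = ", ")
    ))
  }
  candidates <- candidates[order(candidates$from, candidates$to, method = "radix"), ]
  idx <- adjacency_index(train)
  xi <- match(candidates$from, idx$nodes)
  yi <- match(candidates$to, idx$nodes)
  if (anyNA(xi) || anyNA(yi)) {
    abort("Candidate endpoints must belong to the training graph's node set.")
  }
  nc <- nrow(candidates)
  scores <- integer(nc)
  step <- max(1000L, nc %/% 10L)
  for (i in seq_len(nc)) {
    s <- 0L
    for (k in seq_len(nrow(specs))) {
      s <- s + score_link_fast_idx(idx, xi[i], yi[i], specs[k, ])
    }
    scores[i] <- s
    if (verbose && i %% step == 0L) {
      inform(sprintf("scored %d / %d candidates", i, nc))
    }
  }
  structure(
    tibble(from = candidates$from, to = candidates$to, score = scores),
    predictors = specs$id,
    class = c("score_table", class(tibble()))
  )
}

#' All non-observed ordered node pairs
#'
#' @param g A `digraph`.
#' @return Tibble of ordered pairs of distinct nodes not in `g`'s arc set.
#' @export
non_observed_pairs <- function(g) {
  nodes <- graph_nodes(g)
  all_pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  keep <- !(arc_key(all_pairs$from, all_pairs$to) %in% arc_key(g$from, g$to))
  out <- as_tibble(all_pairs[keep, ])
  out[order(out$from, out$to, method = "radix"), ]
}
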