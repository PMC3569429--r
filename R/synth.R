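# Seeded generators for synthetic directed networks and named fixtures.
# These stand in for sparse real directed networks at food-web scale
# (tens to hundreds of nodes) so the whole pipeline is testable offline.

node_labels <- function(n, prefix = "v") {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Uniform random simple digraph
#'
#' Samples exactly `n_arcs` arcs without replacement, uniformly over simple
#' digraphs of that size (no self-loops, no duplicates). With
#' `allow_reciprocal = FALSE`, unordered node pairs are sampled and each is
#' oriented at random, so no reciprocal pair can occur.
#'
#' @param n_nodes Number of nodes.
#' @param n_arcs Number of arcs; at most `n_nodes * (n_nodes - 1)`, halved
#'   when reciprocal pairs are disallowed.
#' @param allow_reciprocal May both `u -> v` and `v -> u` appear?
#' @param seed Integer seed; identical configurations give identical graphs.
#' @return A `digraph` on nodes `v1..vn`.
#' @export
random_digraph <- function(n_nodes, n_arcs, allow_reciprocal = TRUE, seed = NULL) {
  stopifnot(n_nodes >= 1L, n_arcs >= 0L)
  max_arcs <- if (allow_reciprocal) n_nodes * (n_nodes - 1L) else n_nodes * (n_nodes - 1L) / 2L
  if (n_arcs > max_arcs) {
    abort(sprintf("Infeasible density: at most %d arcs for %d nodes%s.",
      max_arcs, n_nodes, if (allow_reciprocal) "" else " without reciprocal pairs"))
  }
  nodes <- node_labels(n_nodes)
  if (n_arcs == 0L) {
    return(digraph(NULL, nodes = nodes))
  }
  arcs <- with_seed(seed, {
    if (allow_reciprocal) {
      k <- sample.int(n_nodes * (n_nodes - 1L), n_arcs)
      i <- (k - 1L) %/% (n_nodes - 1L) + 1L
      j <- (k - 1L) %% (n_nodes - 1L) + 1L
      j <- ifelse(j >= i, j + 1L, j) # skip the diagonal
      cbind(i, j)
    } else {
      prs <- utils::combn(n_nodes, 2L)
      k <- sample.int(ncol(prs), n_arcs)
      flip <- sample(c(TRUE, FALSE), n_arcs, replace = TRUE)
      i <- ifelse(flip, prs[2L, k], prs[1L, k])
      j <- ifelse(flip, prs[1L, k], prs[2L, k])
      cbind(i, j)
    }
  })
  digraph(tibble(from = nodes[arcs[, 1L]], to = nodes[arcs[, 2L]]), nodes = nodes)
}

#' Layered DAG (potential-definable by construction)
#'
#' Partitions nodes into `layers` contiguous, balanced layers and draws arcs
#' only from layer l+1 to layer l, so every arc drops exactly one level and
#' the graph is potential-definable with the layer index as its potential.
#' Density is controlled by `arc_probability` (independent inclusion of each
#' admissible arc) or by an exact `n_arcs`.
#'
#' @param n_nodes Number of nodes.
#' @param layers Number of layers (>= 2).
#' @param arc_probability Inclusion probability per admissible arc
#'   (default 1: complete inter-layer bipartite graphs).
#' @param n_arcs Exact arc count (overrides `arc_probability`).
#' @param seed Integer seed.
#' @return A `digraph`; node labels carry their layer (`l<layer>_<k>`).
#' @export
layered_dag <- function(n_nodes, layers, arc_probability = 1, n_arcs = NULL, seed = NULL) {
  stopifnot(n_nodes >= 2L)
  if (layers < 2L || layers > n_nodes) {
    abort("`layers` must satisfy 2 <= layers <= n_nodes.")
  }
  layer_of <- sort(rep_len(seq_len(layers), n_nodes))
  nodes <- sprintf("l%d_%02d", layer_of, stats::ave(layer_of, layer_of, FUN = seq_along))
  cand_from <- list()
  cand_to <- list()
  for (l in seq_len(layers - 1L)) {
    hi <- which(layer_of == l + 1L) # higher layer = higher potential
    lo <- which(layer_of == l)
    grid <- expand.grid(hi = hi, lo = lo)
    cand_from[[l]] <- grid$hi
    cand_to[[l]] <- grid$lo
  }
  cf <- unlist(cand_from)
  ct <- unlist(cand_to)
  keep <- with_seed(seed, {
    if (!is.null(n_arcs)) {
      if (n_arcs > length(cf)) {
        abort(sprintf("Infeasible density: at most %d inter-layer arcs.", length(cf)))
      }
      seq_along(cf) %in% sample.int(length(cf), n_arcs)
    } else {
      stopifnot(arc_probability > 0, arc_probability <= 1)
      runif(length(cf)) <= arc_probability
    }
  })
  digraph(tibble(from = nodes[cf[keep]], to = nodes[ct[keep]]), nodes = nodes)
}

#' Planted Bi-fan benchmark graph
#'
#' Bipartite source-to-sink digraph with independent arc inclusion; rich in
#' Bi-fan structure, free of directed cycles and of directed triangles. The
#' closed-form expected Bi-fan count
#' `choose(sources, 2) * choose(sinks, 2) * p^4` is attached as the
#' `expected_bifan_count` attribute.
#'
#' @param sources,sinks Part sizes (each >= 2).
#' @param arc_probability Inclusion probability `p` in (0, 1].
#' @param seed Integer seed.
#' @return A `digraph` with nodes `s1.., t1..`.
#' @export
planted_bifan_graph <- function(sources, sinks, arc_probability, seed = NULL) {
  if (sources < 2L || sinks < 2L) {
    abort("Need at least 2 sources and 2 sinks.")
  }
  stopifnot(arc_probability > 0, arc_probability <= 1)
  s_nodes <- node_labels(sources, "s")
  t_nodes <- node_labels(sinks, "t")
  grid <- expand.grid(from = s_nodes, to = t_nodes, stringsAsFactors = FALSE)
  keep <- with_seed(seed, runif(nrow(grid)) <= arc_probability)
  g <- digraph(grid[keep, ], nodes = c(s_nodes, t_nodes))
  attr(g, "expected_bifan_count") <-
    choose(sources, 2) * choose(sinks, 2) * arc_probability^4
  g
}

#' Named fixture graphs
#'
#' Small documented graphs used throughout the examples and tests: directed
#' paths (`"path_k"`), directed cycles (`"directed_cycle_k"`), a reciprocal
#' pair, and the six catalog patterns on nodes `a, b, c, d` in canonical
#' role order.
#'
#' @param name One of `"path_<k>"`, `"directed_cycle_<k>"`,
#'   `"reciprocal_pair"`, `"ffl"`, `"3-ffl"`, `"3-loop"`, `"bi-fan"`,
#'   `"bi-parallel"`, `"4-loop"`, `"4-ffl"`.
#' @return A `digraph`.
#' @export
fixture_graph <- function(name) {
  name <- tolower(name)
  letter <- function(i) letters[i]
  from_arcs <- function(arcs) {
    digraph(tibble(from = letter(arcs[, 1L]), to = letter(arcs[, 2L])))
  }
  refs <- reference_pattern_arcs()
  fixed <- list(
    "reciprocal_pair" = digraph(tibble(from = c("a", "b"), to = c("b", "a"))),
    "ffl" = from_arcs(refs[["3-FFL"]]),
    "3-ffl" = from_arcs(refs[["3-FFL"]]),
    "3-loop" = from_arcs(refs[["3-Loop"]]),
    "bi-fan" = from_arcs(refs[["Bi-fan"]]),
    "bi-parallel" = from_arcs(refs[["Bi-parallel"]]),
    "4-loop" = from_arcs(refs[["4-Loop"]]),
    "4-ffl" = from_arcs(refs[["4-FFL"]])
  )
  if (name %in% names(fixed)) {
    return(fixed[[name]])
  }
  m <- regmatches(name, regexec("^(path|directed_cycle)_(\\d+)$", name))[[1L]]
  if (length(m) == 3L) {
    k <- as.integer(m[3L])
    if (identical(m[2L], "path") && k >= 1L) {
      nodes <- node_labels(k + 1L, "p")
      return(digraph(tibble(from = nodes[-(k + 1L)], to = nodes[-1L])))
    }
    if (identical(m[2L], "directed_cycle") && k >= 2L) {
      nodes <- node_labels(k, "c")
      return(digraph(tibble(from = nodes, to = c(nodes[-1L], nodes[1L]))))
    }
  }
  abort(sprintf(
    "Unknown fixture '%s'. Available: %s, path_<k>, directed_cycle_<k>.",
    name, paste(names(fixed), collapse = ", ")
  ))
}
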