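#' Construct a simple directed graph
#'
#' A `digraph` is a tibble of arcs (columns `from`, `to`, character node
#' labels) carrying the full node universe in its `nodes` attribute, so that
#' isolated nodes survive operations such as train/probe splitting. The
#' constructor normalizes its input to a simple digraph: duplicate arcs are
#' collapsed and self-loops are dropped with a warning. Arc direction encodes
#' a unit potential drop from `from` to `to` under the potential-theory
#' reading; reciprocal arc pairs are legal in data (though no catalog pattern
#' contains one).
#'
#' @param edges A data frame whose first two columns (or columns named
#'   `from` and `to`) give the arcs, or `NULL` for an arc-free graph.
#' @param nodes Optional character vector of node labels to include in the
#'   node universe in addition to arc endpoints (e.g. isolated nodes).
#' @return A `digraph`: a tibble with columns `from` and `to`, arcs sorted
#'   lexicographically, with attribute `nodes` (sorted node labels).
#' @examples
#' g <- digraph(data.frame(from = c("a", "a", "b"), to = c("b", "b", "c")))
#' n_arcs(g) # duplicates collapse: 2
#' @export
digraph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    arcs <- tibble(from = character(), to = character())
  } else {
    arcs <- as_arc_tbl(edges, "edges")
  }
  endpoint_nodes <- unique(c(arcs$from, arcs$to)) # before normalization
  loops <- arcs$from == arcs$to
  if (any(loops)) {
    warn(sprintf(
      "Dropped %d self-loop(s); the method operates on loop-free simple digraphs.",
      sum(loops)
    ))
    arcs <- arcs[!loops, , drop = FALSE]
  }
  arcs <- distinct(arcs, .data$from, .data$to)
  ord <- order(arcs$from, arcs$to, method = "radix")
  arcs <- arcs[ord, , drop = FALSE]
  all_nodes <- sort_c(unique(c(as.character(nodes %||% character()), endpoint_nodes)))
  new_digraph(arcs, all_nodes)
}

new_digraph <- function(arcs, nodes) {
  structure(
    as_tibble(arcs),
    nodes = nodes,
    class = c("digraph", class(tibble()))
  )
}

#' @export
print.digraph <- function(x, ...) {
  cat(sprintf("# A digraph: %d nodes, %d arcs\n", n_nodes(x), n_arcs(x)))
  print(as_tibble(x)[seq_len(min(nrow(x), 10L)), ])
  if (nrow(x) > 10L) cat(sprintf("# ... with %d more arcs\n", nrow(x) - 10L))
  invisible(x)
}

#' Coerce to a digraph
#'
#' @param x A data frame of arcs or an existing `digraph`.
#' @param ... Passed to [digraph()].
#' @return A `digraph`.
#' @export
as_digraph <- function(x, ...) {
  if (is_digraph(x)) x else digraph(x, ...)
}

#' @rdname as_digraph
#' @export
is_digraph <- function(x) inherits(x, "digraph")

#' Node and arc accessors
#'
#' @param g A `digraph`.
#' @return `graph_nodes()` the character vector of node labels; `n_nodes()`
#'   and `n_arcs()` counts.
#' @export
graph_nodes <- function(g) {
  stopifnot(is_digraph(g))
  attr(g, "nodes")
}

#' @rdname graph_nodes
#' @export
n_nodes <- function(g) length(graph_nodes(g))

#' @rdname graph_nodes
#' @export
n_arcs <- function(g) nrow(g)

#' Does the graph contain a given arc?
#'
#' @param g A `digraph`.
#' @param from,to Node labels.
#' @return Logical vector.
#' @export
has_arc <- function(g, from, to) {
  arc_key(from, to) %in% arc_key(g$from, g$to)
}

# igraph view used for standard graph plumbing (components, distances, DAG
# checks); direction preserved, isolated nodes included.
as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g)[, c("from", "to")],
    directed = TRUE,
    vertices = graph_nodes(g)
  )
}

# integer adjacency index: nodes mapped to 1..n, out/in neighbour lists
adjacency_index <- function(g) {
  nodes <- graph_nodes(g)
  n <- length(nodes)
  fi <- match(g$from, nodes)
  ti <- match(g$to, nodes)
  lev <- seq_len(n)
  out <- unname(split(ti, factor(fi, levels = lev)))
  inc <- unname(split(fi, factor(ti, levels = lev)))
  list(nodes = nodes, n = n, from = fi, to = ti, out = out, inc = inc)
}

# dense logical adjacency matrix (brute-force oracle path; small graphs only)
dense_adjacency <- function(idx) {
  A <- matrix(FALSE, idx$n, idx$n)
  A[cbind(idx$from, idx$to)] <- TRUE
  A
}
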