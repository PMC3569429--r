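# Minimal loop-embedded pattern catalog and predictor derivation.
#
# Patterns are small digraphs on role indices 1..order. Under the generalized
# subgraph definition (any node subset together with any subset of the arcs
# among them), a pattern is minimal loop-embedded iff its underlying
# undirected graph contains a cycle while no proper generalized subgraph
# does; reciprocal arc pairs never count as loops and are barred from
# patterns. The six catalog members of orders 3 and 4 are exactly the
# reciprocal-free orientations of the full cycle on 3 or 4 nodes.

# canonical role labelings used throughout (documented S-label order):
#   3-FFL        1->2, 2->3, 1->3          (feed-forward loop)
#   3-Loop       1->2, 2->3, 3->1          (directed 3-cycle)
#   Bi-fan       1->3, 1->4, 2->3, 2->4    (two sources, two sinks)
#   Bi-parallel  1->2, 1->3, 2->4, 3->4    (two length-2 source-sink paths)
#   4-Loop       1->2, 2->3, 3->4, 4->1    (directed 4-cycle)
#   4-FFL        1->2, 2->3, 3->4, 1->4    (path plus source-sink chord)
reference_pattern_arcs <- function() {
  list(
    "3-FFL" = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)),
    "3-Loop" = rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L)),
    "Bi-fan" = rbind(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L)),
    "Bi-parallel" = rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L)),
    "4-Loop" = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
    "4-FFL" = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(1L, 4L))
  )
}

.catalog_cache <- new.env(parent = emptyenv())

# canonical form: minimum adjacency bit-string over all role permutations
canonical_key <- function(order, arcs) {
  perms <- permutations_of(order)
  best <- NULL
  for (p in perms) {
    A <- matrix(0L, order, order)
    if (nrow(arcs) > 0L) {
      A[cbind(p[arcs[, 1L]], p[arcs[, 2L]])] <- 1L
    }
    key <- paste(A, collapse = "")
    if (is.null(best) || key < best) best <- key
  }
  best
}

# automorphism group: permutations mapping the arc set onto itself
pattern_automorphisms <- function(order, arcs) {
  keys <- sort(arc_key(arcs[, 1L], arcs[, 2L]))
  Filter(
    function(p) identical(sort(arc_key(p[arcs[, 1L]], p[arcs[, 2L]])), keys),
    permutations_of(order)
  )
}

# does the underlying undirected (simple) graph contain a cycle? union-find
undirected_has_cycle <- function(order, arcs) {
  if (nrow(arcs) == 0L) {
    return(FALSE)
  }
  u <- pmin(arcs[, 1L], arcs[, 2L])
  v <- pmax(arcs[, 1L], arcs[, 2L])
  keep <- !duplicated(paste(u, v))
  u <- u[keep]
  v <- v[keep]
  parent <- seq_len(order)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (e in seq_along(u)) {
    ru <- find(u[e])
    rv <- find(v[e])
    if (ru == rv) {
      return(TRUE)
    }
    parent[ru] <- rv
  }
  FALSE
}

# minimal loop-embedded: cyclic, every node on the cycle structure (no node
# droppable), and no proper arc subset cyclic. Deleting arcs one at a time
# suffices: any proper cyclic arc subset stays cyclic inside some
# single-arc-deleted superset.
is_minimal_loop_embedded <- function(order, arcs) {
  if (!undirected_has_cycle(order, arcs)) {
    return(FALSE)
  }
  touched <- unique(c(arcs[, 1L], arcs[, 2L]))
  if (length(touched) < order) {
    return(FALSE) # dropping an isolated node leaves a loop-embedded proper subgraph
  }
  for (e in seq_len(nrow(arcs))) {
    if (undirected_has_cycle(order, arcs[-e, , drop = FALSE])) {
      return(FALSE)
    }
  }
  TRUE
}

new_pattern <- function(name, order, arcs) {
  structure(
    list(
      name = name,
      order = order,
      arcs = arcs,
      automorphisms = pattern_automorphisms(order, arcs),
      key = canonical_key(order, arcs)
    ),
    class = "pattern_graph"
  )
}

#' @export
print.pattern_graph <- function(x, ...) {
  cat(sprintf(
    "<pattern %s> order %d, arcs: %s, |Aut| = %d\n",
    x$name %||% "?", x$order,
    paste(sprintf("%d->%d", x$arcs[, 1L], x$arcs[, 2L]), collapse = ", "),
    length(x$automorphisms)
  ))
  invisible(x)
}

#' Enumerate minimal loop-embedded patterns of a given order
#'
#' Brute-force generation of all digraphs on `order` labeled nodes with no
#' self-loops and no reciprocal arc pairs, keeping those whose underlying
#' undirected graph contains a cycle and that are minimal under the
#' generalized subgraph relation (no proper node-subset/arc-subset is itself
#' loop-embedded), deduplicated by digraph isomorphism. Order 2 is permitted
#' to demonstrate emptiness (the only 2-node loop candidate is a reciprocal
#' pair, which does not count as a loop).
#'
#' @param order Pattern order, one of 2, 3, 4.
#' @return List of `pattern_graph` objects in deterministic canonical order:
#'   2 patterns for order 3 (3-FFL, 3-Loop), 4 for order 4 (Bi-fan,
#'   Bi-parallel, 4-Loop, 4-FFL).
#' @export
enumerate_minimal_loop_embedded <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || !(order %in% 2:4)) {
    abort("Unsupported order: patterns are enumerated for orders 2, 3 and 4 only.")
  }
  order <- as.integer(order)
  prs <- utils::combn(order, 2L)
  npair <- ncol(prs)
  # per unordered pair: 0 absent, 1 forward (i->j), 2 backward (j->i);
  # reciprocal pairs are unrepresentable, matching the no-2-loop rule
  states <- as.matrix(expand.grid(rep(list(0:2), npair)))
  found <- list()
  for (r in seq_len(nrow(states))) {
    st <- states[r, ]
    sel <- st != 0L
    if (sum(sel) < order) next # a full cycle needs `order` edges
    i <- prs[1L, sel]
    j <- prs[2L, sel]
    swap <- st[sel] == 2L
    arcs <- cbind(ifelse(swap, j, i), ifelse(swap, i, j))
    storage.mode(arcs) <- "integer"
    if (!is_minimal_loop_embedded(order, arcs)) next
    key <- canonical_key(order, arcs)
    if (is.null(found[[key]])) {
      found[[key]] <- arcs
    }
  }
  keys <- sort(names(found))
  out <- lapply(keys, function(k) {
    arcs <- found[[k]]
    p <- new_pattern(NA_character_, order, arcs)
    p$name <- classify_pattern(p)
    # re-express on the documented canonical role labeling for that name
    new_pattern(p$name, order, reference_pattern_arcs()[[p$name]])
  })
  # deterministic order: canonical catalog name order
  ref_names <- names(reference_pattern_arcs())
  out[order(match(vapply(out, `[[`, "", "name"), ref_names))]
}

#' The six-pattern catalog
#'
#' @return Named list of the six `pattern_graph` objects (orders 3 and 4) in
#'   canonical order: 3-FFL, 3-Loop, Bi-fan, Bi-parallel, 4-Loop, 4-FFL.
#' @export
catalog_patterns <- function() {
  if (is.null(.catalog_cache$patterns)) {
    pats <- c(enumerate_minimal_loop_embedded(3L), enumerate_minimal_loop_embedded(4L))
    names(pats) <- vapply(pats, `[[`, "", "name")
    ref_names <- names(reference_pattern_arcs())
    .catalog_cache$patterns <- pats[ref_names]
  }
  .catalog_cache$patterns
}

#' Classify a small digraph against the pattern catalog
#'
#' @param p A `pattern_graph`, a `digraph`, or a 2-column matrix of role-index
#'   arcs.
#' @return The canonical catalog name (matching by digraph isomorphism), or
#'   an error for non-catalog graphs.
#' @export
classify_pattern <- function(p) {
  if (is_digraph(p)) {
    idx <- adjacency_index(p)
    arcs <- cbind(idx$from, idx$to)
    order <- idx$n
  } else if (inherits(p, "pattern_graph")) {
    arcs <- p$arcs
    order <- p$order
  } else {
    arcs <- p
    order <- max(arcs)
  }
  if (!(order %in% 3:4)) {
    abort("Not a catalog pattern: order must be 3 or 4.")
  }
  key <- canonical_key(order, arcs)
  refs <- reference_pattern_arcs()
  for (nm in names(refs)) {
    if (nrow(refs[[nm]]) == nrow(arcs) && max(refs[[nm]]) <= order &&
      identical(canonical_key(order, refs[[nm]]), key)) {
      return(nm)
    }
  }
  abort("Not a catalog pattern: no isomorphic match among the six minimal loop-embedded subgraphs.")
}

#' Arc orbits of a pattern under its automorphism group
#'
#' Two removable arcs that an automorphism maps onto each other give the same
#' predictor, so predictors correspond to arc orbits. Representatives are the
#' lexicographically smallest (from, to) role pair of each orbit.
#'
#' @param p A `pattern_graph` or a catalog name.
#' @return A 2-column integer matrix, one representative arc per orbit, in
#'   canonical order.
#' @export
link_orbits <- function(p) {
  if (is.character(p)) p <- catalog_patterns()[[match.arg(p, names(catalog_patterns()))]]
  stopifnot(inherits(p, "pattern_graph"))
  arcs <- p$arcs
  keys <- arc_key(arcs[, 1L], arcs[, 2L])
  orbit_of <- rep(NA_integer_, nrow(arcs))
  n_orb <- 0L
  for (e in seq_len(nrow(arcs))) {
    if (!is.na(orbit_of[e])) next
    n_orb <- n_orb + 1L
    for (perm in p$automorphisms) {
      img <- arc_key(perm[arcs[e, 1L]], perm[arcs[e, 2L]])
      orbit_of[match(img, keys)] <- n_orb
    }
  }
  reps <- vapply(seq_len(n_orb), function(k) {
    members <- which(orbit_of == k)
    members[order(arcs[members, 1L], arcs[members, 2L])][1L]
  }, 1L)
  reps <- reps[order(arcs[reps, 1L], arcs[reps, 2L])]
  arcs[reps, , drop = FALSE]
}

#' Derive the twelve link predictors
#'
#' Removing one arc (up to automorphism) from each of the six catalog
#' patterns yields twelve predictors S1--S12, grouped by parent pattern as
#' 3-FFL: S1--S3, 3-Loop: S4, Bi-fan: S5, Bi-parallel: S6--S7, 4-Loop: S8,
#' 4-FFL: S9--S12. Within a parent, labels follow the lexicographic order of
#' the removed arc in the documented canonical role labeling.
#'
#' @return A tibble with one row per predictor: `id`, `parent`, `order`,
#'   `probe_from`/`probe_to` (role indices of the removed arc) and `residual`
#'   (list column of the remaining role arcs). For every predictor the
#'   automorphism subgroup of the parent fixing the probe arc is trivial
#'   (asserted at build time), so occurrence counting reduces to counting
#'   distinct assignments of the free roles.
#' @export
derive_predictors <- function() {
  if (!is.null(.catalog_cache$predictors)) {
    return(.catalog_cache$predictors)
  }
  pats <- catalog_patterns()
  rows <- list()
  for (pat in pats) {
    orbits <- link_orbits(pat)
    for (k in seq_len(nrow(orbits))) {
      probe <- orbits[k, ]
      # stabilizer of the probe arc must be trivial for plain counting
      stab <- Filter(
        function(perm) perm[probe[1L]] == probe[1L] && perm[probe[2L]] == probe[2L],
        pat$automorphisms
      )
      stopifnot(length(stab) == 1L)
      keep <- !(pat$arcs[, 1L] == probe[1L] & pat$arcs[, 2L] == probe[2L])
      rows[[length(rows) + 1L]] <- tibble(
        parent = pat$name,
        order = pat$order,
        probe_from = probe[1L],
        probe_to = probe[2L],
        residual = list(pat$arcs[keep, , drop = FALSE])
      )
    }
  }
  out <- bind_rows(rows)
  out <- tibble(id = paste0("S", seq_len(nrow(out))), out)
  .catalog_cache$predictors <- out
  out
}

# resolve predictor ids / parent-pattern names to rows of derive_predictors()
expand_predictors <- function(ids) {
  specs <- derive_predictors()
  ids <- as.character(ids)
  out <- character()
  for (x in ids) {
    if (x %in% specs$id) {
      out <- c(out, x)
    } else if (x %in% specs$parent) {
      out <- c(out, specs$id[specs$parent == x])
    } else {
      abort(sprintf(
        "Unknown predictor '%s'; use S1..S12 or a parent pattern name (%s).",
        x, paste(unique(specs$parent), collapse = ", ")
      ))
    }
  }
  specs[match(unique(out), specs$id), , drop = FALSE]
}
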