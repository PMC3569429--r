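# catalog enumeration, classification, orbits, predictor derivation

test_that("enumeration finds exactly the known minimal loop-embedded patterns", {
  expect_length(enumerate_minimal_loop_embedded(2), 0L) # reciprocal pairs are not loops

  p3 <- enumerate_minimal_loop_embedded(3)
  expect_length(p3, 2L)
  expect_setequal(vapply(p3, `[[`, "", "name"), c("3-FFL", "3-Loop"))

  p4 <- enumerate_minimal_loop_embedded(4)
  expect_length(p4, 4L)
  expect_setequal(
    vapply(p4, `[[`, "", "name"),
    c("Bi-fan", "Bi-parallel", "4-Loop", "4-FFL")
  )

  expect_error(enumerate_minimal_loop_embedded(5), "[Uu]nsupported")
})

test_that("catalog equals reciprocal-free cycle orientations up to isomorphism", {
  # independent oracle: orient each edge of the undirected n-cycle both ways,
  # deduplicate under rotation/reflection composed with the orientations
  cycle_orientation_keys <- function(n) {
    ring <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
    keys <- character()
    for (mask in 0:(2^n - 1)) {
      dirs <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L
      arcs <- ring
      arcs[dirs, ] <- arcs[dirs, c(2L, 1L), drop = FALSE]
      keys <- c(keys, potentialnet:::canonical_key(n, arcs))
    }
    unique(keys)
  }
  for (n in 3:4) {
    found <- vapply(enumerate_minimal_loop_embedded(n), `[[`, "", "key")
    expect_setequal(found, cycle_orientation_keys(n))
  }
})

test_that("patterns are reciprocal-free single cycles with consistent automorphisms", {
  for (p in catalog_patterns()) {
    arcs <- p$arcs
    # no reciprocal role pair
    expect_false(any(paste(arcs[, 1], arcs[, 2]) %in% paste(arcs[, 2], arcs[, 1])))
    # underlying undirected graph is one cycle through all roles
    deg <- tabulate(c(arcs[, 1], arcs[, 2]), p$order)
    expect_true(all(deg == 2L))
    expect_equal(nrow(arcs), p$order)
    # automorphisms map the arc set onto itself
    for (perm in p$automorphisms) {
      expect_setequal(
        paste(perm[arcs[, 1]], perm[arcs[, 2]]),
        paste(arcs[, 1], arcs[, 2])
      )
    }
  }
})

test_that("no catalog pattern contains a loop-embedded proper generalized subgraph", {
  # exhaustive node-subset x arc-subset search, independent of the
  # single-deletion rule used inside the enumerator
  for (p in catalog_patterns()) {
    arcs <- p$arcs
    m <- nrow(arcs)
    for (vmask in 1:(2^p$order - 1)) {
      vs <- which(bitwAnd(vmask, 2^(seq_len(p$order) - 1L)) > 0L)
      inside <- arcs[, 1] %in% vs & arcs[, 2] %in% vs
      sub_arcs <- which(inside)
      for (emask in 0:(2^length(sub_arcs) - 1)) {
        chosen <- sub_arcs[bitwAnd(emask, 2^(seq_along(sub_arcs) - 1L)) > 0L]
        proper <- !(length(vs) == p$order && length(chosen) == m)
        if (!proper) next
        expect_false(
          potentialnet:::undirected_has_cycle(p$order, arcs[chosen, , drop = FALSE]),
          info = sprintf("%s vmask=%d emask=%d", p$name, vmask, emask)
        )
      }
    }
  }
})

test_that("classification matches by isomorphism and rejects non-members", {
  expect_equal(classify_pattern(rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))), "3-FFL")
  expect_equal(
    classify_pattern(rbind(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))),
    "Bi-fan"
  )
  expect_equal(
    classify_pattern(rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L))),
    "4-Loop"
  )
  # relabeled digraph input
  expect_equal(classify_pattern(fixture_graph("directed_cycle_3")), "3-Loop")
  expect_error(
    classify_pattern(rbind(c(1L, 2L), c(2L, 3L))),
    "[Nn]ot a catalog pattern"
  )
})

test_that("arc orbits give the documented predictor multiplicities", {
  counts <- vapply(catalog_patterns(), function(p) nrow(link_orbits(p)), 1L)
  expect_equal(
    unname(counts[c("3-FFL", "3-Loop", "Bi-fan", "Bi-parallel", "4-Loop", "4-FFL")]),
    c(3L, 1L, 1L, 2L, 1L, 4L)
  )
  expect_equal(sum(counts), 12L)
})

test_that("the twelve predictors carry consistent metadata", {
  preds <- derive_predictors()
  expect_equal(preds$id, paste0("S", 1:12))
  expect_equal(
    unname(table(preds$parent)[c("3-FFL", "3-Loop", "Bi-fan", "Bi-parallel", "4-Loop", "4-FFL")]),
    as.table(c(3L, 1L, 1L, 2L, 1L, 4L)),
    ignore_attr = TRUE
  )
  expect_equal(preds$parent[preds$id == "S5"], "Bi-fan")
  pats <- catalog_patterns()
  for (i in seq_len(nrow(preds))) {
    p <- pats[[preds$parent[i]]]
    # probe arc belongs to the parent; residual = parent arcs minus probe
    expect_true(any(p$arcs[, 1] == preds$probe_from[i] & p$arcs[, 2] == preds$probe_to[i]))
    expect_equal(nrow(preds$residual[[i]]), nrow(p$arcs) - 1L)
    # no parent automorphism maps one probe arc to another (specs inequivalent)
    siblings <- which(preds$parent == preds$parent[i])
    for (j in setdiff(siblings, i)) {
      mapped <- vapply(p$automorphisms, function(perm) {
        perm[preds$probe_from[i]] == preds$probe_from[j] &&
          perm[preds$probe_to[i]] == preds$probe_to[j]
      }, TRUE)
      expect_false(any(mapped))
    }
  }
})

test_that("exactly Bi-fan and Bi-parallel are potential-definable, with 2 and 3 levels", {
  defin <- vapply(
    catalog_patterns(),
    function(p) {
      g <- digraph(data.frame(
        from = letters[p$arcs[, 1]],
        to = letters[p$arcs[, 2]]
      ))
      is_potential_definable(g)
    },
    TRUE
  )
  expect_equal(
    defin,
    c("3-FFL" = FALSE, "3-Loop" = FALSE, "Bi-fan" = TRUE,
      "Bi-parallel" = TRUE, "4-Loop" = FALSE, "4-FFL" = FALSE)
  )
  expect_lt(
    potential_level_count(fixture_graph("bi-fan")),
    potential_level_count(fixture_graph("bi-parallel"))
  )
})

test_that("predictor groupings expand from parent names", {
  ffl <- potentialnet:::expand_predictors("3-FFL")
  expect_equal(ffl$id, c("S1", "S2", "S3"))
  mixed <- potentialnet:::expand_predictors(c("Bi-fan", "S4"))
  expect_equal(mixed$id, c("S5", "S4"))
  expect_error(potentialnet:::expand_predictors("S13"), "Unknown predictor")
})
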