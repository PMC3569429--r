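# subgraph-completion scoring: brute force, fast path, hybrids, tables

test_that("worked Bi-fan completions score correctly", {
  tr <- digraph(data.frame(from = c("x", "u", "u"), to = c("v", "y", "v")))
  expect_equal(score_link(tr, c("x", "y"), "S5"), 1L)
  expect_equal(score_link_fast(tr, c("x", "y"), "S5"), 1L)

  tr2 <- digraph(data.frame(
    from = c("x", "u", "u", "x", "u"),
    to = c("v", "y", "v", "w", "w")
  ))
  expect_equal(score_link(tr2, c("x", "y"), "S5"), 2L) # second sink w
  expect_equal(score_link_fast(tr2, c("x", "y"), "S5"), 2L)

  empty <- digraph(NULL, nodes = c("a", "b", "c", "d"))
  for (id in paste0("S", 1:12)) {
    expect_equal(score_link_fast(empty, c("a", "b"), id), 0L)
  }
})

test_that("a path plus its chord is exactly one 4-FFL and no Bi-fan", {
  path <- fixture_graph("path_3") # p1 -> p2 -> p3 -> p4
  preds <- derive_predictors()
  chord <- preds[preds$parent == "4-FFL" &
    preds$probe_from == 1L & preds$probe_to == 4L, ]
  expect_equal(score_link_fast(path, c("p1", "p4"), chord), 1L)
  expect_equal(score_link(path, c("p1", "p4"), chord), 1L)
  expect_equal(score_link_fast(path, c("p1", "p4"), "S5"), 0L)
})

test_that("candidate validation rejects observed arcs and self-loops", {
  tr <- fixture_graph("path_3")
  expect_error(score_link_fast(tr, c("p1", "p2"), "S5"), "already an observed arc")
  expect_error(score_link_fast(tr, c("p1", "p1"), "S5"), "self-loop")
  expect_error(score_link_fast(tr, c("p1", "nope"), "S5"), "node set")
})

test_that("fast scoring equals the brute-force oracle across predictors and graphs", {
  preds <- derive_predictors()
  set.seed(99)
  for (k in 1:25) {
    n <- sample(8:16, 1)
    dens <- runif(1, 0.05, 0.4)
    g <- random_digraph(n, round(dens * n * (n - 1)), seed = 400 + k)
    cands <- non_observed_pairs(g)
    pick <- cands[sample.int(nrow(cands), 2L), ]
    for (ci in 1:2) {
      cand <- c(pick$from[ci], pick$to[ci])
      for (i in seq_len(nrow(preds))) {
        spec <- preds[i, ]
        f <- score_link_fast(g, cand, spec)
        expect_equal(f, score_link(g, cand, spec),
          info = sprintf("graph %d cand %s->%s %s", k, cand[1], cand[2], spec$id)
        )
        expect_equal(f, oracle_score(g, cand, spec),
          info = sprintf("oracle graph %d %s", k, spec$id)
        )
      }
    }
  }
})

test_that("scores are monotone under arc addition and invariant to relabeling", {
  preds <- derive_predictors()
  for (k in 1:6) {
    g <- random_digraph(12, 30, seed = 600 + k)
    cands <- non_observed_pairs(g)
    set.seed(k)
    cand <- unlist(cands[sample.int(nrow(cands), 1L), ])
    extra <- cands[sample.int(nrow(cands), 4L), ]
    extra <- extra[!(extra$from == cand[1] & extra$to == cand[2]), ]
    g_plus <- digraph(rbind(as.data.frame(g), as.data.frame(extra)),
      nodes = graph_nodes(g)
    )
    perm <- setNames(sprintf("w%02d", sample(n_nodes(g))), graph_nodes(g))
    g_perm <- digraph(
      data.frame(from = unname(perm[g$from]), to = unname(perm[g$to])),
      nodes = unname(perm)
    )
    for (id in c("S1", "S4", "S5", "S7", "S8", "S11")) {
      base <- score_link_fast(g, cand, id)
      expect_gte(score_link_fast(g_plus, cand, id), base)
      expect_equal(
        score_link_fast(g_perm, unname(perm[cand]), id),
        base
      )
    }
  }
})

test_that("reverse arcs in the training set do not alter a candidate's score", {
  g <- random_digraph(10, 20, allow_reciprocal = FALSE, seed = 77)
  cands <- non_observed_pairs(g)
  # a candidate whose reverse arc we can add without touching the candidate
  cand <- NULL
  for (i in seq_len(nrow(cands))) {
    if (!has_arc(g, cands$to[i], cands$from[i])) {
      cand <- c(cands$from[i], cands$to[i])
      break
    }
  }
  g_rev <- digraph(
    rbind(as.data.frame(g), data.frame(from = cand[2], to = cand[1])),
    nodes = graph_nodes(g)
  )
  for (id in c("S2", "S5", "S6")) {
    expect_equal(
      score_link_fast(g_rev, cand, id),
      score_link_fast(g, cand, id)
    )
  }
})

test_that("hybrid scores are sums of members and count whole parent patterns", {
  g <- random_digraph(12, 35, seed = 8)
  cands <- non_observed_pairs(g)
  set.seed(8)
  cand <- unlist(cands[sample.int(nrow(cands), 1L), ])
  s123 <- vapply(c("S1", "S2", "S3"), function(id) score_link_fast(g, cand, id), 1L)
  expect_equal(hybrid_score(g, cand, c("S1", "S2", "S3")), sum(s123))
  expect_equal(hybrid_score(g, cand, "3-FFL"), sum(s123))
  expect_equal(hybrid_score(g, cand, "S5"), score_link_fast(g, cand, "S5"))
  expect_error(hybrid_score(g, cand, character()), "at least one")

  # the 3-FFL hybrid equals the count of 3-FFLs created by the addition
  pats <- catalog_patterns()
  g_plus <- digraph(rbind(as.data.frame(g), data.frame(from = cand[1], to = cand[2])),
    nodes = graph_nodes(g)
  )
  created <- oracle_count_occurrences(g_plus, pats[["3-FFL"]]) -
    oracle_count_occurrences(g, pats[["3-FFL"]])
  expect_equal(hybrid_score(g, cand, "3-FFL"), created)
})

test_that("score_all covers the candidate universe consistently", {
  g <- random_digraph(5, 8, seed = 4)
  tbl <- score_all(g, "S5")
  expect_equal(nrow(tbl), 5L * 4L - n_arcs(g))
  expect_true(all(tbl$score >= 0))
  # element-wise consistency
  for (i in sample.int(nrow(tbl), 5L)) {
    expect_equal(
      tbl$score[i],
      score_link_fast(g, c(tbl$from[i], tbl$to[i]), "S5")
    )
  }
  # empty training graph scores everything 0
  empty <- digraph(NULL, nodes = letters[1:5])
  tbl0 <- score_all(empty, "S8")
  expect_true(all(tbl0$score == 0L))
  # overlap with observed arcs errors
  expect_error(
    score_all(g, "S5", candidates = as.data.frame(g)[1, ]),
    "overlap"
  )
})
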