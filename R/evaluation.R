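# Train/probe splitting, AUC computation, repeated-experiment protocol.

#' Random train/probe split of the observed arcs
#'
#' Holds out a uniform random sample of the arcs as the probe (testing) set;
#' the probe size is round-half-up of `(1 - train_fraction) * n_arcs`. Nodes
#' isolated by the removal stay in the training graph so the candidate
#' universe is unchanged.
#'
#' @param g A `digraph` with at least 10 arcs.
#' @param train_fraction Fraction of arcs kept for training (default 0.9).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return List with elements `train` (a `digraph`) and `probe` (tibble of
#'   held-out arcs).
#' @export
split_arcs <- function(g, train_fraction = 0.9, seed = NULL) {
  stopifnot(is_digraph(g))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  m <- n_arcs(g)
  if (m < 10L) {
    abort("Need at least 10 arcs to split.")
  }
  n_probe <- floor((1 - train_fraction) * m + 0.5)
  if (n_probe < 1L) {
    abort("Probe set would be empty after rounding; lower `train_fraction`.")
  }
  probe_rows <- with_seed(seed, sample.int(m, n_probe))
  probe <- as_tibble(g[probe_rows, c("from", "to")])
  probe <- probe[order(probe$from, probe$to, method = "radix"), ]
  train <- new_digraph(g[-probe_rows, c("from", "to")], graph_nodes(g))
  list(train = train, probe = probe)
}

new_auc_result <- function(n, n_higher, n_equal, method) {
  structure(
    tibble(
      n = as.numeric(n),
      n_higher = as.numeric(n_higher),
      n_equal = as.numeric(n_equal),
      auc = (n_higher + 0.5 * n_equal) / n,
      method = method
    ),
    class = c("auc_result", class(tibble()))
  )
}

#' AUC from comparison counts
#'
#' AUC = (n' + 0.5 n'') / n where among `n` missing-vs-nonexistent score
#' comparisons the missing link scored strictly higher `n'` times and tied
#' `n''` times.
#'
#' @param n Total comparisons (> 0).
#' @param n_higher,n_equal Counts with `n_higher + n_equal <= n`.
#' @return An `auc_result` (one-row tibble: `n`, `n_higher`, `n_equal`,
#'   `auc`, `method`).
#' @export
auc_from_counts <- function(n, n_higher, n_equal) {
  if (!(n > 0)) {
    abort("`n` must be positive.")
  }
  if (n_higher < 0 || n_equal < 0 || n_higher + n_equal > n) {
    abort("Counts must satisfy 0 <= n_higher + n_equal <= n.")
  }
  new_auc_result(n, n_higher, n_equal, "counts")
}

# look up candidate scores in a score table; error on unscored arcs
lookup_scores <- function(scores, arcs, arg) {
  arcs <- as_arc_tbl(arcs, arg)
  i <- match(arc_key(arcs$from, arcs$to), arc_key(scores$from, scores$to))
  if (anyNA(i)) {
    miss <- which(is.na(i))[1L]
    abort(sprintf(
      "Unscored arc in `%s`: %s -> %s is missing from the score table.",
      arg, arcs$from[miss], arcs$to[miss]
    ))
  }
  scores$score[i]
}

#' Exact AUC over all probe-by-nonexistent pairs
#'
#' Deterministic evaluation of the comparison probability over every
#' (missing, nonexistent) pair, computed from midrank-style counts; `n` is
#' the full product `|probe| * |nonexistent|`.
#'
#' @param scores A score table (tibble `from`, `to`, `score`) covering both
#'   arc sets.
#' @param probe,nonexistent Data frames of arcs (disjoint, non-empty).
#' @return An `auc_result`.
#' @export
auc_exact <- function(scores, probe, nonexistent) {
  sp <- lookup_scores(scores, probe, "probe")
  sq <- lookup_scores(scores, nonexistent, "nonexistent")
  if (length(sp) == 0L || length(sq) == 0L) {
    abort("`probe` and `nonexistent` must be non-empty.")
  }
  qs <- sort(sq)
  n_leq <- findInterval(sp, qs)
  n_lt <- findInterval(sp, qs, left.open = TRUE)
  new_auc_result(
    n = length(sp) * length(sq),
    n_higher = sum(n_lt),
    n_equal = sum(n_leq - n_lt),
    method = "exact"
  )
}

#' Sampled AUC
#'
#' Monte-Carlo estimate: `n_comparisons` independent uniform draws of one
#' missing and one nonexistent link, tallied with ties worth one half.
#'
#' @inheritParams auc_exact
#' @param n_comparisons Number of independent comparisons.
#' @param seed Integer seed for reproducible sampling.
#' @return An `auc_result`.
#' @export
auc_sampled <- function(scores, probe, nonexistent, n_comparisons = 10000L, seed = NULL) {
  sp <- lookup_scores(scores, probe, "probe")
  sq <- lookup_scores(scores, nonexistent, "nonexistent")
  if (length(sp) == 0L || length(sq) == 0L) {
    abort("`probe` and `nonexistent` must be non-empty.")
  }
  stopifnot(n_comparisons >= 1L)
  draws <- with_seed(seed, {
    cbind(
      sample.int(length(sp), n_comparisons, replace = TRUE),
      sample.int(length(sq), n_comparisons, replace = TRUE)
    )
  })
  a <- sp[draws[, 1L]]
  b <- sq[draws[, 2L]]
  new_auc_result(
    n = n_comparisons,
    n_higher = sum(a > b),
    n_equal = sum(a == b),
    method = "sampled"
  )
}

# uniform sample (or full enumeration) of nonexistent links of the full graph
nonexistent_arcs <- function(g, exclude = NULL, sample_size = NULL, seed = NULL) {
  universe <- non_observed_pairs(g)
  if (!is.null(exclude)) {
    ex <- as_arc_tbl(exclude, "exclude")
    universe <- universe[!(arc_key(universe$from, universe$to) %in%
      arc_key(ex$from, ex$to)), ]
  }
  if (!is.null(sample_size) && sample_size < nrow(universe)) {
    rows <- with_seed(seed, sample.int(nrow(universe), sample_size))
    universe <- universe[sort(rows), ]
  }
  universe
}

#' Repeated link-prediction experiment
#'
#' Runs the full evaluation protocol: for each repetition the observed arcs
#' are randomly partitioned into training and probe sets (seeds
#' `base_seed + 1 .. base_seed + repetitions`), every candidate (probe plus
#' nonexistent links) is scored on the training graph with each predictor
#' set, and the AUC is computed — exactly over all probe-by-nonexistent
#' pairs whenever that product fits `exact_budget`, otherwise by
#' `sample_comparisons` sampled comparisons. Means and standard deviations
#' per predictor set are reported.
#'
#' @param g A `digraph` (the full observed network).
#' @param predictor_sets List of character vectors of predictor ids / parent
#'   names; each element is evaluated as one (possibly hybrid) predictor.
#'   Unnamed elements are labeled by their ids joined with `+`.
#' @param repetitions Number of independent partitions (the reference
#'   protocol uses 50).
#' @param base_seed Integer; all randomness derives from it.
#' @param train_fraction Training fraction per split (default 0.9).
#' @param nonexistent_sample `"all"` to enumerate every nonexistent link, or
#'   an integer cap; `NULL` (default) enumerates all when the universe has at
#'   most 20000 arcs and otherwise samples `10 * |probe|`.
#' @param exact_budget Use exact AUC while `|probe| * |nonexistent|` is at
#'   most this (default 1e7).
#' @param sample_comparisons Comparisons for the sampled fallback.
#' @param verbose Progress messages.
#' @return A `link_experiment`: tibble with one row per predictor set
#'   (`predictor`, `mean_auc`, `sd_auc`, `n_reps`), with the per-repetition
#'   results available via [tidy()] and run metadata via [glance()].
#' @export
run_experiment <- function(g, predictor_sets = list("S5"), repetitions = 50L,
                           base_seed = 1L, train_fraction = 0.9,
                           nonexistent_sample = NULL, exact_budget = 1e7,
                           sample_comparisons = 1e5, verbose = FALSE) {
  stopifnot(is_digraph(g), repetitions >= 1L)
  if (!is.list(predictor_sets)) predictor_sets <- as.list(predictor_sets)
  labels <- names(predictor_sets) %||% rep("", length(predictor_sets))
  labels <- vapply(seq_along(predictor_sets), function(i) {
    if (nzchar(labels[i])) labels[i] else paste(expand_predictors(predictor_sets[[i]])$id, collapse = "+")
  }, "")
  runs <- list()
  for (r in seq_len(repetitions)) {
    seed_r <- base_seed + r
    sp <- split_arcs(g, train_fraction, seed = seed_r)
    n_probe <- nrow(sp$probe)
    universe_size <- n_nodes(g) * (n_nodes(g) - 1L) - n_arcs(g)
    size <- if (identical(nonexistent_sample, "all")) {
      NULL
    } else if (is.null(nonexistent_sample)) {
      if (universe_size <= 20000L) NULL else 10L * n_probe
    } else {
      as.integer(nonexistent_sample)
    }
    ne <- nonexistent_arcs(g, sample_size = size, seed = seed_r + 100003L)
    cands <- bind_rows(sp$probe, ne)
    for (i in seq_along(predictor_sets)) {
      st <- score_all(sp$train, predictor_sets[[i]], candidates = cands)
      res <- if (n_probe * nrow(ne) <= exact_budget) {
        auc_exact(st, sp$probe, ne)
      } else {
        auc_sampled(st, sp$probe, ne,
          n_comparisons = sample_comparisons,
          seed = seed_r + 200003L
        )
      }
      runs[[length(runs) + 1L]] <- tibble(
        rep = r, seed = seed_r, predictor = labels[i],
        n_probe = n_probe, n_nonexistent = nrow(ne),
        n = res$n, n_higher = res$n_higher, n_equal = res$n_equal,
        auc = res$auc, method = res$method
      )
    }
    if (verbose) inform(sprintf("repetition %d / %d done", r, repetitions))
  }
  runs <- bind_rows(runs)
  summary_tbl <- runs |>
    group_by(.data$predictor) |>
    summarise(
      mean_auc = mean(.data$auc),
      sd_auc = if (dplyr::n() > 1L) sd(.data$auc) else NA_real_,
      n_reps = dplyr::n(),
      .groups = "drop"
    )
  summary_tbl <- summary_tbl[match(unique(labels), summary_tbl$predictor), ]
  structure(
    summary_tbl,
    runs = runs,
    base_seed = base_seed,
    train_fraction = train_fraction,
    class = c("link_experiment", class(tibble()))
  )
}
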