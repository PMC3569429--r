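# broom-style accessors for fitted objects

#' Tidy a potential assignment
#'
#' @param x A `potential_fit` from [assign_potentials()].
#' @param ... Unused.
#' @return Tibble with one row per node: `node`, `component`, `potential`
#'   (`NA` when the graph is not potential-definable).
#' @method tidy potential_fit
#' @export
tidy.potential_fit <- function(x, ...) {
  nodes <- names(x$components)
  tibble(
    node = nodes,
    component = unname(x$components),
    potential = if (x$definable) unname(x$potentials[nodes]) else NA_integer_
  )
}

#' @rdname tidy.potential_fit
#' @return `glance()`: one-row tibble with `definable`, `n_levels`,
#'   `n_components`, `n_nodes`, `n_arcs`.
#' @method glance potential_fit
#' @export
glance.potential_fit <- function(x, ...) {
  tibble(
    definable = x$definable,
    n_levels = if (x$definable) potential_level_count(x) else NA_integer_,
    n_components = max(x$components),
    n_nodes = x$n_nodes,
    n_arcs = x$n_arcs
  )
}

#' Tidy a link-prediction experiment
#'
#' @param x A `link_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return Per-repetition results: `rep`, `seed`, `predictor`, `n_probe`,
#'   `n_nonexistent`, comparison counts, `auc`, `method`.
#' @method tidy link_experiment
#' @export
tidy.link_experiment <- function(x, ...) {
  attr(x, "runs")
}

#' @rdname tidy.link_experiment
#' @return `glance()`: one-row tibble with protocol metadata and the best
#'   predictor by mean AUC.
#' @method glance link_experiment
#' @export
glance.link_experiment <- function(x, ...) {
  best <- which.max(x$mean_auc)
  tibble(
    n_predictors = nrow(x),
    n_reps = x$n_reps[1L],
    train_fraction = attr(x, "train_fraction"),
    base_seed = attr(x, "base_seed"),
    best_predictor = x$predictor[best],
    best_mean_auc = x$mean_auc[best]
  )
}
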