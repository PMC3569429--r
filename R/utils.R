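# internal helpers shared across modules

# run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# locale-independent sort for node labels; "\r" never occurs in labels
sort_c <- function(x) sort(x, method = "radix")

arc_key <- function(from, to) paste(from, to, sep = "\r")

# coerce a data frame / 2-column object to a from,to character tibble
as_arc_tbl <- function(x, arg = "arcs") {
  if (is.character(x) && length(x) == 2L) {
    return(tibble(from = x[[1L]], to = x[[2L]]))
  }
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort(sprintf("`%s` must be a data frame with columns `from` and `to`.", arg))
  }
  nm <- names(x)
  if (all(c("from", "to") %in% nm)) {
    tibble(from = as.character(x[["from"]]), to = as.character(x[["to"]]))
  } else {
    tibble(from = as.character(x[[1L]]), to = as.character(x[[2L]]))
  }
}

# all permutations of 1..n as a list of integer vectors (n <= 4 in practice)
permutations_of <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
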