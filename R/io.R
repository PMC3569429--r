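#' Read a directed edge list
#'
#' Parses a plain-text edge list with one arc per line,
#' `"source<whitespace>target"`; extra tokens (e.g. weights) are ignored
#' because the method is purely topological. Lines starting with the comment
#' prefix and blank lines are skipped. The result is normalized: duplicate
#' arcs collapse and self-loops are dropped with a warning.
#'
#' @param path Path to a UTF-8 text file.
#' @param comment_prefix Lines starting with this character are skipped.
#' @return A [digraph()].
#' @export
read_edgelist <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl(paste0("^\\s*", comment_prefix), lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    abort(sprintf("Empty graph: no arc lines in %s", path))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed line %d in %s: expected at least 2 whitespace-separated tokens.",
      idx[bad[1L]], path
    ))
  }
  digraph(tibble(
    from = vapply(toks, `[[`, "", 1L),
    to = vapply(toks, `[[`, "", 2L)
  ))
}

#' Write a digraph as an edge list
#'
#' @param g A `digraph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(is_digraph(g))
  writeLines(paste(g$from, g$to), path)
  invisible(path)
}

#' Read a Pajek .net file
#'
#' Supports the `*Vertices`, `*Arcs` and `*Edges` sections (1-based vertex
#' indices). `*Arcs` lines become single directed arcs; `*Edges` lines are
#' undirected and expand to two reciprocal arcs. Quoted vertex labels are
#' preserved; unlabeled vertices are named by their index.
#'
#' @param path Path to a Pajek `.net` file.
#' @return A [digraph()] containing every declared vertex (including
#'   isolated ones).
#' @export
read_pajek <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  sec <- tolower(sub("\\s.*$", "", lines))
  vhead <- which(sec == "*vertices")
  if (length(vhead) == 0L) {
    abort(sprintf("Parse error in %s: missing *Vertices section.", path))
  }
  vhead <- vhead[1L]
  nv <- suppressWarnings(as.integer(strsplit(lines[vhead], "\\s+")[[1L]][2L]))
  if (is.na(nv) || nv < 0L) {
    abort(sprintf("Parse error in %s: bad *Vertices count.", path))
  }
  headers <- which(startsWith(sec, "*"))
  labels <- as.character(seq_len(nv))
  v_end <- min(c(headers[headers > vhead], length(lines) + 1L))
  for (ln in lines[seq.int(vhead + 1L, length.out = max(0L, v_end - vhead - 1L))] ) {
    m <- regmatches(ln, regexec("^(\\d+)\\s+\"([^\"]*)\"", ln))[[1L]]
    if (length(m) == 3L) {
      i <- as.integer(m[2L])
      if (i >= 1L && i <= nv) labels[i] <- m[3L]
    }
  }
  read_pairs <- function(section) {
    starts <- which(sec == section)
    out <- list()
    for (s in starts) {
      e <- min(c(headers[headers > s], length(lines) + 1L))
      body <- lines[seq.int(s + 1L, length.out = max(0L, e - s - 1L))]
      for (ln in body) {
        tok <- strsplit(ln, "\\s+")[[1L]]
        ij <- suppressWarnings(as.integer(tok[1:2]))
        if (length(tok) < 2L || anyNA(ij)) {
          abort(sprintf("Parse error in %s: malformed %s line '%s'.", path, section, ln))
        }
        if (any(ij < 1L) || any(ij > nv)) {
          abort(sprintf(
            "Parse error in %s: vertex index out of range 1..%d in line '%s'.",
            path, nv, ln
          ))
        }
        out[[length(out) + 1L]] <- ij
      }
    }
    out
  }
  arcs <- read_pairs("*arcs")
  edges <- read_pairs("*edges")
  fr <- c(
    vapply(arcs, `[[`, 1L, 1L),
    vapply(edges, `[[`, 1L, 1L), vapply(edges, `[[`, 1L, 2L)
  )
  to <- c(
    vapply(arcs, `[[`, 1L, 2L),
    vapply(edges, `[[`, 1L, 2L), vapply(edges, `[[`, 1L, 1L)
  )
  digraph(tibble(from = labels[fr], to = labels[to]), nodes = labels)
}
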