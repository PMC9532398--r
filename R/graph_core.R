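#' Simple undirected graphs
#'
#' A `simple_graph` is the substrate every other function in the package
#' consumes: a simple (no self-loops, no multi-edges), undirected, unweighted
#' graph stored as sorted per-node adjacency lists. Node labels are arbitrary
#' strings; internally nodes are contiguous integer ids `1..n` assigned in
#' first-appearance order, so all outputs are deterministic given the input.
#'
#' @param edges two-column matrix (or data.frame) of node ids (integers in
#'   `1..n`) or labels (character), one row per edge. May have zero rows.
#' @param n node count; required when `edges` is an id matrix that does not
#'   touch every node. Ignored when `labels` is given.
#' @param labels character vector of node labels; defaults to
#'   `as.character(seq_len(n))`.
#' @param on_duplicate what to do with duplicate (or reversed duplicate)
#'   edges: `"collapse"` keeps one copy and records the number collapsed in
#'   attribute `"n_collapsed"`, `"error"` raises.
#'
#' @return An object of class `simple_graph` with elements `labels`, `adj`
#'   (list of sorted integer neighbor vectors), `n` and `m`.
#'
#' @examples
#' g <- simple_graph(cbind(c(1, 2, 3), c(2, 3, 1)), n = 3)
#' degrees(g)
#' @export
simple_graph <- function(edges, n = NULL, labels = NULL,
                         on_duplicate = c("collapse", "error")) {
  on_duplicate <- match.arg(on_duplicate)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("`edges` must have two columns")
  edges <- edges[, 1:2, drop = FALSE]

  if (is.character(edges)) {
    if (is.null(labels)) {
      labels <- unique(as.vector(t(edges)))
    }
    ii <- match(edges[, 1L], labels)
    jj <- match(edges[, 2L], labels)
    if (anyNA(ii) || anyNA(jj)) stop("edge labels not found in `labels`")
  } else {
    ii <- as.integer(edges[, 1L])
    jj <- as.integer(edges[, 2L])
    if (is.null(labels)) {
      if (is.null(n)) n <- if (length(ii)) max(ii, jj) else 0L
      labels <- as.character(seq_len(n))
    }
  }
  n <- length(labels)
  if (anyDuplicated(labels)) stop("node labels must be unique")
  if (length(ii) && (min(ii, jj) < 1L || max(ii, jj) > n)) {
    stop("edge ids out of range 1..n")
  }
  if (any(ii == jj)) stop("self-loops are not allowed")

  lo <- pmin(ii, jj)
  hi <- pmax(ii, jj)
  key <- (lo - 1) * n + hi
  dup <- duplicated(key)
  n_collapsed <- sum(dup)
  if (n_collapsed > 0L) {
    if (on_duplicate == "error") {
      stop(sprintf("%d duplicate edge(s) found (strict mode)", n_collapsed))
    }
    lo <- lo[!dup]
    hi <- hi[!dup]
  }

  adj <- unname(split(c(hi, lo), factor(c(lo, hi), levels = seq_len(n))))
  adj <- lapply(adj, function(v) sort.int(as.integer(v)))

  g <- structure(
    list(labels = labels, adj = adj, n = n, m = length(lo)),
    class = "simple_graph"
  )
  attr(g, "n_collapsed") <- n_collapsed
  g
}

#' @export
print.simple_graph <- function(x, ...) {
  cat(sprintf("simple_graph: %d nodes, %d edges\n", x$n, x$m))
  invisible(x)
}

#' Node degrees of a simple graph
#'
#' @param graph a [simple_graph].
#' @return Integer vector of degrees, one per node; `sum(degrees(g)) == 2 * g$m`.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "simple_graph"))
  vapply(graph$adj, length, integer(1))
}

#' Validate the internal invariants of a simple graph
#'
#' Checks that the adjacency structure is symmetric, sorted, free of
#' self-loops and duplicates, and consistent with the stored `n` and `m`.
#' Mostly useful in tests and after manual construction.
#'
#' @param graph a [simple_graph].
#' @return `graph`, invisibly; errors describe the first violated invariant.
#' @export
validate_simple_graph <- function(graph) {
  stopifnot(inherits(graph, "simple_graph"))
  n <- graph$n
  if (length(graph$labels) != n || length(graph$adj) != n) {
    stop("label/adjacency length mismatch")
  }
  d <- degrees(graph)
  if (sum(d) != 2L * graph$m) stop("sum of degrees != 2m")
  for (i in seq_len(n)) {
    nb <- graph$adj[[i]]
    if (is.unsorted(nb, strictly = TRUE)) {
      stop(sprintf("neighbors of node %d not strictly sorted", i))
    }
    if (any(nb == i)) stop(sprintf("self-loop at node %d", i))
    if (length(nb) && (nb[1] < 1L || nb[length(nb)] > n)) {
      stop("neighbor id out of range")
    }
    for (j in nb) {
      if (!any(graph$adj[[j]] == i)) {
        stop(sprintf("asymmetric adjacency: %d -> %d", i, j))
      }
    }
  }
  invisible(graph)
}

# Unordered edge matrix (lower id first), one row per edge.
edge_matrix <- function(graph) {
  d <- degrees(graph)
  i <- rep.int(seq_len(graph$n), d)
  j <- unlist(graph$adj, use.names = FALSE)
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

#' Read a plain-text edge list
#'
#' Parses a two-column edge list with arbitrary string labels into a
#' [simple_graph]. Lines starting with `#` and blank lines are skipped. The
#' delimiter is auto-detected (tab, comma, or any whitespace) unless given.
#' Extra columns (e.g. weights) are ignored with a warning; the methods in
#' this package are defined for undirected, unweighted graphs only.
#'
#' Node ids are assigned in first-appearance order, so the mapping from
#' labels to ids -- and every downstream table -- is reproducible. Isolated
#' nodes cannot be expressed in a bare edge list; pass their labels through
#' `nodes` (a character vector, or path to a one-label-per-line file). This
#' matters for the configuration model and for node proportions, where
#' degree-0 nodes count.
#'
#' @param source file path, connection, or a character vector of lines.
#' @param delimiter field separator; `NULL` (default) auto-detects.
#' @param on_duplicate `"collapse"` (default) merges duplicate and reversed
#'   duplicate edges into one undirected edge, `"error"` raises.
#' @param nodes optional labels of additional (possibly isolated) nodes.
#' @return A [simple_graph]; attribute `"n_collapsed"` records merged edges.
#' @examples
#' g <- load_edge_list(c("a b", "b c"))
#' g$m # 2
#' @export
load_edge_list <- function(source, delimiter = NULL,
                           on_duplicate = c("collapse", "error"),
                           nodes = NULL) {
  on_duplicate <- match.arg(on_duplicate)
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    lines <- source
  } else {
    stop("`source` must be a file path, connection, or character vector")
  }
  if (!is.null(nodes) && length(nodes) == 1L && file.exists(nodes)) {
    nodes <- readLines(nodes, warn = FALSE)
    nodes <- trimws(nodes)
    nodes <- nodes[nzchar(nodes) & !startsWith(nodes, "#")]
  }

  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L && length(nodes) == 0L) {
    stop("empty input: no edges and no nodes")
  }

  if (is.null(delimiter)) {
    delimiter <- if (any(grepl(",", lines, fixed = TRUE))) "," else "[ \t]+"
  } else if (delimiter %in% c(" ", "\t")) {
    delimiter <- "[ \t]+"
  }
  fields <- strsplit(trimws(lines), delimiter)

  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- lineno[which(nf < 2L)[1]]
    stop(sprintf("parse error: line %d has fewer than 2 fields", bad))
  }
  if (any(nf > 2L)) {
    warning("extra columns ignored; graphs are undirected and unweighted")
  }

  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  loops <- from == to
  if (any(loops)) {
    stop(sprintf("validation error: self-loop on line %d (node '%s')",
                 lineno[which(loops)[1]], from[which(loops)[1]]))
  }

  labels <- unique(c(as.vector(rbind(from, to)), nodes))
  simple_graph(cbind(from, to), labels = labels, on_duplicate = on_duplicate)
}

#' Write a graph as a plain-text edge list
#'
#' One line per undirected edge, original labels, lower internal id first.
#' Round-trips through [load_edge_list()] to a graph with identical
#' adjacency. An empty graph yields an empty file (isolated nodes are not
#' representable in a bare edge list; keep a node sidecar if you need them).
#'
#' @param graph a [simple_graph].
#' @param sink file path or writable connection.
#' @param delimiter field separator used between the two labels.
#' @return `sink`, invisibly.
#' @export
write_edge_list <- function(graph, sink, delimiter = "\t") {
  stopifnot(inherits(graph, "simple_graph"))
  em <- edge_matrix(graph)
  out <- if (nrow(em)) {
    paste(graph$labels[em[, 1L]], graph$labels[em[, 2L]], sep = delimiter)
  } else {
    character()
  }
  writeLines(out, sink)
  invisible(sink)
}
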