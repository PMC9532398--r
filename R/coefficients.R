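#' Nodewise structural similarity and complementarity coefficients
#'
#' From the node census the six nodewise coefficients are plain ratios of
#' closed motifs to paths:
#'
#' * t-clustering `sW = 2 T_i / tW_i` (the Watts-Strogatz local clustering
#'   coefficient) and t-closure `sH = 2 T_i / tH_i` (the local closure
#'   coefficient): the fractions of wedge resp. head triples at `i` closed
#'   into triangles;
#' * structural similarity `s = 4 T_i / (tW_i + tH_i)`, the fraction of all
#'   triples at `i` that close -- a weighted average of `sW` and `sH`, so
#'   `min(sW, sH) <= s <= max(sW, sH)`, and `s = 1` iff `i` sits in a
#'   complete component;
#' * their quadrangle analogues q-clustering `cW = 2 Q_i / qW_i`, q-closure
#'   `cH = 2 Q_i / qH_i` and structural complementarity
#'   `c = 4 Q_i / (qW_i + qH_i)`, with `c = 1` iff `i` sits in a complete
#'   bipartite component.
#'
#' A coefficient with a zero denominator is undefined and reported as `NA`
#' (never coerced to 0): e.g. `sW` for degree-1 nodes, or every
#' complementarity coefficient at the center of a star, whose degree-1
#' neighbors generate no quadruples. Averages downstream skip `NA`s.
#'
#' @param nodes node census from [node_census_from_edges()].
#' @return A data.frame with one row per node: `node, label, degree, sW, sH,
#'   s, cW, cH, c`.
#' @examples
#' nc <- path_census(gen_fixture("complete", 4))$nodes
#' node_coefficients(nc)$s # all 1
#' @export
node_coefficients <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(
    node = nodes$node, label = nodes$label, degree = nodes$degree,
    sW = ratio(2 * nodes$T, nodes$tW),
    sH = ratio(2 * nodes$T, nodes$tH),
    s = ratio(4 * nodes$T, nodes$tW + nodes$tH),
    cW = ratio(2 * nodes$Q, nodes$qW),
    cH = ratio(2 * nodes$Q, nodes$qH),
    c = ratio(4 * nodes$Q, nodes$qW + nodes$qH),
    row.names = NULL
  )
}

#' Edgewise coefficients and structural equivalence
#'
#' For every (undirected) edge:
#' * `s_ij = 2 T_ij / (tW_ij + tH_ij) = 2 n_ij / (d_i + d_j - 2)`, the
#'   fraction of 2-paths through the edge closed into triangles;
#' * `c_ij = 2 Q_ij / (qW_ij + qH_ij)`, the fraction of 3-paths through the
#'   edge closed into chordless quadrangles;
#' * `H_ij = 2 n_ij / (d_i + d_j)`, the Sorenson (normalized Hamming)
#'   structural equivalence of the endpoints' neighborhoods.
#'
#' `s_ij` differs from `H_ij` only by the `-2` discounting the known
#' `(i, j)` edge. Each nodewise coefficient is a weighted average of its
#' edgewise values, so `min_j s_ij <= s_i <= max_j s_ij` and likewise for
#' `c`. Zero denominators yield `NA`.
#'
#' @param graph a [simple_graph].
#' @param edges edge census from [path_census_edges()] for `graph`.
#' @return A data.frame with one row per undirected edge (`i < j`):
#'   `i, j, label_i, label_j, s, c, H`.
#' @export
edge_coefficients <- function(graph, edges) {
  stopifnot(inherits(graph, "simple_graph"), is.data.frame(edges))
  keep <- edges$i < edges$j
  e <- edges[keep, , drop = FALSE]
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  d <- degrees(graph)
  data.frame(
    i = e$i, j = e$j,
    label_i = graph$labels[e$i], label_j = graph$labels[e$j],
    s = ratio(2 * e$T, e$tW + e$tH),
    c = ratio(2 * e$Q, e$qW + e$qH),
    H = ratio(2 * e$T, d[e$i] + d[e$j]),
    row.names = NULL
  )
}

#' Global similarity and complementarity coefficients
#'
#' `s = 3T / n_triples` is the fraction of connected triples closed into
#' triangles -- the classical global clustering coefficient (transitivity).
#' `c = 4Q / n_quadruples` is the fraction of 3-paths closed into chordless
#' quadrangles. `s = 1` only on complete graphs; `c = 1` only on complete
#' bipartite graphs, and `c = 0` on complete graphs with `n >= 4` since
#' every 4-cycle there is chorded. In G(n, p) the expectations are
#' `E[s] = p` and `E[c] = p (1 - p)^2`.
#'
#' @param global output of [global_census()].
#' @return A list with `s` and `c` (each `NA` when the corresponding path
#'   count is zero).
#' @export
global_coefficients <- function(global) {
  list(
    s = if (global$n_triples > 0) 3 * global$T / global$n_triples else NA_real_,
    c = if (global$n_quadruples > 0) 4 * global$Q / global$n_quadruples else NA_real_
  )
}

#' All structural coefficients of a graph
#'
#' One-call wrapper: runs the path census and returns node, edge and global
#' coefficient tables.
#'
#' @param graph a [simple_graph].
#' @return A list of class `structural_coefficients` with elements `nodes`,
#'   `edges`, `global`, plus the underlying `census`.
#' @examples
#' sc <- structural_coefficients(gen_fixture("complete_bipartite", c(2, 2)))
#' sc$global$c # 1
#' @export
structural_coefficients <- function(graph) {
  cen <- path_census(graph)
  structure(
    list(
      nodes = node_coefficients(cen$nodes),
      edges = edge_coefficients(graph, cen$edges),
      global = global_coefficients(cen$global),
      census = cen
    ),
    class = "structural_coefficients"
  )
}

#' @export
print.structural_coefficients <- function(x, ...) {
  cat(sprintf("structural_coefficients: global s=%.4g, c=%.4g (%d nodes)\n",
              x$global$s, x$global$c, nrow(x$nodes)))
  invisible(x)
}

#' Asymmetric Excess Sorenson index of a connected triple
#'
#' For a connected triple `(k, i, j)` (edges `(k, i)` and `(i, j)` must
#' exist), measures how many of `k`'s connections are shared by `j` while
#' discounting the triple's own edges:
#' `H_{kj|i} = (n_jk - 1) / (d_k - 1 - a_jk)`.
#' The `-1`s remove `i` (a known shared neighbor) and the `(i, k)` edge from
#' `k`'s degree; `a_jk` removes a direct `(j, k)` edge if present. The
#' structural complementarity of a node is bounded above by the maximum of
#' these indices over its neighbors and 2-hop neighbors: high `c_i` can
#' exist only amid high structural equivalence between `i`'s neighbors and
#' between `i` and its 2-hop neighborhood.
#'
#' @param graph a [simple_graph].
#' @param k,j,i node ids (integers) or labels (strings) forming the
#'   connected triple `(k, i, j)`.
#' @return A value in `[0, 1]`, or `NA` when the denominator is zero.
#' @export
asymmetric_excess_sorenson <- function(graph, k, j, i) {
  stopifnot(inherits(graph, "simple_graph"))
  resolve <- function(v) {
    if (is.character(v)) {
      id <- match(v, graph$labels)
      if (is.na(id)) stop(sprintf("unknown node label '%s'", v))
      id
    } else {
      as.integer(v)
    }
  }
  k <- resolve(k); j <- resolve(j); i <- resolve(i)
  has_edge <- function(a, b) any(graph$adj[[a]] == b)
  if (!has_edge(k, i) || !has_edge(i, j)) {
    stop("(k, i, j) is not a connected triple: edges (k,i) and (i,j) required")
  }
  n_jk <- length(intersect(graph$adj[[j]], graph$adj[[k]]))
  a_jk <- as.integer(has_edge(j, k))
  den <- length(graph$adj[[k]]) - 1L - a_jk
  if (den <= 0L) NA_real_ else (n_jk - 1) / den
}

#' Complementarity upper bound from structural equivalence
#'
#' Per-node evaluation of the bound `c_i <= max(H_{kj|i}, H_{li|j})` over
#' `j` in `N(i)`, `k` in `N(i) \ {j}` and `l` in `N(j) \ {i}`: the largest
#' Asymmetric Excess Sorenson index between any two of `i`'s neighbors, or
#' between `i` and any of its 2-hop neighbors. Nodes for which no admissible
#' triple has a defined index get `NA`.
#'
#' @param graph a [simple_graph].
#' @return Numeric vector, one bound per node.
#' @export
complementarity_upper_bound <- function(graph) {
  stopifnot(inherits(graph, "simple_graph"))
  n <- graph$n
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    best <- NA_real_
    for (j in graph$adj[[i]]) {
      for (k in setdiff(graph$adj[[i]], j)) {
        h <- asymmetric_excess_sorenson(graph, k, j, i)
        if (!is.na(h) && (is.na(best) || h > best)) best <- h
      }
      for (l in setdiff(graph$adj[[j]], i)) {
        h <- asymmetric_excess_sorenson(graph, l, i, j)
        if (!is.na(h) && (is.na(best) || h > best)) best <- h
      }
    }
    out[i] <- best
  }
  out
}
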