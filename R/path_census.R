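#' Edge-level path census
#'
#' Counts, for every ordered edge (i, j), the six path/cycle motifs the
#' structural coefficients are built from:
#'
#' * `T` -- triangles containing the edge (`= n_ij`, the shared neighbors);
#' * `tW`, `tH` -- wedge triples `(k, i, j)` and head triples `(i, j, k)`,
#'   with closed forms `d_i - 1` and `d_j - 1`;
#' * `Q` -- strong (chordless) quadrangles `i-j-k-l-i`, i.e. 4-cycles through
#'   the edge with both diagonals `(i, k)` and `(j, l)` absent;
#' * `qW`, `qH` -- wedge quadruples `(j, i, k, l)` and head quadruples
#'   `(i, j, k, l)`; 3-paths over four distinct nodes, chords allowed.
#'
#' Chordlessness is enforced only in the quadrangle count (the numerator of
#' every complementarity coefficient); the quadruple counts are plain 3-path
#' counts so that coefficients are fractions of paths that close. By
#' symmetry `T_ij = T_ji`, `Q_ij = Q_ji`, `tW_ij = tH_ji` and
#' `qW_ij = qH_ji`. Everything downstream -- node and global counts, all
#' coefficients -- is an aggregation of this table.
#'
#' @param graph a [simple_graph].
#' @return A data.frame with one row per ordered edge (2m rows, sorted by
#'   `(i, j)`) and columns `i, j, T, tW, tH, Q, qW, qH`.
#' @examples
#' path_census_edges(gen_fixture("cycle", 4))
#' @export
path_census_edges <- function(graph) {
  stopifnot(inherits(graph, "simple_graph"))
  res <- census_edges_cpp(graph$adj)
  as.data.frame(res)
}

#' Node-level census by aggregation of edge counts
#'
#' Sums the edge table over edges incident to each node: `T_i` and `Q_i` are
#' halved (each triangle/quadrangle at `i` spans two of its incident edges),
#' the four path counts are plain sums. Closed forms used as internal
#' guards: `tW_i = d_i (d_i - 1)` and `tH_i = sum_{j in N(i)} (d_j - 1)`.
#'
#' @param graph the [simple_graph] the edge table was computed from.
#' @param edges output of [path_census_edges()] for `graph`.
#' @return A data.frame with one row per node: `node, label, degree, T, tW,
#'   tH, Q, qW, qH`. Isolated nodes get all-zero counts.
#' @export
node_census_from_edges <- function(graph, edges) {
  stopifnot(inherits(graph, "simple_graph"), is.data.frame(edges))
  d <- degrees(graph)
  if (nrow(edges) != 2L * graph$m) {
    stop("edge table does not match graph (row count != 2m)")
  }
  n <- graph$n
  agg <- function(x) {
    out <- numeric(n)
    rs <- rowsum(x, edges$i)
    out[as.integer(rownames(rs))] <- rs[, 1L]
    out
  }
  if (nrow(edges)) {
    T_i <- agg(edges$T) / 2
    Q_i <- agg(edges$Q) / 2
    tW_i <- agg(edges$tW)
    tH_i <- agg(edges$tH)
    qW_i <- agg(edges$qW)
    qH_i <- agg(edges$qH)
  } else {
    T_i <- Q_i <- tW_i <- tH_i <- qW_i <- qH_i <- numeric(n)
  }
  if (any(tW_i != d * (d - 1))) {
    stop("edge table inconsistent with graph degrees (tW aggregation)")
  }
  data.frame(
    node = seq_len(n), label = graph$labels, degree = d,
    T = T_i, tW = tW_i, tH = tH_i, Q = Q_i, qW = qW_i, qH = qH_i,
    row.names = NULL
  )
}

#' Graph-level census totals
#'
#' Totals with every motif counted once: `T = sum(T_i) / 3` (a triangle has
#' three corners), `Q = sum(Q_i) / 4` (a chordless quadrangle has four).
#' `n_triples` is the number of connected triples `sum_i choose(d_i, 2)
#' = sum(tW_i) / 2`, and `n_quadruples` the number of distinct 3-paths,
#' `sum over edges (i,j) of (d_i - 1)(d_j - 1) - n_ij = sum(qW_i) / 2`;
#' the only exclusion is the coincidence of the two path endpoints, chords
#' are allowed. Non-integral divisions indicate a corrupted census and
#' raise.
#'
#' @param nodes output of [node_census_from_edges()].
#' @param graph the corresponding [simple_graph].
#' @return A list with `T`, `Q`, `n_triples`, `n_quadruples`.
#' @export
global_census <- function(nodes, graph) {
  stopifnot(is.data.frame(nodes), inherits(graph, "simple_graph"))
  if (nrow(nodes) != graph$n) stop("node table does not match graph")
  Tsum <- sum(nodes$T)
  Qsum <- sum(nodes$Q)
  if (Tsum %% 3 != 0) stop("internal consistency error: sum(T_i) not divisible by 3")
  if (Qsum %% 4 != 0) stop("internal consistency error: sum(Q_i) not divisible by 4")
  if (sum(nodes$qW) != sum(nodes$qH)) {
    stop("internal consistency error: wedge/head quadruple totals differ")
  }
  list(
    T = Tsum / 3,
    Q = Qsum / 4,
    n_triples = sum(nodes$tW) / 2,
    n_quadruples = sum(nodes$qW) / 2
  )
}

#' Full path census of a graph
#'
#' Convenience wrapper running [path_census_edges()],
#' [node_census_from_edges()] and [global_census()] in one call.
#'
#' @param graph a [simple_graph].
#' @return A list of class `path_census` with elements `edges`, `nodes`,
#'   `global`.
#' @export
path_census <- function(graph) {
  edges <- path_census_edges(graph)
  nodes <- node_census_from_edges(graph, edges)
  structure(
    list(edges = edges, nodes = nodes, global = global_census(nodes, graph)),
    class = "path_census"
  )
}

#' @export
print.path_census <- function(x, ...) {
  g <- x$global
  cat(sprintf(
    "path_census: T=%g (triples %g), Q=%g (quadruples %g)\n",
    g$T, g$n_triples, g$Q, g$n_quadruples
  ))
  invisible(x)
}

#' Brute-force census oracle
#'
#' Recomputes the full census by literal enumeration: paths are enumerated
#' as tuples of distinct nodes over the adjacency matrix, triangles and
#' chordless quadrangles by classifying the induced subgraph of every 3- and
#' 4-node subset. This is an independent verification route for
#' [path_census()] -- the two must agree exactly on every graph -- and is
#' deliberately restricted to small graphs.
#'
#' @param graph a [simple_graph] with at most 15 nodes.
#' @return A list with `edges`, `nodes`, `global` in the same layout as
#'   [path_census()].
#' @export
oracle_census <- function(graph) {
  stopifnot(inherits(graph, "simple_graph"))
  n <- graph$n
  if (n > 15L) stop("oracle_census is exhaustive; refusing n > 15")
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) A[i, graph$adj[[i]]] <- 1L
  d <- degrees(graph)
  V <- seq_len(n)

  # --- induced-subgraph classification of subsets --------------------------
  is_c4 <- function(s) { # 4-subset induces a chordless 4-cycle
    sub <- A[s, s]
    sum(sub) == 8L && all(rowSums(sub) == 2L)
  }
  tri_sets <- if (n >= 3L) utils::combn(n, 3L, simplify = FALSE) else list()
  quad_sets <- if (n >= 4L) utils::combn(n, 4L, simplify = FALSE) else list()
  tri_flag <- vapply(tri_sets, function(s) sum(A[s, s]) == 6L, logical(1))
  quad_flag <- vapply(quad_sets, is_c4, logical(1))
  member <- function(sets) { # sets x nodes membership matrix
    mm <- matrix(FALSE, length(sets), n)
    for (si in seq_along(sets)) mm[si, sets[[si]]] <- TRUE
    mm
  }
  tri_mem <- member(tri_sets)
  quad_mem <- member(quad_sets)

  # --- edge table ----------------------------------------------------------
  rows <- list()
  r <- 0L
  for (i in V) {
    for (j in graph$adj[[i]]) {
      tW <- sum(A[i, ] == 1L & V != j)
      tH <- sum(A[j, ] == 1L & V != i)
      Tij <- sum(tri_flag & tri_mem[, i] & tri_mem[, j])
      Qij <- sum(quad_flag & quad_mem[, i] & quad_mem[, j])
      qH <- 0L
      for (k in V[A[j, ] == 1L & V != i]) {
        qH <- qH + sum(A[k, ] == 1L & V != j & V != i)
      }
      qW <- 0L
      for (k in V[A[i, ] == 1L & V != j]) {
        qW <- qW + sum(A[k, ] == 1L & V != i & V != j)
      }
      r <- r + 1L
      rows[[r]] <- c(i, j, Tij, tW, tH, Qij, qW, qH)
    }
  }
  edges <- if (r) {
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- c("i", "j", "T", "tW", "tH", "Q", "qW", "qH")
    df
  } else {
    data.frame(i = integer(), j = integer(), T = numeric(), tW = numeric(),
               tH = numeric(), Q = numeric(), qW = numeric(), qH = numeric())
  }

  # --- node table by direct path enumeration -------------------------------
  T_i <- Q_i <- tW_i <- tH_i <- qW_i <- qH_i <- numeric(n)
  for (i in V) {
    T_i[i] <- sum(tri_flag & tri_mem[, i])
    Q_i[i] <- sum(quad_flag & quad_mem[, i])
    nb <- graph$adj[[i]]
    tW_i[i] <- d[i] * (d[i] - 1) # ordered pairs of distinct neighbors
    tH_i[i] <- sum(vapply(nb, function(j) sum(A[j, ] == 1L & V != i), numeric(1)))
    # wedge quadruples (j, i, k, l): j, k in N(i), j != k, l in N(k) \ {i, j}
    for (j in nb) for (k in nb[nb != j]) {
      qW_i[i] <- qW_i[i] + sum(A[k, ] == 1L & V != i & V != j)
    }
    # head quadruples (i, j, k, l): j in N(i), k in N(j) \ {i}, l in N(k) \ {i, j}
    for (j in nb) for (k in graph$adj[[j]][graph$adj[[j]] != i]) {
      qH_i[i] <- qH_i[i] + sum(A[k, ] == 1L & V != i & V != j)
    }
  }
  nodes <- data.frame(
    node = V, label = graph$labels, degree = d,
    T = T_i, tW = tW_i, tH = tH_i, Q = Q_i, qW = qW_i, qH = qH_i,
    row.names = NULL
  )

  # --- global counts from subset classification and 3-path enumeration -----
  n_quadruples <- 0L
  for (i in V) for (j in V[A[i, ] == 1L]) {
    for (k in V[A[j, ] == 1L & V != i]) {
      n_quadruples <- n_quadruples + sum(A[k, ] == 1L & V != j & V != i)
    }
  }
  global <- list(
    T = sum(tri_flag),
    Q = sum(quad_flag),
    n_triples = sum(choose(d, 2)),
    n_quadruples = n_quadruples / 2
  )
  structure(list(edges = edges, nodes = nodes, global = global),
            class = "path_census")
}
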