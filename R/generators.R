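#' Deterministic graph fixtures
#'
#' Named graphs realizing the extremal cases of the structural coefficients:
#' complete graphs maximize similarity (`s_i = s = 1`), complete bipartite
#' graphs maximize complementarity (`c_i = c = 1`), while cycles, paths and
#' stars exercise the degenerate and boundary behavior (undefined
#' coefficients, zero counts).
#'
#' @param kind one of `"complete"`, `"complete_bipartite"`, `"cycle"`,
#'   `"path"`, `"star"`.
#' @param sizes positive integer(s): `n` for most kinds, `c(a, b)` for
#'   `"complete_bipartite"`; for `"star"` the total node count (one hub,
#'   `n - 1` leaves).
#' @return A [simple_graph].
#' @examples
#' gen_fixture("complete", 4)$m # 6
#' gen_fixture("complete_bipartite", c(2, 3))$m # 6
#' @export
gen_fixture <- function(kind, sizes) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("sizes must be positive")
  edges <- switch(kind,
    complete = {
      n <- sizes[1]
      if (n < 2L) matrix(integer(), ncol = 2) else t(utils::combn(n, 2L))
    },
    complete_bipartite = {
      if (length(sizes) < 2L) stop("complete_bipartite needs two sizes")
      a <- sizes[1]; b <- sizes[2]
      cbind(rep(seq_len(a), each = b), rep(a + seq_len(b), times = a))
    },
    cycle = {
      n <- sizes[1]
      if (n < 3L) stop("cycle needs at least 3 nodes")
      cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L))
    },
    path = {
      n <- sizes[1]
      if (n < 2L) matrix(integer(), ncol = 2) else cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
    },
    star = {
      n <- sizes[1]
      if (n < 2L) stop("star needs at least 2 nodes")
      cbind(rep(1L, n - 1L), seq_len(n - 1L) + 1L)
    },
    stop(sprintf("unknown fixture kind '%s'", kind))
  )
  n <- switch(kind, complete_bipartite = sum(sizes[1:2]), sizes[1])
  simple_graph(edges, n = n)
}

#' Erdos-Renyi random graph G(n, p)
#'
#' Each of the `choose(n, 2)` node pairs is linked independently with
#' probability `p`. Under the ER model the expected global similarity
#' coefficient equals `p` and the expected global complementarity
#' coefficient equals `p * (1 - p)^2`: a connected quadruple closes into a
#' chordless quadrangle iff the closing edge exists (prob. `p`) and the two
#' potential chords do not (prob. `(1 - p)^2`).
#'
#' @param n node count.
#' @param p edge probability in `[0, 1]`.
#' @param seed optional integer; the same seed yields the identical graph and
#'   the caller's RNG state is untouched.
#' @return A [simple_graph] on `n` nodes.
#' @export
gen_er <- function(n, p, seed = NULL) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  n <- as.integer(n)
  if (n < 2L) return(simple_graph(matrix(integer(), ncol = 2), n = n))
  pairs <- t(utils::combn(n, 2L))
  keep <- with_seed(seed, runif(nrow(pairs)) < p)
  simple_graph(pairs[keep, , drop = FALSE], n = n)
}

#' Geometric sphere-model graphs for similarity and complementarity
#'
#' `n` points are sampled uniformly on the unit `dim`-sphere (surface in
#' `R^(dim+1)`, via normalized standard normal vectors). In `"similarity"`
#' mode two nodes are linked when their angular distance is below `theta`:
#' nodes connect to others nearby, 2-paths tend to close, and triangles
#' abound. In `"complementarity"` mode they are linked when the angular
#' distance exceeds `pi - theta`: nodes connect to the far side of the
#' sphere, where for every point there is a single antipode at maximum
#' distance; connected nodes then share few neighbors but each approximates
#' the other's 2-hop neighborhood, producing chordless quadrangles and
#' locally dense bipartite-like structure.
#'
#' The hard threshold is the simplest link function decreasing in distance
#' (resp. increasing, for complementarity) and makes runs fully reproducible
#' under `seed`. On the circle (`dim = 1`) the angular distance between two
#' uniform points is itself uniform on `[0, pi]`, so the two modes produce
#' the same expected density for the same `theta` -- convenient for matched
#' comparisons.
#'
#' @param n node count.
#' @param theta angular threshold in radians, in `[0, pi]`. `theta = 0`
#'   gives an empty graph in both modes; `theta = pi` a complete graph.
#' @param dim sphere dimension, `>= 1`.
#' @param mode `"similarity"` or `"complementarity"`.
#' @param seed optional integer seed.
#' @return A [simple_graph] on `n` nodes.
#' @export
gen_sphere <- function(n, theta, dim = 1L, mode = c("similarity", "complementarity"),
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, dim >= 1, theta >= 0, theta <= pi)
  n <- as.integer(n)
  x <- with_seed(seed, matrix(rnorm(n * (dim + 1L)), nrow = n))
  x <- x / sqrt(rowSums(x^2))
  ang <- acos(pmax(pmin(tcrossprod(x), 1), -1))
  link <- if (mode == "similarity") ang < theta else ang > pi - theta
  link[lower.tri(link, diag = TRUE)] <- FALSE
  idx <- which(link, arr.ind = TRUE)
  simple_graph(idx, n = n)
}
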