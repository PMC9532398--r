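# Shared fixtures and cross-check helpers.

# C4 plus the 1-3 chord: the smallest graph mixing triangles and chorded
# 4-cycles; node ids 1..4 with edges 12, 23, 34, 41, 13.
diamond_graph <- function() {
  simple_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
}

to_igraph <- function(g) {
  em <- structcoef:::edge_matrix(g)
  igraph::graph_from_edgelist(em, directed = FALSE) |>
    igraph::add_vertices(max(0, g$n - max(c(0, em))))
}

# Compare two census results (edges/nodes/global) for exact equality,
# ignoring row order differences (both use the same ordering by design).
expect_census_equal <- function(a, b) {
  expect_equal(a$edges[c("i", "j", "T", "tW", "tH", "Q", "qW", "qH")],
               b$edges[c("i", "j", "T", "tW", "tH", "Q", "qW", "qH")],
               ignore_attr = TRUE)
  expect_equal(a$nodes[c("T", "tW", "tH", "Q", "qW", "qH")],
               b$nodes[c("T", "tW", "tH", "Q", "qW", "qH")],
               ignore_attr = TRUE)
  expect_equal(a$global, b$global)
}
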