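test_that("edge lists are parsed, deduplicated and validated", {
  path <- withr::local_tempfile(lines = c("# a comment", "1 2", "2 3  # inline"))
  g <- read_edge_list(path)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  dup <- withr::local_tempfile(lines = c("1 2", "2 1", "1 2"))
  expect_warning(g2 <- read_edge_list(dup), "duplicate")
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::vcount(g2), 2)

  loop <- withr::local_tempfile(lines = c("1 2", "3 3"))
  expect_error(read_edge_list(loop), "self-loop")
  empty <- withr::local_tempfile(lines = c("# nothing", ""))
  expect_error(read_edge_list(empty), "no edges")
  expect_error(read_edge_list(withr::local_tempfile(lines = "lonely")),
               "two node identifiers")
})

test_that("edge list writing round-trips through reading", {
  g <- g_two_k4()
  path <- withr::local_tempfile()
  write_edge_list(g, path, header = "fixture")
  g2 <- read_edge_list(path)
  expect_true(igraph::identical_graphs(
    igraph::permute(g2, match(igraph::V(g2)$name, igraph::V(g)$name)), g))
})

test_that("edge betweenness uses the ordered-pair convention", {
  expect_equal(unname(edge_betweenness_pairs(graph_from_edges(edge_df("a", "b")))), 2)
  b <- edge_betweenness_pairs(g_path_abc())
  expect_equal(b[["a|b"]], 4) # ordered pairs a<->b and a<->c
  expect_equal(unname(edge_betweenness_pairs(g_triangle())), rep(2, 3))
})

test_that("edge and node betweenness match exhaustive path enumeration", {
  for (seed in 1:5) {
    ed <- random_edges(7, 0.4, seed)
    if (nrow(ed) == 0) next
    g <- graph_from_edges(ed)
    oracle <- oracle_betweenness(ed, igraph::V(g)$name)
    got <- edge_betweenness_pairs(g)
    expect_equal(got[names(oracle$edge)], oracle$edge, tolerance = 1e-10)
    expect_equal(max_node_betweenness(g), max(oracle$node), tolerance = 1e-10)
    # conservation: each shortest path contributes one unit per edge it uses
    expect_equal(sum(got), oracle$dist_sum, tolerance = 1e-10)
  }
})

test_that("max node betweenness handles paths and stars", {
  expect_equal(max_node_betweenness(g_path_abc()), 2)
  star <- graph_from_edges(edge_df("c", "x", "c", "y", "c", "z"))
  expect_equal(max_node_betweenness(star), 6) # 3*2 ordered leaf pairs
})

test_that("structural summary reproduces closed-form toy values", {
  tri <- structural_summary(g_triangle(), sir_reps = 10, seed = 1)
  expect_equal(tri$avg_shortest_path, 1)
  expect_equal(tri$clustering, 1)
  expect_equal(tri$synchronizability, 1) # K3 Laplacian spectrum {0, 3, 3}

  k2 <- structural_summary(graph_from_edges(edge_df("a", "b")),
                           sir_reps = 10, seed = 1)
  expect_equal(k2$clustering, 0) # degree-1 nodes contribute 0
  expect_equal(k2$avg_shortest_path, 1)
})

test_that("complete graphs have Laplacian eigenratio 1", {
  for (n in 2:6) expect_equal(laplacian_eigenratio(g_complete(n)), 1)
})

test_that("assortativity of a regular graph is flagged undefined", {
  s <- structural_summary(g_triangle(), sir_reps = 5, seed = 1)
  expect_true(is.na(s$assortativity))
})

test_that("average shortest path ignores disconnected pairs", {
  g <- g_two_triangles()
  s <- structural_summary(g, sir_reps = 5, seed = 1)
  expect_equal(s$avg_shortest_path, 1) # each component is a triangle
  expect_false(s$connected)
})
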