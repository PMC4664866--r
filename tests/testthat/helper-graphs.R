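# Small fixture graphs built in code.

g_path_abc <- function() graph_from_edges(edge_df("a", "b", "b", "c"))

g_triangle <- function() {
  graph_from_edges(edge_df("a", "b", "b", "c", "a", "c"))
}

g_two_triangles <- function() {
  graph_from_edges(edge_df("a", "b", "b", "c", "a", "c",
                           "d", "e", "e", "f", "d", "f"))
}

clique_edges <- function(names) {
  idx <- t(utils::combn(length(names), 2))
  data.frame(u = names[idx[, 1]], v = names[idx[, 2]],
             stringsAsFactors = FALSE)
}

g_two_k4 <- function() {
  graph_from_edges(rbind(clique_edges(letters[1:4]), clique_edges(letters[5:8])))
}

g_complete <- function(n) clique_graph(paste0("v", seq_len(n)))

clique_graph <- function(names) graph_from_edges(clique_edges(names))

karate_graph <- function() {
  read_edge_list(system.file("extdata/karate.edgelist", package = "cblink"))
}
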