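#' @useDynLib cblink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import igraph
NULL

# canonical key of an unordered pair of node names
pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\r")
}

# edge data.frame (columns u, v) -> canonical keys
edge_keys <- function(edges) pair_key(edges$u, edges$v)

as_edge_df <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(u = el[, 1], v = el[, 2], stringsAsFactors = FALSE)
}

#' Build an undirected simple graph from an edge table
#'
#' @param edges data.frame with character columns `u` and `v`, one row per
#'   edge. Self-loops and duplicate pairs are rejected.
#' @param nodes optional character vector of node identifiers; must contain
#'   every endpoint. Use it to keep isolated nodes (e.g. nodes stranded by an
#'   edge split) in the graph.
#' @return an undirected [igraph::igraph] object with named vertices.
#' @export
graph_from_edges <- function(edges, nodes = NULL) {
  u <- as.character(edges$u)
  v <- as.character(edges$v)
  if (any(u == v)) stop("self-loops are not allowed")
  if (anyDuplicated(pair_key(u, v))) stop("duplicate edges are not allowed")
  ids <- unique(c(u, v))
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    if (!all(ids %in% nodes)) stop("edge endpoint not in `nodes`")
    ids <- nodes
  }
  igraph::graph_from_data_frame(data.frame(u, v), directed = FALSE,
                                vertices = ids)
}

#' Read an undirected edge list from a text file
#'
#' One edge per line as two whitespace-separated node identifiers; anything
#' after `#` is a comment. Duplicate lines (in either orientation) are
#' collapsed with a warning; a self-loop line is an error.
#'
#' @param path path to the edge-list file.
#' @return an undirected [igraph::igraph] with named vertices.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", raw))
  keep <- which(nzchar(stripped))
  if (length(keep) == 0L) stop("no edges found in ", path)
  toks <- strsplit(stripped[keep], "[[:space:]]+")
  nt <- vapply(toks, length, integer(1))
  if (any(nt < 2L))
    stop("line ", keep[which(nt < 2L)[1]], ": expected two node identifiers")
  u <- vapply(toks, `[`, character(1), 1L)
  v <- vapply(toks, `[`, character(1), 2L)
  loop <- u == v
  if (any(loop))
    stop("self-loop at line ", keep[which(loop)[1]], " ('", u[which(loop)[1]],
         "')")
  dup <- duplicated(pair_key(u, v))
  if (any(dup)) {
    warning(sum(dup), " duplicate edge line(s) collapsed")
    u <- u[!dup]
    v <- v[!dup]
  }
  graph_from_edges(data.frame(u, v, stringsAsFactors = FALSE))
}

#' Write a graph as a plain-text edge list
#'
#' @param g an undirected igraph.
#' @param path output file.
#' @param header optional character vector of comment lines (written with a
#'   leading `#`).
#' @export
write_edge_list <- function(g, path, header = NULL) {
  ed <- as_edge_df(g)
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  lines <- c(lines, paste(ed$u, ed$v))
  writeLines(lines, path)
  invisible(path)
}

#' Edge betweenness over ordered node pairs
#'
#' For each edge e, the sum over ordered pairs (i, j), i != j, of the fraction
#' of shortest i-j paths that traverse e. Each unordered pair therefore
#' contributes twice; pairs in different components contribute zero. A single
#' edge joining two nodes has betweenness 2 under this convention.
#'
#' @param g an undirected igraph.
#' @return named numeric vector, one entry per edge (names are
#'   "u|v" with the canonically ordered endpoints).
#' @export
edge_betweenness_pairs <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  b <- igraph::edge_betweenness(g, directed = FALSE) * 2
  ed <- as_edge_df(g)
  names(b) <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v), sep = "|")
  b
}

#' Maximum node betweenness (congestibility)
#'
#' Node betweenness counted over ordered source-target pairs (twice the
#' usual undirected value); the maximum over nodes is used as a congestion
#' proxy for transport on the network.
#'
#' @param g an undirected igraph.
#' @return a single number.
#' @export
max_node_betweenness <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  max(igraph::betweenness(g, directed = FALSE)) * 2
}

#' Laplacian eigenratio (synchronizability)
#'
#' Ratio lambda_max / lambda_2 of the combinatorial Laplacian of the largest
#' connected component. Smaller ratios indicate a more synchronizable
#' network; the ratio is 1 exactly for complete graphs.
#'
#' @param g an undirected igraph.
#' @return a single number (>= 1 for connected graphs with >= 2 nodes).
#' @export
laplacian_eigenratio <- function(g) {
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  n <- igraph::vcount(sub)
  if (n < 2L) return(NA_real_)
  L <- igraph::laplacian_matrix(sub, sparse = FALSE)
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  ev[n] / ev[2L]
}

mean_local_clustering <- function(g) {
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0 # degree-1 nodes contribute 0 by convention
  mean(lc)
}

#' Structural and dynamical summary of a network
#'
#' Computes the six indices used to compare reconstructed networks with the
#' original: mean shortest path (over connected pairs only, so disconnected
#' graphs are handled), mean local clustering coefficient (nodes of degree
#' < 2 contribute 0), degree assortativity (NA when undefined, e.g. regular
#' graphs), congestibility ([max_node_betweenness()]), synchronizability
#' ([laplacian_eigenratio()] of the largest component) and mean epidemic
#' outbreak size ([spreading_ability()]).
#'
#' @param g an undirected igraph.
#' @param transmission per-contact transmission probability for the spreading
#'   index; `NULL` uses the default of [spreading_ability()].
#' @param sir_reps Monte-Carlo replicates for the spreading index.
#' @param seed optional RNG seed for the spreading simulation.
#' @return an object of class `index_report`: a list with elements
#'   `avg_shortest_path`, `clustering`, `assortativity`, `congestibility`,
#'   `synchronizability`, `spreading_ability`, plus the SIR settings used.
#' @export
structural_summary <- function(g, transmission = NULL, sir_reps = 1000L,
                               seed = NULL) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  r <- igraph::assortativity_degree(g)
  if (is.nan(r)) r <- NA_real_
  sa <- spreading_ability(g, transmission = transmission, reps = sir_reps,
                          seed = seed)
  out <- list(
    avg_shortest_path = igraph::mean_distance(g, directed = FALSE,
                                              unconnected = TRUE),
    clustering = mean_local_clustering(g),
    assortativity = r,
    congestibility = max_node_betweenness(g),
    synchronizability = laplacian_eigenratio(g),
    spreading_ability = sa,
    transmission = attr(sa, "transmission"),
    sir_reps = sir_reps,
    connected = igraph::is_connected(g)
  )
  class(out) <- "index_report"
  out
}

#' @export
#' @method print index_report
print.index_report <- function(x, ...) {
  cat("Network indices\n")
  cat(sprintf("  avg shortest path : %.3f%s\n", x$avg_shortest_path,
              if (x$connected) "" else " (connected pairs only)"))
  cat(sprintf("  clustering        : %.3f\n", x$clustering))
  cat(sprintf("  assortativity     : %s\n",
              if (is.na(x$assortativity)) "undefined"
              else sprintf("%.4f", x$assortativity)))
  cat(sprintf("  congestibility    : %.1f\n", x$congestibility))
  cat(sprintf("  synchronizability : %.2f\n", x$synchronizability))
  cat(sprintf("  spreading ability : %.2f (transmission %.3f, %d reps)\n",
              x$spreading_ability, x$transmission, x$sir_reps))
  invisible(x)
}

#' @export
#' @method as.data.frame index_report
as.data.frame.index_report <- function(x, ...) {
  data.frame(
    avg_shortest_path = x$avg_shortest_path,
    clustering = x$clustering,
    assortativity = x$assortativity,
    congestibility = x$congestibility,
    synchronizability = x$synchronizability,
    spreading_ability = x$spreading_ability
  )
}
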