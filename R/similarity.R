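# Local similarity scores for link prediction.

check_node <- function(g, x) {
  if (!(x %in% igraph::V(g)$name)) stop("unknown node: ", x)
}

#' Common-neighbours similarity of a node pair
#'
#' The number of shared neighbours |Gamma(x) n Gamma(y)|.
#'
#' @param g an undirected igraph with named vertices.
#' @param x,y distinct node names.
#' @return integer-valued score.
#' @export
cn_score <- function(g, x, y) {
  check_node(g, x); check_node(g, y)
  if (x == y) stop("x and y must differ")
  nx <- igraph::neighbors(g, x)$name
  ny <- igraph::neighbors(g, y)$name
  length(intersect(nx, ny))
}

#' Resource-allocation similarity of a node pair
#'
#' Each common neighbour z contributes 1 / k_z, so resources funnelled
#' through low-degree intermediaries count more.
#'
#' @inheritParams cn_score
#' @return non-negative score.
#' @export
ra_score <- function(g, x, y) {
  check_node(g, x); check_node(g, y)
  if (x == y) stop("x and y must differ")
  common <- intersect(igraph::neighbors(g, x)$name,
                      igraph::neighbors(g, y)$name)
  if (length(common) == 0L) return(0)
  sum(1 / igraph::degree(g, common))
}

#' Score every non-adjacent node pair
#'
#' The candidate universe is all unordered non-adjacent pairs of `g`
#' (isolated nodes included), of size choose(N, 2) - M. Scores are raw
#' (unnormalised); ranking uses the values as-is.
#'
#' @param g an undirected igraph with named vertices.
#' @param method `"CN"` (common neighbours) or `"RA"` (resource allocation).
#' @return data.frame with columns `u`, `v` (canonical order, `u < v`) and
#'   `score`.
#' @export
score_candidates <- function(g, method = c("CN", "RA")) {
  method <- match.arg(method)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  k <- Matrix::rowSums(A)
  S <- if (method == "CN") A %*% A else A %*% (A / pmax(k, 1))
  Sm <- as.matrix(S)
  Am <- as.matrix(A)
  idx <- which(upper.tri(Am) & Am == 0, arr.ind = TRUE)
  nm <- rownames(Am)
  u <- nm[idx[, 1L]]
  v <- nm[idx[, 2L]]
  data.frame(u = pmin(u, v), v = pmax(u, v), score = Sm[idx],
             stringsAsFactors = FALSE)
}
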