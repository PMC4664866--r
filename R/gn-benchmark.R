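# Planted four-community benchmark graphs and community-recovery scoring.

#' Generate a planted-partition benchmark graph
#'
#' The classic four-community test graph: `n` nodes split into `n_comm`
#' equal communities; every intra-community pair is connected independently
#' with p_in = k_in / (n/n_comm - 1) and every inter-community pair with
#' p_out = (total_degree - k_in) / (n - n/n_comm), so a node has on average
#' k_in neighbours inside its community and k_out = total_degree - k_in
#' outside. Larger k_in means clearer community structure.
#'
#' @param k_in expected intra-community degree, in `[0, total_degree]`.
#' @param total_degree expected total degree (default 16, the canonical
#'   benchmark value).
#' @param n number of nodes (default 128).
#' @param n_comm number of communities (default 4); must divide `n`.
#' @param seed optional integer seed.
#' @return object of class `planted_graph`: list with the `graph` (igraph),
#'   the planted `truth` partition (named vector), and `k_in`, `k_out`,
#'   `p_in`, `p_out`.
#' @export
generate_gn <- function(k_in = 12, total_degree = 16, n = 128L,
                        n_comm = 4L, seed = NULL) {
  if (k_in < 0 || k_in > total_degree)
    stop("k_in must lie in [0, total_degree]")
  if (n %% n_comm != 0L) stop("n must be divisible by n_comm")
  size <- n / n_comm
  p_in <- k_in / (size - 1)
  p_out <- (total_degree - k_in) / (n - size)
  if (p_in > 1 || p_out > 1) stop("requested degrees exceed available pairs")
  if (!is.null(seed)) set.seed(seed)
  comm <- rep(seq_len(n_comm), each = size)
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  same <- comm[idx[, 1L]] == comm[idx[, 2L]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(nrow(idx)) < p
  nm <- as.character(seq_len(n))
  edges <- data.frame(u = nm[idx[keep, 1L]], v = nm[idx[keep, 2L]],
                      stringsAsFactors = FALSE)
  truth <- comm
  names(truth) <- nm
  out <- list(graph = graph_from_edges(edges, nodes = nm), truth = truth,
              k_in = k_in, k_out = total_degree - k_in,
              p_in = p_in, p_out = p_out)
  class(out) <- "planted_graph"
  out
}

#' Fraction of nodes classified into the right community
#'
#' Community labels are arbitrary, so the two partitions are aligned by
#' maximum-weight bipartite matching of their labels on the confusion table
#' before counting agreements.
#'
#' @param found,truth named community vectors over the same node set.
#' @return fraction of agreeing nodes in \[0, 1\].
#' @export
classification_accuracy <- function(found, truth) {
  if (!setequal(names(found), names(truth)))
    stop("partitions cover different node sets")
  f <- as.integer(factor(found[names(truth)]))
  t <- as.integer(factor(truth))
  conf <- table(f, t)
  matched_weight(conf) / length(truth)
}

# maximum-weight bipartite matching on a confusion matrix (rows vs columns)
matched_weight <- function(conf) {
  k1 <- nrow(conf)
  k2 <- ncol(conf)
  nz <- which(conf > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(0)
  edges <- as.vector(rbind(nz[, 1L], k1 + nz[, 2L]))
  bg <- igraph::make_bipartite_graph(c(rep(FALSE, k1), rep(TRUE, k2)), edges)
  m <- igraph::max_bipartite_match(bg, weights = conf[nz])
  m$matching_weight
}

#' Stability of detected communities under random link removal
#'
#' Emulates the situation faced when tuning the predictor on incomplete
#' data: communities detected on the full network ("reference") are compared
#' with communities re-detected after deleting a fraction of links uniformly
#' at random. Returns the mean matched-label agreement over replicates.
#'
#' @param k_in expected intra-community degree of the benchmark graphs.
#' @param remove_frac fraction of links removed (default 0.1, the usual
#'   probe fraction).
#' @param reps number of independent realizations.
#' @param seed optional base seed; realization r uses `seed + r`.
#' @param total_degree,n,n_comm benchmark parameters, see [generate_gn()].
#' @return list with `mean_accuracy`, per-replicate `accuracy`, and the
#'   settings used.
#' @export
detection_robustness <- function(k_in = 10, remove_frac = 0.1, reps = 50L,
                                 seed = NULL, total_degree = 16,
                                 n = 128L, n_comm = 4L) {
  acc <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- if (is.null(seed)) NULL else seed + r
    pg <- generate_gn(k_in, total_degree, n, n_comm, seed = s)
    reference <- detect_communities(pg$graph)
    ed <- as_edge_df(pg$graph)
    n_rm <- round(remove_frac * nrow(ed))
    kept <- ed[-sample.int(nrow(ed), n_rm), , drop = FALSE]
    g_obs <- graph_from_edges(kept, nodes = igraph::V(pg$graph)$name)
    redetected <- detect_communities(g_obs)
    acc[r] <- classification_accuracy(redetected, reference)
  }
  list(mean_accuracy = mean(acc), accuracy = acc, k_in = k_in,
       remove_frac = remove_frac, reps = reps, seed = seed)
}
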