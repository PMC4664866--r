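# Modularity and modularity-maximising community detection.

check_partition <- function(g, membership) {
  nm <- igraph::V(g)$name
  if (is.null(names(membership))) stop("partition must be a named vector")
  if (!all(nm %in% names(membership)))
    stop("partition does not cover all nodes")
  membership[nm]
}

#' Newman modularity of a partition
#'
#' Q = sum_r (e_rr - a_r^2), where e_rr is the fraction of edges with both
#' endpoints in community r and a_r the fraction of edge ends attached to r.
#'
#' @param g an undirected igraph with named vertices and at least one edge.
#' @param membership named vector mapping every node name to a community
#'   label.
#' @return modularity value in \[-1, 1\].
#' @export
modularity_q <- function(g, membership) {
  if (igraph::ecount(g) == 0L) stop("modularity undefined on an edgeless graph")
  m <- check_partition(g, membership)
  igraph::modularity(g, as.integer(factor(m)))
}

# adjacency list as 0-based integer vectors
adj0 <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), function(x) as.integer(x) - 1L)
}

# single-node relocation sweeps: move each node to the neighbouring community
# with the largest positive modularity gain, until no move improves Q
refine_partition <- function(g, memb, max_sweeps = 50L) {
  n <- length(memb)
  deg <- igraph::degree(g)
  M <- igraph::ecount(g)
  nbrs <- igraph::as_adj_list(g, mode = "all")
  nbrs <- lapply(nbrs, as.integer)
  K <- tapply(deg, memb, sum)
  Kvec <- rep(0, max(memb))
  Kvec[as.integer(names(K))] <- K
  for (s in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      if (deg[i] == 0L) next
      r <- memb[i]
      nb_comm <- memb[nbrs[[i]]]
      kin <- tapply(rep(1L, length(nb_comm)), nb_comm, sum)
      cand <- as.integer(names(kin))
      kir <- if (as.character(r) %in% names(kin)) kin[[as.character(r)]] else 0L
      best_dq <- 0
      best_s <- r
      for (cc in cand) {
        if (cc == r) next
        kis <- kin[[as.character(cc)]]
        dq <- (kis - kir) / M -
          deg[i] * (Kvec[cc] - Kvec[r] + deg[i]) / (2 * M^2)
        if (dq > best_dq + 1e-12) {
          best_dq <- dq
          best_s <- cc
        }
      }
      if (best_s != r) {
        Kvec[r] <- Kvec[r] - deg[i]
        Kvec[best_s] <- Kvec[best_s] + deg[i]
        memb[i] <- best_s
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

# merge pairs of communities while that improves Q
merge_pass <- function(g, memb) {
  M <- igraph::ecount(g)
  repeat {
    labs <- sort(unique(memb))
    if (length(labs) < 2L) return(memb)
    ed <- igraph::as_edgelist(g, names = FALSE)
    c1 <- memb[ed[, 1L]]
    c2 <- memb[ed[, 2L]]
    K <- vapply(labs, function(l) sum(igraph::degree(g)[memb == l]), 0)
    names(K) <- labs
    best_dq <- 1e-12
    best <- NULL
    for (a in seq_along(labs)) {
      for (b in seq_along(labs)) {
        if (b <= a) next
        la <- labs[a]; lb <- labs[b]
        m_ab <- sum((c1 == la & c2 == lb) | (c1 == lb & c2 == la))
        dq <- m_ab / M - 2 * (K[[as.character(la)]] / (2 * M)) *
          (K[[as.character(lb)]] / (2 * M))
        if (dq > best_dq) {
          best_dq <- dq
          best <- c(la, lb)
        }
      }
    }
    if (is.null(best)) return(memb)
    memb[memb == best[2L]] <- best[1L]
  }
}

#' Detect communities by extremal optimisation of modularity
#'
#' Recursive bipartitioning: each community is tentatively split in two by a
#' tau-EO search (the node of lowest fitness q_i / k_i is relocated across
#' the cut, with rank selection P(rank j) ~ j^-tau), and the split is kept
#' while it increases global modularity. A final relocation-and-merge
#' refinement polishes the partition. The result is reproducible for a fixed
#' seed; quality (not the search trajectory) is the contract, so any
#' modularity maximiser can stand in for comparison.
#'
#' @param g an undirected igraph with named vertices and >= 1 edge.
#' @param seed optional integer seed.
#' @param tau rank-selection exponent; default 1 + 1/ln(n) per subgraph.
#' @param max_nonimprove stop a bipartition search after this many
#'   consecutive non-improving relocations (default n^2 per subgraph, capped
#'   at `nonimprove_cap`).
#' @param nonimprove_cap upper bound on `max_nonimprove` (keeps large graphs
#'   tractable).
#' @param refine run the relocation/merge refinement (default TRUE).
#' @return named integer vector: node name -> community label (1..k).
#' @export
detect_communities <- function(g, seed = NULL, tau = NULL,
                               max_nonimprove = NULL,
                               nonimprove_cap = 20000L, refine = TRUE) {
  if (igraph::ecount(g) == 0L) stop("cannot detect communities: no edges")
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  adj <- adj0(g)
  deg <- igraph::degree(g)
  memb <- rep(1L, n)
  next_label <- 2L
  queue <- 1L
  qcur <- igraph::modularity(g, memb)

  while (length(queue) > 0L) {
    lab <- queue[1L]
    queue <- queue[-1L]
    nodes <- which(memb == lab)
    ns <- length(nodes)
    if (ns < 2L) next
    pos <- integer(n)
    pos[nodes] <- seq_len(ns)
    sub_adj <- lapply(nodes, function(i) {
      nb <- adj[[i]] + 1L
      nb <- nb[memb[nb] == lab]
      pos[nb] - 1L
    })
    sub_deg <- vapply(sub_adj, length, integer(1))
    if (sum(sub_deg) == 0L) next
    tau_s <- if (is.null(tau)) 1 + 1 / log(max(ns, 3L)) else tau
    mni <- if (is.null(max_nonimprove)) ns^2 else max_nonimprove
    mni <- as.integer(min(mni, nonimprove_cap))
    res <- eo_bipartition_cpp(sub_adj, sub_deg, tau_s, mni)
    side <- res$side
    if (length(unique(side)) < 2L) next
    cand <- memb
    cand[nodes[side == 1L]] <- next_label
    qcand <- igraph::modularity(g, cand)
    if (qcand > qcur + 1e-12) {
      memb <- cand
      qcur <- qcand
      queue <- c(queue, lab, next_label)
      next_label <- next_label + 1L
    }
  }

  if (refine) {
    memb <- refine_partition(g, memb)
    memb <- merge_pass(g, memb)
  }
  memb <- as.integer(factor(memb))
  names(memb) <- nm
  memb
}

#' Classify a node pair as intra- or inter-community
#'
#' @param membership named community vector (see [detect_communities()]).
#' @param x,y node names.
#' @return `"intra"` if both nodes share a community label, else `"inter"`.
#' @export
classify_pair <- function(membership, x, y) {
  if (!all(c(x, y) %in% names(membership)))
    stop("unlabelled node in pair (", x, ", ", y, ")")
  if (membership[[x]] == membership[[y]]) "intra" else "inter"
}

# vectorised version over an edge data.frame
classify_pairs <- function(membership, pairs) {
  miss <- setdiff(unique(c(pairs$u, pairs$v)), names(membership))
  if (length(miss) > 0L) stop("unlabelled node: ", miss[1L])
  ifelse(membership[pairs$u] == membership[pairs$v], "intra", "inter")
}
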