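# Brute-force oracles, written against plain edge data.frames so they stay
# independent of the igraph-backed implementation they check.

edge_df <- function(...) {
  m <- matrix(as.character(c(...)), ncol = 2, byrow = TRUE)
  data.frame(u = m[, 1], v = m[, 2], stringsAsFactors = FALSE)
}

oracle_nodes <- function(edges, nodes = NULL) {
  if (is.null(nodes)) sort(unique(c(edges$u, edges$v))) else nodes
}

oracle_adj <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$u[i]]] <- c(adj[[edges$u[i]]], edges$v[i])
    adj[[edges$v[i]]] <- c(adj[[edges$v[i]]], edges$u[i])
  }
  adj
}

oracle_bfs_dist <- function(adj, s) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[s] <- 0
  q <- s
  while (length(q) > 0) {
    u <- q[1]
    q <- q[-1]
    for (w in adj[[u]]) if (!is.finite(d[w])) {
      d[w] <- d[u] + 1
      q <- c(q, w)
    }
  }
  d
}

# every shortest path from u to t, as node-name vectors
oracle_paths <- function(adj, dist_t, u, t) {
  if (u == t) return(list(u))
  out <- list()
  for (w in adj[[u]]) {
    if (is.finite(dist_t[w]) && dist_t[w] == dist_t[u] - 1) {
      for (p in oracle_paths(adj, dist_t, w, t))
        out <- c(out, list(c(u, p)))
    }
  }
  out
}

# edge and node betweenness over ordered pairs by exhaustive path enumeration
oracle_betweenness <- function(edges, nodes = NULL) {
  nodes <- oracle_nodes(edges, nodes)
  adj <- oracle_adj(edges, nodes)
  ekey <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), sep = "|")
  eb <- stats::setNames(rep(0, nrow(edges)), ekey)
  nb <- stats::setNames(rep(0, length(nodes)), nodes)
  dist_sum <- 0
  for (t in nodes) {
    dist_t <- oracle_bfs_dist(adj, t)
    for (s in nodes) {
      if (s == t || !is.finite(dist_t[s])) next
      paths <- oracle_paths(adj, dist_t, s, t)
      sigma <- length(paths)
      dist_sum <- dist_sum + as.numeric(dist_t[[s]])
      for (p in paths) {
        if (length(p) > 2)
          for (v in p[-c(1, length(p))]) nb[v] <- nb[v] + 1 / sigma
        for (i in seq_len(length(p) - 1)) {
          k <- paste(min(p[i], p[i + 1]), max(p[i], p[i + 1]), sep = "|")
          eb[k] <- eb[k] + 1 / sigma
        }
      }
    }
  }
  list(edge = eb, node = nb, dist_sum = dist_sum)
}

# Erdos-Renyi edge table via base R only
random_edges <- function(n, p, seed) {
  set.seed(seed)
  nm <- as.character(seq_len(n))
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  data.frame(u = nm[idx[keep, 1]], v = nm[idx[keep, 2]],
             stringsAsFactors = FALSE)
}

# all set partitions of n items as membership vectors
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1L))
    for (k in seq_len(max(p) + 1L)) out <- c(out, list(c(p, k)))
  out
}

# modularity from first principles: sum_r (e_rr - a_r^2)
oracle_modularity <- function(edges, memb) {
  M <- nrow(edges)
  labs <- unique(memb)
  q <- 0
  for (l in labs) {
    inside <- sum(memb[edges$u] == l & memb[edges$v] == l)
    ends <- sum(memb[edges$u] == l) + sum(memb[edges$v] == l)
    q <- q + inside / M - (ends / (2 * M))^2
  }
  q
}

# best label-matching agreement by exhaustive permutation
oracle_matching_accuracy <- function(found, truth) {
  f <- as.integer(factor(found[names(truth)]))
  t <- as.integer(factor(truth))
  k <- max(max(f), max(t))
  conf <- matrix(0, k, k)
  for (i in seq_along(t)) conf[f[i], t[i]] <- conf[f[i], t[i]] + 1
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, sum(conf[cbind(seq_len(k), p)]))
  best / length(t)
}
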