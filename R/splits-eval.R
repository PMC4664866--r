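# Edge-set splitting and evaluation metrics (AUC, precision, mean predicted
# betweenness, intra/inter prediction counts).

#' Randomly split the edges of a graph into train / learn / probe sets
#'
#' Edges are assigned uniformly at random without replacement; set sizes are
#' the rounded targets. The learning fraction may be zero (plain train/probe
#' split). The three sets are disjoint and their union is E.
#'
#' @param g an undirected igraph with named vertices.
#' @param fractions numeric vector `(train, learn, probe)` summing to 1;
#'   `learn` may be 0.
#' @param seed optional integer seed.
#' @return object of class `edge_split`: list with edge data.frames `train`,
#'   `learn`, `probe`, the probe size `L`, the full node set `nodes`, and
#'   `fractions`/`seed` metadata.
#' @export
split_edges <- function(g, fractions = c(0.9, 0, 0.1), seed = NULL) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      fractions[1] <= 0 || fractions[3] <= 0)
    stop("fractions must be (train, learn, probe) with train, probe > 0")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  ed <- as_edge_df(g)
  M <- nrow(ed)
  n_probe <- round(fractions[3] * M)
  n_learn <- round(fractions[2] * M)
  if (n_probe < 1L) stop("probe fraction selects no edges")
  perm <- sample.int(M)
  probe <- ed[perm[seq_len(n_probe)], , drop = FALSE]
  learn <- ed[perm[n_probe + seq_len(n_learn)], , drop = FALSE]
  train <- ed[perm[-seq_len(n_probe + n_learn)], , drop = FALSE]
  rownames(train) <- rownames(learn) <- rownames(probe) <- NULL
  out <- list(train = train, learn = learn, probe = probe,
              L = n_probe, nodes = igraph::V(g)$name,
              fractions = fractions, seed = seed)
  class(out) <- "edge_split"
  out
}

#' Training graph of a split
#'
#' Rebuilds the graph on the full node set (nodes isolated by the split stay
#' in the candidate universe) from the training edges, optionally merged
#' with the learning edges.
#'
#' @param split an `edge_split`.
#' @param include_learn merge the learning edges into the graph.
#' @return an undirected igraph.
#' @export
train_graph <- function(split, include_learn = FALSE) {
  ed <- split$train
  if (include_learn && nrow(split$learn) > 0L) ed <- rbind(ed, split$learn)
  graph_from_edges(ed, nodes = split$nodes)
}

# positions and tie labels of a ranking; two entries are tied when they come
# from the same source list with equal score (arbitrary internal order)
ranking_tiers <- function(ranking) {
  n <- nrow(ranking)
  if (!is.null(ranking$score)) {
    src <- if (is.null(ranking$source)) "" else ranking$source
    paste(src, ranking$score)
  } else {
    as.character(seq_len(n))
  }
}

# number of (a, b) pairs with a < b, counting via midranks (0.5 per tie);
# positions here are distinct so no position ties occur
count_below <- function(pa, pb) {
  la <- length(pa)
  lb <- length(pb)
  r <- rank(c(pa, pb))
  gt <- sum(r[seq_len(la)]) - la * (la + 1) / 2 # pairs with pa > pb
  la * lb - gt
}

#' Exhaustive AUC of a ranking
#'
#' The probability that a probe (true missing) link is ranked above a
#' nonexistent link, computed over all probe x nonexistent comparisons:
#' AUC = (n' + 0.5 n'') / n, with n' strictly-higher comparisons and n''
#' ties. Two entries are tied when they are equal-score entries of the same
#' source list (their internal order is an arbitrary tie-break); this is the
#' deterministic limit of the usual n-sample comparison estimator.
#'
#' @param ranking ranked data.frame (columns `u`, `v`, optionally `score`
#'   and `source`).
#' @param probe edge data.frame of true missing links.
#' @param nonexistent edge data.frame of pairs absent from the true network.
#' @return AUC in \[0, 1\].
#' @export
auc_exhaustive <- function(ranking, probe, nonexistent) {
  if (nrow(probe) == 0L) stop("empty probe set")
  if (nrow(nonexistent) == 0L) stop("empty nonexistent set")
  key <- edge_keys(ranking)
  ip <- match(edge_keys(probe), key)
  ix <- match(edge_keys(nonexistent), key)
  if (anyNA(ip) || anyNA(ix))
    stop("probe/nonexistent pair missing from the ranking")
  tiers <- ranking_tiers(ranking)
  pos <- seq_len(nrow(ranking))
  pa <- pos[ip]
  pb <- pos[ix]
  n_strict <- count_below(pa, pb)
  n_tie <- 0
  tp <- tiers[ip]
  tx <- tiers[ix]
  for (tt in intersect(unique(tp), unique(tx))) {
    qa <- pa[tp == tt]
    qb <- pb[tx == tt]
    # inside a tie group the positional comparison is arbitrary: replace it
    n_strict <- n_strict - count_below(qa, qb)
    n_tie <- n_tie + length(qa) * length(qb)
  }
  (n_strict + 0.5 * n_tie) / (length(pa) * length(pb))
}

#' Sampled AUC estimator
#'
#' The classic estimator: `n` random (probe, nonexistent) comparisons, with
#' 1 for a win and 0.5 for a tie. Converges to [auc_exhaustive()] as n grows.
#'
#' @inheritParams auc_exhaustive
#' @param n number of sampled comparisons.
#' @param seed optional seed.
#' @export
auc_sampled <- function(ranking, probe, nonexistent, n = 1e5, seed = NULL) {
  if (nrow(probe) == 0L) stop("empty probe set")
  if (nrow(nonexistent) == 0L) stop("empty nonexistent set")
  if (!is.null(seed)) set.seed(seed)
  key <- edge_keys(ranking)
  ip <- match(edge_keys(probe), key)
  ix <- match(edge_keys(nonexistent), key)
  if (anyNA(ip) || anyNA(ix))
    stop("probe/nonexistent pair missing from the ranking")
  tiers <- ranking_tiers(ranking)
  sp <- ip[sample.int(length(ip), n, replace = TRUE)]
  sx <- ix[sample.int(length(ix), n, replace = TRUE)]
  tie <- tiers[sp] == tiers[sx]
  (sum(!tie & sp < sx) + 0.5 * sum(tie)) / n
}

#' Precision of the top-L predictions
#'
#' Fraction of the first `L` ranked pairs that are true (probe) links.
#' `L` defaults to the probe size, the usual "number of missing links".
#'
#' @inheritParams auc_exhaustive
#' @param L depth of the ranking to inspect (>= 1).
#' @export
precision_at_L <- function(ranking, probe, L = nrow(probe)) {
  if (L < 1L) stop("L must be >= 1")
  if (L > nrow(ranking)) stop("L exceeds ranking length")
  top <- edge_keys(ranking[seq_len(L), , drop = FALSE])
  sum(top %in% edge_keys(probe)) / L
}

#' Mean betweenness of predicted links after insertion
#'
#' Adds all predicted links to the training graph at once, computes edge
#' betweenness under the ordered-pair convention of
#' [edge_betweenness_pairs()], and averages over the predicted links only.
#' High values mean the predictions carry shortest-path traffic, as
#' inter-community bridges do.
#'
#' @param g_train training graph.
#' @param predicted data.frame of predicted pairs (must not already be
#'   edges).
#' @return mean betweenness of the inserted links.
#' @export
mean_predicted_betweenness <- function(g_train, predicted) {
  if (nrow(predicted) == 0L) stop("no predicted links")
  g2 <- add_links(g_train, predicted)
  b <- igraph::edge_betweenness(g2, directed = FALSE) * 2
  m <- igraph::ecount(g_train)
  mean(b[(m + 1L):igraph::ecount(g2)])
}

# insert pair rows as new edges, preserving insertion order
add_links <- function(g, pairs) {
  if (nrow(pairs) == 0L) return(g)
  miss <- setdiff(unique(c(pairs$u, pairs$v)), igraph::V(g)$name)
  if (length(miss) > 0L) stop("unknown node: ", miss[1L])
  if (any(edge_keys(pairs) %in% edge_keys(as_edge_df(g))))
    stop("a predicted pair is already an edge")
  igraph::add_edges(g, rbind(pairs$u, pairs$v))
}

#' Intra/inter composition of a prediction list
#'
#' @param predicted ranked data.frame of predicted links.
#' @param probe edge data.frame of true missing links.
#' @param membership named community vector covering all endpoints.
#' @return list with counts `n_intra_pred`, `n_inter_pred`,
#'   `n_intra_correct`, `n_inter_correct`.
#' @export
intra_inter_counts <- function(predicted, probe, membership) {
  if (nrow(predicted) == 0L)
    return(list(n_intra_pred = 0L, n_inter_pred = 0L,
                n_intra_correct = 0L, n_inter_correct = 0L))
  cls <- classify_pairs(membership, predicted)
  hit <- edge_keys(predicted) %in% edge_keys(probe)
  list(n_intra_pred = sum(cls == "intra"),
       n_inter_pred = sum(cls == "inter"),
       n_intra_correct = sum(cls == "intra" & hit),
       n_inter_correct = sum(cls == "inter" & hit))
}

# candidate pairs of g_train that are in none of the supplied true-link sets
nonexistent_pairs <- function(candidates, ...) {
  truth <- unlist(lapply(list(...), function(e) {
    if (is.null(e) || nrow(e) == 0L) character(0) else edge_keys(e)
  }))
  candidates[!(edge_keys(candidates) %in% truth), , drop = FALSE]
}

#' Evaluate a link-prediction method by repeated random splits
#'
#' For each replicate the edge set is split train/probe, the method ranks
#' the training graph's non-adjacent pairs, and AUC (exhaustive), precision
#' at L = |probe|, the mean inserted-link betweenness and the intra/inter
#' composition are recorded.
#'
#' @param g the observed (true) network.
#' @param method `"CN"`, `"RA"`, `"CBCN"` or `"CBRA"`.
#' @param beta interleaving parameter for the community-based methods.
#' @param probe_frac fraction of edges held out as probe.
#' @param reps number of independent splits.
#' @param seed optional base seed; replicate r uses `seed + r`.
#' @return object of class `evaluation_report`: per-replicate data.frame
#'   plus mean/sd summary.
#' @export
evaluate_method <- function(g, method = c("CN", "RA", "CBCN", "CBRA"),
                            beta = 1, probe_frac = 0.1, reps = 10L,
                            seed = NULL) {
  method <- match.arg(method)
  base <- if (method %in% c("CN", "CBCN")) "CN" else "RA"
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    s <- if (is.null(seed)) NULL else seed + r
    sp <- split_edges(g, c(1 - probe_frac, 0, probe_frac), seed = s)
    gt <- train_graph(sp)
    partition <- detect_communities(gt)
    scored <- score_candidates(gt, base)
    ranking <- rank_candidates(scored, method, beta, gt, partition)
    nonex <- nonexistent_pairs(scored, sp$probe)
    pred <- utils::head(ranking, sp$L)
    cnt <- intra_inter_counts(pred, sp$probe, partition)
    rows[[r]] <- data.frame(
      rep = r,
      auc = auc_exhaustive(ranking, sp$probe, nonex),
      precision = precision_at_L(ranking, sp$probe, sp$L),
      mean_B = mean_predicted_betweenness(gt, pred),
      n_intra_pred = cnt$n_intra_pred,
      n_inter_pred = cnt$n_inter_pred,
      n_intra_correct = cnt$n_intra_correct,
      n_inter_correct = cnt$n_inter_correct
    )
  }
  per_rep <- do.call(rbind, rows)
  metrics <- setdiff(names(per_rep), "rep")
  out <- list(
    method = method, beta = beta, probe_frac = probe_frac, reps = reps,
    seed = seed, per_rep = per_rep,
    mean = vapply(per_rep[metrics], mean, 0),
    sd = vapply(per_rep[metrics], stats::sd, 0)
  )
  class(out) <- "evaluation_report"
  out
}

#' @export
#' @method print evaluation_report
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Link prediction evaluation: %s (beta = %s, %d reps, probe %g%%)\n",
              x$method, format(x$beta), x$reps, 100 * x$probe_frac))
  for (m in names(x$mean))
    cat(sprintf("  %-16s %8.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
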