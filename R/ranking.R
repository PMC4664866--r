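# Ranking of scored candidate pairs and beta-interleaving of the
# intra-/inter-community lists.

#' Rank scored pairs by descending score
#'
#' Ties are broken by lexicographic order of the canonical (u, v) pair, so
#' the ranking is deterministic.
#'
#' @param scored data.frame with columns `u`, `v`, `score`
#'   (see [score_candidates()]).
#' @return the same data.frame ordered by decreasing score (rank 1 first).
#' @export
rank_descending <- function(scored) {
  if (nrow(scored) == 0L) return(scored)
  u <- pmin(scored$u, scored$v)
  v <- pmax(scored$u, scored$v)
  scored$u <- u
  scored$v <- v
  out <- scored[order(-scored$score, u, v, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interleave the intra- and inter-community rankings
#'
#' Builds the combined prediction list R: at each step the head of the
#' intra-community list is appended with probability `beta`, otherwise the
#' head of the inter-community list; once a list is exhausted the other is
#' drained. beta = 1 puts all intra-community candidates first, beta = 0 all
#' inter-community candidates first (both cases are deterministic and leave
#' the RNG untouched). The relative order within each source list is always
#' preserved.
#'
#' @param r_intra,r_inter ranked data.frames (columns `u`, `v`, `score`);
#'   must be disjoint.
#' @param beta probability of drawing from the intra list, in \[0, 1\].
#' @param seed optional integer seed for the draw sequence.
#' @return data.frame with columns `u`, `v`, `score` and `source`
#'   ("intra"/"inter").
#' @export
interleave <- function(r_intra, r_inter, beta, seed = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1)
    stop("beta must be a single probability in [0, 1]")
  tag <- function(df, s) {
    if (nrow(df) == 0L)
      return(data.frame(u = character(0), v = character(0),
                        score = numeric(0), source = character(0),
                        stringsAsFactors = FALSE))
    data.frame(u = df$u, v = df$v, score = df$score, source = s,
               stringsAsFactors = FALSE)
  }
  a <- tag(r_intra, "intra")
  b <- tag(r_inter, "inter")
  n1 <- nrow(a)
  n2 <- nrow(b)
  n <- n1 + n2
  if (n == 0L) return(a)
  if (beta == 1 || n2 == 0L) {
    out <- rbind(a, b)
  } else if (beta == 0 || n1 == 0L) {
    out <- rbind(b, a)
  } else {
    if (!is.null(seed)) set.seed(seed)
    pick <- stats::runif(n) < beta          # TRUE = attempt intra draw
    ta <- cumsum(pick)
    tb <- cumsum(!pick)
    bad <- which(ta > n1 | tb > n2)
    if (length(bad) > 0L) {
      k <- bad[1L]
      drained_intra <- ta[k] > n1           # intra ran out first
      pick[k:n] <- !drained_intra
    }
    out <- rbind(a, b)[order(c(which(pick), which(!pick))), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Top-L link predictions for a training graph
#'
#' For the plain similarity methods (CN, RA) this is the head of the global
#' descending-score ranking. For the community-based methods (CBCN, CBRA)
#' the candidates are first classified as intra- or inter-community using a
#' partition detected on the training graph, ranked separately, and merged
#' by beta-interleaving.
#'
#' @param g_train training graph (undirected igraph, named vertices).
#' @param method one of `"CN"`, `"RA"`, `"CBCN"`, `"CBRA"`.
#' @param beta interleaving probability (ignored for CN/RA).
#' @param L number of predictions to return; if `L` exceeds the candidate
#'   count, all candidates are returned.
#' @param seed optional seed (community detection + interleaving).
#' @param partition optional precomputed partition of `g_train`; detected
#'   with [detect_communities()] when missing.
#' @return ranked data.frame of at most `L` rows.
#' @export
predict_top_L <- function(g_train, method = c("CN", "RA", "CBCN", "CBRA"),
                          beta = 1, L = NULL, seed = NULL, partition = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  base <- if (method %in% c("CN", "CBCN")) "CN" else "RA"
  scored <- score_candidates(g_train, base)
  full <- rank_candidates(scored, method, beta, g_train, partition)
  if (is.null(L)) L <- nrow(full)
  if (L < 0) stop("L must be >= 0")
  utils::head(full, L)
}

# shared ranking path: plain descending sort or community-based interleave
rank_candidates <- function(scored, method, beta, g_train, partition = NULL) {
  if (method %in% c("CN", "RA")) return(rank_descending(scored))
  if (is.null(partition)) partition <- detect_communities(g_train)
  cls <- classify_pairs(partition, scored)
  interleave(rank_descending(scored[cls == "intra", , drop = FALSE]),
             rank_descending(scored[cls == "inter", , drop = FALSE]),
             beta)
}
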