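# Learning the interleaving parameter beta from held-out links.

#' AUC and mean inserted-link betweenness as functions of beta
#'
#' For every beta on the grid, the intra/inter candidate lists of the
#' training graph are interleaved `reps` times (replicate r re-seeded
#' deterministically as `seed + r`), and the AUC against the held-out links
#' and the mean betweenness of the top-|held_out| predictions after
#' insertion are averaged. beta in {0, 1} is deterministic, so those grid
#' points have zero variance across replicates.
#'
#' @param g_train training graph.
#' @param held_out edge data.frame of held-out true links (probe or learning
#'   set) used as the positive class.
#' @param method `"CBCN"` or `"CBRA"`.
#' @param grid increasing beta values in \[0, 1\].
#' @param reps interleaving replicates per grid point.
#' @param seed optional base seed (community detection + replicates).
#' @param partition optional precomputed partition of `g_train`.
#' @param nonexistent optional data.frame of negative-class pairs; defaults
#'   to all candidates of `g_train` not in `held_out`.
#' @return object of class `beta_curve`: data.frame with columns `beta`,
#'   `auc`, `mean_B`, plus metadata attributes.
#' @export
beta_curve <- function(g_train, held_out, method = c("CBCN", "CBRA"),
                       grid = seq(0, 1, by = 0.01), reps = 10L, seed = NULL,
                       partition = NULL, nonexistent = NULL) {
  method <- match.arg(method)
  if (nrow(held_out) == 0L) stop("empty held-out set")
  if (any(grid < 0 | grid > 1) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing within [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  base <- if (method == "CBCN") "CN" else "RA"
  if (is.null(partition)) partition <- detect_communities(g_train)
  scored <- score_candidates(g_train, base)
  if (is.null(nonexistent)) nonexistent <- nonexistent_pairs(scored, held_out)
  cls <- classify_pairs(partition, scored)
  r_intra <- rank_descending(scored[cls == "intra", , drop = FALSE])
  r_inter <- rank_descending(scored[cls == "inter", , drop = FALSE])
  L <- nrow(held_out)
  auc_m <- mb_m <- numeric(length(grid))
  for (i in seq_along(grid)) {
    b <- grid[i]
    nr <- if (b == 0 || b == 1) 1L else reps
    av <- mv <- numeric(nr)
    for (r in seq_len(nr)) {
      s <- if (is.null(seed)) NULL else seed + r
      rk <- interleave(r_intra, r_inter, b, seed = s)
      av[r] <- auc_exhaustive(rk, held_out, nonexistent)
      mv[r] <- mean_predicted_betweenness(g_train, utils::head(rk, L))
    }
    auc_m[i] <- mean(av)
    mb_m[i] <- mean(mv)
  }
  out <- data.frame(beta = grid, auc = auc_m, mean_B = mb_m)
  attr(out, "method") <- method
  attr(out, "reps") <- reps
  attr(out, "L") <- L
  class(out) <- c("beta_curve", "data.frame")
  out
}

#' Beta whose mean inserted-link betweenness matches a target
#'
#' Picks the grid point minimising |<B>(beta) - target_B|; ties are broken
#' toward the larger beta (the higher-AUC side).
#'
#' @param curve a [beta_curve()].
#' @param target_B target mean betweenness, typically that of the held-out
#'   true links when added to the training graph.
#' @return a beta value from the curve's grid.
#' @export
estimate_beta_star <- function(curve, target_B) {
  if (nrow(curve) == 0L) stop("empty curve")
  d <- abs(curve$mean_B - target_B)
  max(curve$beta[d <= min(d) + 1e-12])
}

#' Accuracy-constrained choice of beta
#'
#' The betweenness-matching beta of [estimate_beta_star()] is kept only if
#' its AUC on the curve stays above `(1 - sacrifice) * auc_o`, where `auc_o`
#' is the AUC of the plain similarity method on the same split. Otherwise
#' the smallest beta whose AUC reaches that floor is returned (AUC grows
#' with beta, so the constraint can only pull beta upward).
#'
#' @param curve a [beta_curve()].
#' @param auc_o AUC of the original (CN/RA) method on the same data.
#' @param target_B betweenness target passed to [estimate_beta_star()].
#' @param sacrifice maximal tolerated relative AUC loss, in (0, 1);
#'   default 0.1.
#' @return a beta value from the curve's grid.
#' @export
constrained_beta <- function(curve, auc_o, target_B, sacrifice = 0.1) {
  if (sacrifice <= 0 || sacrifice >= 1)
    stop("sacrifice must be in (0, 1)")
  floor_auc <- (1 - sacrifice) * auc_o
  b_match <- estimate_beta_star(curve, target_B)
  auc_match <- curve$auc[match(b_match, curve$beta)]
  if (auc_match >= floor_auc - 1e-12) return(b_match)
  ok <- which(curve$auc >= floor_auc - 1e-12)
  if (length(ok) == 0L) return(curve$beta[which.max(curve$auc)])
  curve$beta[min(ok)]
}

#' Learn beta by threefold validation
#'
#' The edge set is split into training, learning and probe parts (default
#' 80/10/10). The learning links stand in for the unknown missing links:
#' their mean betweenness when added to the training graph is the target,
#' and the beta curve is computed on the training graph against the
#' learning set. The probe set is never inspected; during learning, probe
#' pairs are indistinguishable from nonexistent pairs. Returns both the
#' matching estimate and its accuracy-constrained variant.
#'
#' @param g the observed network.
#' @param method `"CBCN"` or `"CBRA"`.
#' @param fractions `(train, learn, probe)` fractions; learn must be > 0.
#' @param grid,reps passed to [beta_curve()].
#' @param sacrifice constraint strength, see [constrained_beta()].
#' @param seed optional integer seed (controls the split, the partition and
#'   the interleaving replicates).
#' @param split optional precomputed `edge_split` (overrides `fractions`).
#' @return object of class `beta_fit`: list with `beta_hat`,
#'   `constrained_beta`, `target_B`, `auc_o`, the `curve`, the `split` and
#'   the `partition` used.
#' @export
learn_beta_hat <- function(g, method = c("CBCN", "CBRA"),
                           fractions = c(0.8, 0.1, 0.1),
                           grid = seq(0, 1, by = 0.01), reps = 10L,
                           sacrifice = 0.1, seed = NULL, split = NULL) {
  method <- match.arg(method)
  if (is.null(split)) {
    if (fractions[2] <= 0) stop("learning fraction must be > 0")
    split <- split_edges(g, fractions, seed = seed)
  } else if (nrow(split$learn) == 0L) {
    stop("split has an empty learning set")
  }
  g_t <- train_graph(split)
  if (!is.null(seed)) set.seed(seed)
  partition <- detect_communities(g_t)
  base <- if (method == "CBCN") "CN" else "RA"
  scored <- score_candidates(g_t, base)
  nonex <- nonexistent_pairs(scored, split$learn) # probe stays "unknown"
  target_B <- mean_predicted_betweenness(g_t, split$learn)
  curve <- beta_curve(g_t, split$learn, method, grid = grid, reps = reps,
                      seed = seed, partition = partition,
                      nonexistent = nonex)
  auc_o <- auc_exhaustive(rank_descending(scored), split$learn, nonex)
  out <- list(
    beta_hat = estimate_beta_star(curve, target_B),
    constrained_beta = constrained_beta(curve, auc_o, target_B, sacrifice),
    target_B = target_B, auc_o = auc_o, sacrifice = sacrifice,
    method = method, curve = curve, split = split, partition = partition,
    seed = seed
  )
  class(out) <- "beta_fit"
  out
}

#' @export
#' @method print beta_fit
print.beta_fit <- function(x, ...) {
  cat(sprintf("Learned interleaving parameter (%s)\n", x$method))
  cat(sprintf("  beta_hat (matches <B> = %.2f) : %.2f\n",
              x$target_B, x$beta_hat))
  cat(sprintf("  constrained beta (<= %g%% AUC loss vs %.4f): %.2f\n",
              100 * x$sacrifice, x$auc_o, x$constrained_beta))
  invisible(x)
}

#' Oracle beta using probe knowledge
#'
#' The hindsight value of beta: a plain train/probe split where the target
#' betweenness is computed from the probe links themselves. Used as the
#' reference that the threefold-validation estimate should recover.
#'
#' @inheritParams learn_beta_hat
#' @param probe_frac probe fraction of the 2-way split.
#' @return list with `beta_star`, `target_B`, the `curve` and the `split`.
#' @export
oracle_beta_star <- function(g, method = c("CBCN", "CBRA"), probe_frac = 0.1,
                             grid = seq(0, 1, by = 0.01), reps = 10L,
                             seed = NULL) {
  method <- match.arg(method)
  split <- split_edges(g, c(1 - probe_frac, 0, probe_frac), seed = seed)
  g_t <- train_graph(split)
  if (!is.null(seed)) set.seed(seed)
  target_B <- mean_predicted_betweenness(g_t, split$probe)
  curve <- beta_curve(g_t, split$probe, method, grid = grid, reps = reps,
                      seed = seed)
  list(beta_star = estimate_beta_star(curve, target_B),
       target_B = target_B, curve = curve, split = split)
}
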