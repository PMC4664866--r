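ten_edge_graph <- function() {
  graph_from_edges(edge_df("a", "b", "b", "c", "c", "d", "d", "e", "e", "a",
                           "a", "c", "b", "d", "c", "e", "d", "a", "e", "b"))
}

test_that("edge splits have the rounded sizes and partition the edge set", {
  g <- ten_edge_graph()
  s <- split_edges(g, c(0.9, 0, 0.1), seed = 1)
  expect_equal(nrow(s$train), 9)
  expect_equal(nrow(s$probe), 1)
  expect_equal(s$L, 1)

  s3 <- split_edges(g, c(0.8, 0.1, 0.1), seed = 2)
  expect_equal(vapply(s3[c("train", "learn", "probe")], nrow, 1L),
               c(train = 8L, learn = 1L, probe = 1L))
  keys <- unlist(lapply(s3[c("train", "learn", "probe")],
                        function(e) paste(pmin(e$u, e$v), pmax(e$u, e$v))))
  expect_equal(sort(unname(keys)),
               sort(paste(pmin(igraph::as_edgelist(g)[, 1],
                               igraph::as_edgelist(g)[, 2]),
                          pmax(igraph::as_edgelist(g)[, 1],
                               igraph::as_edgelist(g)[, 2]))))

  expect_identical(split_edges(g, seed = 7)$probe, split_edges(g, seed = 7)$probe)
  expect_false(identical(split_edges(g, seed = 7)$probe,
                         split_edges(g, seed = 8)$probe))
  expect_error(split_edges(g, c(0.5, 0.1, 0.1)), "sum to 1")
})

test_that("training graph keeps nodes isolated by the split", {
  g <- g_path_abc()
  s <- split_edges(g, c(0.5, 0, 0.5), seed = 3)
  gt <- train_graph(s)
  expect_setequal(igraph::V(gt)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(gt), 1)
})

test_that("exhaustive AUC matches hand enumeration and handles ties", {
  rk <- data.frame(u = c("p", "x", "q", "y"), v = rep("z", 4))
  p <- data.frame(u = c("p", "q"), v = c("z", "z"))
  x <- data.frame(u = c("x", "y"), v = c("z", "z"))
  expect_equal(auc_exhaustive(rk, p, x), 3 / 4) # (1 + 1 + 0.5*0 + 1)/4... enumerated: p1 beats both, p2 beats y only

  # perfect ranking and all-tied ranking
  rk2 <- data.frame(u = c("p", "q", "x", "y"), v = rep("z", 4),
                    score = c(5, 4, 3, 2))
  expect_equal(auc_exhaustive(rk2, p, x), 1)
  rk3 <- data.frame(u = c("p", "x", "q", "y"), v = rep("z", 4),
                    score = rep(1, 4))
  expect_equal(auc_exhaustive(rk3, p, x), 0.5)
  expect_error(auc_exhaustive(rk, p[0, ], x), "empty probe")
  expect_error(auc_exhaustive(rk, p, data.frame(u = "k", v = "z")),
               "missing from the ranking")
})

test_that("sampled AUC converges to the exhaustive value", {
  g <- karate_graph()
  s <- split_edges(g, seed = 5)
  gt <- train_graph(s)
  rk <- rank_descending(score_candidates(gt, "RA"))
  nonex <- rk[!(paste(rk$u, rk$v) %in% paste(s$probe$u, s$probe$v)), c("u", "v")]
  exact <- auc_exhaustive(rk, s$probe, nonex)
  n <- 1e5
  est <- auc_sampled(rk, s$probe, nonex, n = n, seed = 1)
  se <- sqrt(exact * (1 - exact) / n)
  expect_lt(abs(est - exact), 3 * se + 1e-12)
})

test_that("AUC and precision are invariant to node relabelling", {
  g <- karate_graph()
  s <- split_edges(g, seed = 11)
  gt <- train_graph(s)
  rk <- rank_descending(score_candidates(gt, "CN"))
  nonex <- rk[!(paste(rk$u, rk$v) %in% paste(s$probe$u, s$probe$v)), c("u", "v")]
  a1 <- auc_exhaustive(rk, s$probe, nonex)
  p1 <- precision_at_L(rk, s$probe)

  relab <- function(x) paste0("node_", x)
  g2 <- graph_from_edges(data.frame(u = relab(s$train$u), v = relab(s$train$v)),
                         nodes = relab(igraph::V(g)$name))
  rk2 <- rank_descending(score_candidates(g2, "CN"))
  probe2 <- data.frame(u = relab(s$probe$u), v = relab(s$probe$v))
  nonex2 <- data.frame(u = relab(nonex$u), v = relab(nonex$v))
  expect_equal(auc_exhaustive(rk2, probe2, nonex2), a1)
  expect_equal(precision_at_L(rk2, probe2), p1)
})

test_that("precision counts hits in the top of the list", {
  rk <- data.frame(u = c("a", "b", "c", "d"), v = rep("z", 4))
  probe_all <- rk[1:2, ]
  expect_equal(precision_at_L(rk, probe_all, 2), 1)
  expect_equal(precision_at_L(rk, data.frame(u = "q", v = "z"), 2), 0)
  expect_equal(precision_at_L(rk, rk[c(1, 2, 4), ], 4), 0.75)
  expect_error(precision_at_L(rk, probe_all, 0), "L must be")
})

test_that("mean inserted-link betweenness matches hand-enumerated cases", {
  bridge <- data.frame(u = "c", v = "d")
  expect_equal(mean_predicted_betweenness(g_two_triangles(), bridge), 18)

  open <- graph_from_edges(edge_df("a", "c", "b", "c"))
  expect_equal(mean_predicted_betweenness(open, data.frame(u = "a", v = "b")), 2)

  # mean of two inserted links cross-checked against full enumeration
  g <- g_two_triangles()
  two <- data.frame(u = c("c", "a"), v = c("d", "e"))
  g2 <- reconstruct(g, two)
  ed2 <- as.data.frame(igraph::as_edgelist(g2))
  names(ed2) <- c("u", "v")
  oracle <- oracle_betweenness(ed2, igraph::V(g2)$name)
  keys <- paste(pmin(two$u, two$v), pmax(two$u, two$v), sep = "|")
  expect_equal(mean_predicted_betweenness(g, two),
               mean(oracle$edge[keys]), tolerance = 1e-10)
  expect_error(mean_predicted_betweenness(g, two[0, ]), "no predicted")
  expect_error(mean_predicted_betweenness(g, data.frame(u = "a", v = "b")),
               "already an edge")
})

test_that("intra/inter composition counts are consistent", {
  memb <- stats::setNames(rep(1:2, each = 3), c("a", "b", "c", "d", "e", "f"))
  pred <- data.frame(u = c("a", "a", "d"), v = c("b", "d", "f"))
  probe <- data.frame(u = c("a", "x"), v = c("b", "y"))
  cnt <- intra_inter_counts(pred, probe, memb)
  expect_equal(cnt, list(n_intra_pred = 2L, n_inter_pred = 1L,
                         n_intra_correct = 1L, n_inter_correct = 0L))
  all_intra <- intra_inter_counts(pred[c(1, 3), ], probe[0, ], memb)
  expect_equal(all_intra$n_intra_correct + all_intra$n_inter_correct, 0L)
})
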