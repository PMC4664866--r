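synthetic_curve <- function(beta = seq(0, 1, by = 0.1),
                            auc = seq(0.5, 0.9, length.out = 11),
                            mean_B = seq(60, 20, length.out = 11)) {
  structure(data.frame(beta = beta, auc = auc, mean_B = mean_B),
            class = c("beta_curve", "data.frame"))
}

test_that("betweenness matching picks the nearest grid point", {
  cv <- synthetic_curve()
  expect_equal(estimate_beta_star(cv, 100), 0)  # target above <B>(0)
  expect_equal(estimate_beta_star(cv, 5), 1)    # target below <B>(1)
  expect_equal(estimate_beta_star(cv, 40.1), 0.5)
  # exact midpoint between two grid values breaks toward larger beta
  expect_equal(estimate_beta_star(cv, 42), 0.5)
})

test_that("the accuracy constraint only ever raises beta", {
  cv <- synthetic_curve()
  # matching beta 0.5 has auc 0.7; floor 0.9*0.7 = 0.63 -> inactive
  expect_equal(constrained_beta(cv, auc_o = 0.70, target_B = 40, 0.1), 0.5)
  # floor 0.9*0.88 = 0.792 > auc(0.5): first grid point reaching the floor
  expect_equal(constrained_beta(cv, auc_o = 0.88, target_B = 40, 0.1), 0.8)
  # near-total sacrifice deactivates the constraint
  expect_equal(constrained_beta(cv, auc_o = 0.88, target_B = 40, 0.99), 0.5)
  expect_error(constrained_beta(cv, 0.8, 40, sacrifice = 0), "sacrifice")
  for (s in c(0.05, 0.1, 0.3)) {
    b <- constrained_beta(cv, auc_o = 0.9, target_B = 40, s)
    expect_gte(b, estimate_beta_star(cv, 40))
  }
})

test_that("curve endpoints are deterministic and learning is reproducible", {
  pg <- generate_gn(k_in = 14, seed = 21)
  s <- split_edges(pg$graph, c(0.8, 0.1, 0.1), seed = 21)
  gt <- train_graph(s)
  c1 <- beta_curve(gt, s$learn, "CBCN", grid = c(0, 1), reps = 3, seed = 5)
  c2 <- beta_curve(gt, s$learn, "CBCN", grid = c(0, 1), reps = 3, seed = 6)
  expect_equal(c1$auc, c2$auc)      # beta in {0,1} ignores the seed
  expect_equal(c1$mean_B, c2$mean_B)
  expect_error(beta_curve(gt, s$learn[0, ], "CBCN"), "empty held-out")

  f1 <- learn_beta_hat(pg$graph, "CBCN", grid = seq(0, 1, 0.25),
                       reps = 3, seed = 9)
  f2 <- learn_beta_hat(pg$graph, "CBCN", grid = seq(0, 1, 0.25),
                       reps = 3, seed = 9)
  expect_equal(f1$beta_hat, f2$beta_hat)
  expect_equal(f1$curve$auc, f2$curve$auc)
})

test_that("a single-community graph yields a flat curve and the tie-break", {
  g <- clique_graph(paste0("v", 1:7))
  ed <- as.data.frame(igraph::as_edgelist(g))
  names(ed) <- c("u", "v")
  s <- split_edges(g, c(0.8, 0.1, 0.1), seed = 3)
  fit <- learn_beta_hat(g, "CBCN", grid = seq(0, 1, 0.5), reps = 2, seed = 3)
  # no inter-community candidates: every beta gives the same list
  expect_equal(length(unique(fit$curve$mean_B)), 1)
  expect_equal(fit$beta_hat, 1) # ties resolve toward the high-AUC end
})

test_that("the learner never inspects the probe set", {
  pg <- generate_gn(k_in = 14, seed = 33)
  s <- split_edges(pg$graph, c(0.8, 0.1, 0.1), seed = 33)
  fit <- learn_beta_hat(pg$graph, "CBCN", grid = seq(0, 1, 0.5), reps = 2,
                        seed = 33, split = s)
  # swapping the probe set for a disjoint one changes nothing upstream
  s2 <- s
  s2$probe <- data.frame(u = "1", v = "128") # any non-edge pair
  fit2 <- learn_beta_hat(pg$graph, "CBCN", grid = seq(0, 1, 0.5), reps = 2,
                         seed = 33, split = s2)
  expect_equal(fit$beta_hat, fit2$beta_hat)
  expect_equal(fit$curve$auc, fit2$curve$auc)
  expect_equal(fit$auc_o, fit2$auc_o)
})
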