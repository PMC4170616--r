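test_that("config validation and zero-weight forward pass", {
  expect_error(mlp_config(hidden_nodes = 0), "hidden_nodes")
  expect_error(mlp_config(learning_rate = 0), "learning_rate")
  expect_error(mlp_config(split = c(train = 0.5, test = 0.5, validation = 0.5)),
               "sum to 1")
  ## with all-zero weights the sigmoid output is exactly 0.5 everywhere
  w <- list(W1 = matrix(0, 2, 3), b1 = c(0, 0), w2 = c(0, 0), b2 = 0)
  out <- gliosig:::mlp_forward(w, matrix(rnorm(30), 10, 3))$yhat
  expect_equal(out, rep(0.5, 10))
})

test_that("backpropagation gradients match central finite differences", {
  withr::with_seed(13, {
    X <- matrix(rnorm(8 * 4), 8, 4)
    y <- runif(8)
  })
  w <- gliosig:::mlp_init(4, 3, seed = 5)
  g <- gliosig:::mlp_gradients(w, X, y)
  eps <- 1e-6
  for (nm in c("W1", "b1", "w2", "b2")) {
    num <- w[[nm]] * 0
    for (i in seq_along(w[[nm]])) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num[i] <- (gliosig:::mlp_gradients(wp, X, y)$loss -
                   gliosig:::mlp_gradients(wm, X, y)$loss) / (2 * eps)
    }
    expect_lt(max(abs(num - g[[nm]])), 1e-6)
  }
})

test_that("a 2-hidden-node net separates the XOR pattern", {
  X <- scale(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2))
  y <- c(0, 1, 1, 0)
  solved <- vapply(1:10, function(s) {
    m <- train_mlp(X, y, mlp_config(hidden_nodes = 2, max_epochs = 5000,
                                    momentum = 0.9, seed = s), seed = s)
    sqrt(mean((mlp_predict(m, X) - y)^2)) < 0.1
  }, logical(1))
  expect_gte(sum(solved), 8)
})

test_that("training is deterministic and early stopping respects patience", {
  withr::with_seed(17, {
    X <- matrix(rnorm(60), 30, 2)
    y <- as.numeric(X[, 1] + 0.3 * rnorm(30) > 0)
  })
  cfg <- mlp_config(max_epochs = 200, patience = 10, seed = 3)
  m1 <- train_mlp(X[1:20, ], y[1:20], cfg, X[21:30, ], y[21:30])
  m2 <- train_mlp(X[1:20, ], y[1:20], cfg, X[21:30, ], y[21:30])
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$history, m2$history)
  expect_lte(m1$epochs, 200)
})

test_that("probe ranking: self-prediction wins, affine invariance, determinism", {
  co <- generate_cohort(cohort_spec(80, 8, seed = 27))
  cfg <- mlp_config(bootstraps = 5, max_epochs = 100, patience = 10, seed = 2)
  ## the target probe itself as a candidate predicts near-perfectly
  rk <- rank_probes_by_prediction(co$expression, "probe_0001", cfg,
                                  candidates = rownames(co$expression))
  expect_equal(rk$probe[1], "probe_0001")
  expect_lt(rk$mean_rmse[1], 0.25)
  ## affine rescaling of a candidate leaves its score unchanged
  expr2 <- co$expression
  expr2["probe_0002", ] <- 100 + 7 * expr2["probe_0002", ]
  rk2 <- rank_probes_by_prediction(expr2, "probe_0001", cfg,
                                   candidates = rownames(expr2))
  expect_equal(rk2$mean_rmse[rk2$probe == "probe_0002"],
               rk$mean_rmse[rk$probe == "probe_0002"], tolerance = 1e-10)
  ## full determinism of the stage
  rk3 <- rank_probes_by_prediction(co$expression, "probe_0001", cfg,
                                   candidates = rownames(co$expression))
  expect_identical(rk$mean_rmse, rk3$mean_rmse)
  expect_error(rank_probes_by_prediction(co$expression, "probe_0001", cfg,
                                         candidates = character()),
               "empty candidate")
})

test_that("interaction inference evaluates every ordered pair", {
  expect_equal(nrow(interaction_pairs(c("a", "b"))), 2)
  expect_equal(nrow(interaction_pairs(sprintf("p%03d", 1:200))), 39800)
  co <- generate_cohort(cohort_spec(60, 4, seed = 3))
  cfg <- mlp_config(bootstraps = 2, max_epochs = 50, patience = 10, seed = 1)
  net <- infer_pairwise_interactions(co$expression, cfg)
  expect_equal(nrow(net$edges), 4 * 3)
  expect_false(any(net$edges$source == net$edges$target))
  ## deterministic re-run
  net2 <- infer_pairwise_interactions(co$expression, cfg)
  expect_identical(net$edges$weight, net2$edges$weight)
  expect_error(infer_pairwise_interactions(co$expression[1, , drop = FALSE],
                                           cfg), "at least 2")
})

test_that("edge pruning and hub detection follow the degree-5 rule", {
  ## star graph: center with 6 retained edges is the single hub
  star <- interaction_network(data.frame(
    source = paste0("leaf", 1:6), target = "center",
    weight = c(3, -2.5, 2, 1.5, 1, 0.5)))
  pr <- select_top_edges_and_hubs(star, top_k = 100, hub_degree = 5)
  expect_equal(pr$hubs$node, "center")
  expect_equal(pr$hubs$degree, 6)
  expect_equal(pr$hubs$strength, sum(abs(star$edges$weight)))

  ## exactly 4 incident edges is not a hub (strict >= 5)
  star4 <- interaction_network(data.frame(
    source = paste0("leaf", 1:4), target = "center", weight = rep(1, 4)))
  pr4 <- select_top_edges_and_hubs(star4, hub_degree = 5)
  expect_equal(nrow(pr4$hubs), 0)

  ## hub ranking matches a brute-force strength sort; pruning respects top_k
  withr::with_seed(41, {
    nodes <- paste0("n", 1:8)
    e <- interaction_pairs(nodes)
    e$weight <- rnorm(nrow(e))
  })
  net <- interaction_network(e)
  pr8 <- select_top_edges_and_hubs(net, top_k = 20, hub_degree = 5,
                                   n_top_hubs = 3)
  expect_equal(nrow(pr8$network$edges), 20)
  kept <- pr8$network$edges
  brute <- vapply(unique(c(kept$source, kept$target)), function(nd)
    sum(abs(kept$weight[kept$source == nd | kept$target == nd])), numeric(1))
  brute <- sort(brute[brute >= 0 &
                        table(c(kept$source, kept$target))[names(brute)] >= 5],
                decreasing = TRUE)
  expect_equal(pr8$hubs$node, names(brute))
  expect_equal(pr8$hubs$strength, unname(brute))
  expect_equal(sum(pr8$hubs$top), min(3, nrow(pr8$hubs)))

  ## hub set shrinks monotonically as the degree threshold grows
  h5 <- nrow(select_top_edges_and_hubs(net, top_k = 20, hub_degree = 5)$hubs)
  h7 <- nrow(select_top_edges_and_hubs(net, top_k = 20, hub_degree = 7)$hubs)
  expect_lte(h7, h5)
})
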