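#' Multilayer-perceptron configuration
#'
#' One-hidden-layer perceptron with sigmoidal transfer, trained by batch
#' (per-epoch) gradient descent with momentum. Defaults follow the
#' screening protocol used for the glioma interactome analysis: 2 hidden
#' nodes, learning rate 0.5, momentum 0.1, 60/20/20 Monte-Carlo
#' train/test/validation resampling over 50 bootstraps.
#'
#' @param hidden_nodes Hidden layer size (>= 1).
#' @param learning_rate,momentum Gradient-descent rates in (0, 1].
#' @param split Train/test/validation fractions summing to 1.
#' @param bootstraps Number of Monte-Carlo resamples.
#' @param max_epochs Epoch budget per training run.
#' @param patience Early-stopping patience on the test-split error.
#' @param seed Base seed; every resample and weight initialization is
#'   seeded deterministically from it.
#' @return List of class `mlp_config`.
#' @export
mlp_config <- function(hidden_nodes = 2, learning_rate = 0.5, momentum = 0.1,
                       split = c(train = 0.6, test = 0.2, validation = 0.2),
                       bootstraps = 50, max_epochs = 500, patience = 25,
                       seed = 1) {
  stop_if(hidden_nodes < 1, "mlp_config: hidden_nodes must be >= 1")
  stop_if(learning_rate <= 0 || learning_rate > 1,
          "mlp_config: learning_rate must be in (0, 1]")
  stop_if(momentum < 0 || momentum > 1, "mlp_config: momentum must be in [0, 1]")
  stop_if(abs(sum(split) - 1) > 1e-8, "mlp_config: split fractions must sum to 1")
  stop_if(bootstraps < 1 || max_epochs < 1 || patience < 1,
          "mlp_config: bootstraps, max_epochs, patience must be positive")
  structure(list(hidden_nodes = as.integer(hidden_nodes),
                 learning_rate = learning_rate, momentum = momentum,
                 split = split, bootstraps = as.integer(bootstraps),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "mlp_config")
}

## Forward pass. X: n x d. Returns hidden activations and outputs.
mlp_forward <- function(w, X) {
  Z <- sigmoid(sweep(X %*% t(w$W1), 2, w$b1, "+"))
  yhat <- as.numeric(sigmoid(Z %*% w$w2 + w$b2))
  list(Z = Z, yhat = yhat)
}

## Backpropagation gradient of the summed squared error
## E = 0.5 * sum_n (yhat - y)^2 (per-epoch deltas accumulated over the
## whole batch, classic batch backprop).
mlp_gradients <- function(w, X, y) {
  fw <- mlp_forward(w, X)
  err <- fw$yhat - y
  d_out <- err * fw$yhat * (1 - fw$yhat)            # n
  g_w2 <- as.numeric(crossprod(fw$Z, d_out))        # h
  g_b2 <- sum(d_out)
  d_hid <- (d_out %*% t(w$w2)) * fw$Z * (1 - fw$Z)  # n x h
  g_W1 <- crossprod(d_hid, X)                       # h x d
  g_b1 <- colSums(d_hid)
  list(W1 = g_W1, b1 = g_b1, w2 = g_w2, b2 = g_b2,
       loss = sum(err^2) / 2)
}

mlp_init <- function(d, h, seed) {
  withr::with_seed(seed, {
    list(W1 = matrix(stats::runif(h * d, -0.5, 0.5), h, d),
         b1 = stats::runif(h, -0.5, 0.5),
         w2 = stats::runif(h, -0.5, 0.5),
         b2 = stats::runif(1, -0.5, 0.5))
  })
}

#' Train a one-hidden-layer sigmoid perceptron
#'
#' Batch gradient descent on the mean-squared error with a momentum term;
#' weights are updated once per epoch. When a held-out test split is
#' supplied, training stops after `patience` epochs without improvement of
#' the test RMSE and the best-epoch weights are restored.
#'
#' @param inputs n x d numeric matrix; callers should standardize features
#'   (zero mean, unit sd).
#' @param targets Length-n values in \[0, 1\].
#' @param config An [mlp_config].
#' @param test_inputs,test_targets Optional held-out split for early
#'   stopping.
#' @param seed Seed for weight initialization (default `config$seed`).
#' @return List of class `mlp_model`: weights `W1`, `b1`, `w2`, `b2`,
#'   `history` (per-epoch train and test RMSE), `epochs`, `best_epoch`.
#' @export
train_mlp <- function(inputs, targets, config = mlp_config(),
                      test_inputs = NULL, test_targets = NULL,
                      seed = config$seed) {
  X <- as.matrix(inputs)
  y <- as.numeric(targets)
  stop_if(any(!is.finite(X)), "train_mlp: non-finite inputs")
  stop_if(any(y < 0 | y > 1), "train_mlp: targets must lie in [0, 1]")
  stop_if(nrow(X) != length(y), "train_mlp: input/target size mismatch")
  h <- config$hidden_nodes
  w <- mlp_init(ncol(X), h, seed)
  v <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, w2 = w$w2 * 0, b2 = 0)
  has_test <- !is.null(test_inputs)
  if (has_test) test_inputs <- as.matrix(test_inputs)
  best <- list(err = Inf, w = w, epoch = 0L)
  wait <- 0L
  hist_train <- numeric(0); hist_test <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    g <- mlp_gradients(w, X, y)
    stop_if(!is.finite(g$loss), "train_mlp: non-finite loss at epoch ", epoch)
    for (nm in c("W1", "b1", "w2", "b2")) {
      v[[nm]] <- config$momentum * v[[nm]] - config$learning_rate * g[[nm]]
      w[[nm]] <- w[[nm]] + v[[nm]]
    }
    hist_train[epoch] <- sqrt(2 * g$loss / nrow(X))
    if (has_test) {
      te <- sqrt(mean((mlp_forward(w, test_inputs)$yhat - test_targets)^2))
      hist_test[epoch] <- te
      if (te < best$err - 1e-12) {
        best <- list(err = te, w = w, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  if (has_test && best$epoch > 0L) w <- best$w
  structure(list(W1 = w$W1, b1 = w$b1, w2 = w$w2, b2 = w$b2,
                 history = list(train = hist_train, test = hist_test),
                 epochs = length(hist_train),
                 best_epoch = if (has_test) best$epoch else length(hist_train)),
            class = "mlp_model")
}

#' Predict with a trained perceptron
#' @param model An `mlp_model`.
#' @param inputs n x d matrix on the training scale.
#' @return Numeric outputs in (0, 1).
#' @export
mlp_predict <- function(model, inputs) {
  mlp_forward(model, as.matrix(inputs))$yhat
}

## Seeded 60/20/20 (or per-config) index split.
mc_split <- function(n, split, seed) {
  withr::with_seed(seed, {
    idx <- sample.int(n)
    n_tr <- max(1L, round(split[["train"]] * n))
    n_te <- max(1L, round(split[["test"]] * n))
    list(train = idx[seq_len(n_tr)],
         test = idx[n_tr + seq_len(min(n_te, n - n_tr - 1L))],
         validation = idx[(n_tr + min(n_te, n - n_tr - 1L) + 1L):n])
  })
}

#' Rank candidate probes by ability to predict a target gene's status
#'
#' For each candidate probe, a single-input perceptron is trained to
#' predict the target probe's median-split high/low status (coded 0/1)
#' over Monte-Carlo 60/20/20 resamples; the candidate's score is its mean
#' validation-split RMSE, ranked ascending (rank 1 = most predictive). A
#' misclassification rate at the 0.5 decision threshold is reported as a
#' secondary column.
#'
#' @param expression Probes x samples matrix (log-scale), rownames = probes.
#' @param target_probe Probe whose median-split status is predicted.
#' @param config An [mlp_config]; `bootstraps` resamples are run per
#'   candidate.
#' @param candidates Candidate probe IDs (default: all probes except the
#'   target).
#' @return Data frame of class `probe_ranking`: `probe`, `mean_rmse`,
#'   `sd_rmse`, `mean_misclass`, `rank`.
#' @export
rank_probes_by_prediction <- function(expression, target_probe,
                                      config = mlp_config(),
                                      candidates = setdiff(rownames(expression),
                                                           target_probe)) {
  stopifnot(is.matrix(expression))
  stop_if(!target_probe %in% rownames(expression),
          "rank_probes_by_prediction: target probe not found")
  stop_if(ncol(expression) < 30,
          "rank_probes_by_prediction: need at least 30 samples")
  candidates <- as.character(candidates)
  stop_if(length(candidates) == 0, "rank_probes_by_prediction: empty candidate set")
  y_all <- as.numeric(expression[target_probe, ] > stats::median(expression[target_probe, ]))
  n <- ncol(expression)
  res <- vapply(seq_along(candidates), function(ci) {
    x <- as.numeric(scale(expression[candidates[ci], ]))
    if (!all(is.finite(x))) x <- rep(0, n)  # constant probe
    rmse <- numeric(config$bootstraps)
    mis <- numeric(config$bootstraps)
    for (b in seq_len(config$bootstraps)) {
      sp <- mc_split(n, config$split, child_seed(config$seed, ci, b))
      m <- train_mlp(cbind(x[sp$train]), y_all[sp$train], config,
                     test_inputs = cbind(x[sp$test]),
                     test_targets = y_all[sp$test],
                     seed = child_seed(config$seed, ci, b, 7L))
      pred <- mlp_predict(m, cbind(x[sp$validation]))
      rmse[b] <- sqrt(mean((pred - y_all[sp$validation])^2))
      mis[b] <- mean((pred > 0.5) != (y_all[sp$validation] == 1))
    }
    c(mean(rmse), stats::sd(rmse), mean(mis))
  }, numeric(3))
  out <- data.frame(probe = candidates,
                    mean_rmse = res[1, ], sd_rmse = res[2, ],
                    mean_misclass = res[3, ])
  out$rank <- rank(out$mean_rmse, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("probe_ranking", "data.frame")
  out
}

#' Ordered probe pairs evaluated by the interaction inference
#'
#' All ordered (source, target) pairs among `probes` excluding self-pairs:
#' `m * (m - 1)` rows for m probes.
#'
#' @param probes Character vector of probe IDs.
#' @return Data frame with columns `source`, `target`.
#' @export
interaction_pairs <- function(probes) {
  probes <- as.character(probes)
  g <- expand.grid(source = probes, target = probes,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g[g$source != g$target, , drop = FALSE]
}

#' Construct an interaction network
#'
#' @param edges Data frame with `source`, `target`, `weight` (signed,
#'   finite); no self-edges.
#' @param nodes Node universe (default: all endpoints).
#' @return List of class `interaction_network` with `edges` and `nodes`.
#' @export
interaction_network <- function(edges,
                                nodes = union(edges$source, edges$target)) {
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  stop_if(any(edges$source == edges$target),
          "interaction_network: self-edges are not allowed")
  stop_if(any(!is.finite(edges$weight)),
          "interaction_network: non-finite edge weight")
  structure(list(edges = edges[, c("source", "target", "weight")],
                 nodes = as.character(nodes)),
            class = "interaction_network")
}

#' Infer signed pairwise interactions among a probe panel
#'
#' For every target probe j, a perceptron with the remaining m - 1 probes
#' as inputs is trained over Monte-Carlo resamples to predict j's
#' expression (min-max rescaled into \[0.1, 0.9\] for the sigmoid output
#' node). The influence of input i on target j is the connection-weight
#' product summed over hidden nodes, `sum_h W1[h, i] * w2[h]`, averaged
#' over resamples: positive weights are excitatory, negative inhibitory.
#' All `m * (m - 1)` ordered pairs are evaluated.
#'
#' @param expression Probes x samples matrix restricted to the m >= 2 panel
#'   probes.
#' @param config An [mlp_config]; `bootstraps` controls the number of
#'   resamples per target.
#' @return An [interaction_network] with one signed, weighted edge per
#'   ordered pair.
#' @export
infer_pairwise_interactions <- function(expression, config = mlp_config()) {
  stopifnot(is.matrix(expression))
  m <- nrow(expression)
  stop_if(m < 2, "infer_pairwise_interactions: need at least 2 probes")
  probes <- rownames(expression)
  n <- ncol(expression)
  Xall <- standardize_cols(t(expression))  # n x m
  edges <- vector("list", m)
  for (j in seq_len(m)) {
    yr <- expression[j, ]
    rngy <- range(yr)
    y <- if (diff(rngy) > 0) 0.1 + 0.8 * (yr - rngy[1]) / diff(rngy) else rep(0.5, n)
    X <- Xall[, -j, drop = FALSE]
    wsum <- numeric(m - 1)
    for (b in seq_len(config$bootstraps)) {
      sp <- mc_split(n, config$split, child_seed(config$seed, 1000L + j, b))
      mdl <- train_mlp(X[sp$train, , drop = FALSE], y[sp$train], config,
                       test_inputs = X[sp$test, , drop = FALSE],
                       test_targets = y[sp$test],
                       seed = child_seed(config$seed, 1000L + j, b, 7L))
      wsum <- wsum + as.numeric(crossprod(mdl$W1, mdl$w2))
    }
    edges[[j]] <- data.frame(source = probes[-j], target = probes[j],
                             weight = wsum / config$bootstraps)
  }
  interaction_network(do.call(rbind, edges), nodes = probes)
}

#' Prune a network to its strongest edges and detect hubs
#'
#' Keeps the `top_k` edges by absolute weight; a hub is a node with at
#' least `hub_degree` retained incident edges (in or out). Hubs are ranked
#' by interaction strength, the sum of |weight| over their retained
#' incident edges, and the strongest `n_top_hubs` are flagged.
#'
#' @param net An [interaction_network].
#' @param top_k Edges retained (default 100).
#' @param hub_degree Minimum incident retained edges for hub status
#'   (default 5).
#' @param n_top_hubs Number of top-ranked hubs to flag (default 3).
#' @return List of class `pruned_network`: `network` (pruned
#'   `interaction_network`), `hubs` (data frame `node`, `degree`,
#'   `strength`, `rank`, `top`), `top_k`.
#' @export
select_top_edges_and_hubs <- function(net, top_k = 100, hub_degree = 5,
                                      n_top_hubs = 3) {
  stopifnot(inherits(net, "interaction_network"))
  stop_if(nrow(net$edges) == 0, "select_top_edges_and_hubs: empty network")
  e <- net$edges[order(-abs(net$edges$weight)), , drop = FALSE]
  e <- utils::head(e, top_k)
  rownames(e) <- NULL
  deg_tab <- table(c(e$source, e$target))
  nodes <- names(deg_tab)
  strength <- vapply(nodes, function(nd)
    sum(abs(e$weight[e$source == nd | e$target == nd])), numeric(1))
  hubs <- data.frame(node = nodes, degree = as.integer(deg_tab),
                     strength = unname(strength), row.names = NULL)
  hubs <- hubs[hubs$degree >= hub_degree, , drop = FALSE]
  hubs <- hubs[order(-hubs$strength), , drop = FALSE]
  hubs$rank <- seq_len(nrow(hubs))
  hubs$top <- hubs$rank <= n_top_hubs
  rownames(hubs) <- NULL
  structure(list(network = interaction_network(e, nodes = net$nodes),
                 hubs = hubs, top_k = top_k),
            class = "pruned_network")
}
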