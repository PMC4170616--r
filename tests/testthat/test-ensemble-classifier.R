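test_that("moderated t: shrinkage formula, limits and limma cross-check", {
  ## formula arithmetic: d0=4, s0^2=1, d=4, s^2=2 -> posterior 1.5
  expect_equal((4 * 1 + 4 * 2) / (4 + 4), 1.5)
  tc <- make_two_class(n_genes = 60, n_per_class = 4, n_de = 5, shift = 3)
  mt4 <- moderated_t(tc$x, tc$classes, d0 = 4, s0_2 = 1)
  g2 <- mt4$s2[2]
  expect_equal(mt4$s2_post[2], (4 * 1 + 6 * g2) / (4 + 6))

  ## d0 = 0: equals the ordinary pooled two-sample t, gene by gene
  mt0 <- moderated_t(tc$x, tc$classes, d0 = 0)
  ref_t <- apply(tc$x, 1, function(v)
    stats::t.test(v[tc$classes == "B"], v[tc$classes == "A"],
                  var.equal = TRUE)$statistic)
  expect_equal(mt0$t, unname(ref_t), tolerance = 1e-12)

  ## s^2 = s0^2 is a fixed point of the shrinkage for any d0
  x_fix <- tc$x
  mt_any <- moderated_t(x_fix, tc$classes, d0 = 7, s0_2 = mt0$s2[1])
  expect_equal(mt_any$s2_post[1], mt0$s2[1])

  ## d0 -> large: posterior variance pools to s0^2
  mt_inf <- moderated_t(tc$x, tc$classes, d0 = 1e6, s0_2 = 1.3)
  expect_equal(mt_inf$s2_post, rep(1.3, nrow(tc$x)), tolerance = 1e-4)

  ## hyperparameter estimation agrees with the canonical implementation
  skip_if_not_installed("limma")
  withr::with_seed(9, {
    x <- matrix(rnorm(200 * 12, sd = rep(exp(rnorm(200, 0, 0.7)), 12)),
                200, 12)
  })
  cl <- rep(c("A", "B"), each = 6)
  mine <- moderated_t(x, cl)
  fit <- limma::eBayes(limma::lmFit(x, stats::model.matrix(~factor(cl))))
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s0_2"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t, unname(fit$t[, 2]), tolerance = 1e-8)

  expect_error(moderated_t(tc$x, rep("A", ncol(tc$x))), "two classes")
  expect_error(moderated_t(tc$x[, 1:5], c("A", "A", "A", "A", "B")),
               ">= 2 samples")
})

test_that("majority vote follows the stated tie-break rule", {
  lev <- c("A", "B")
  ## clear majority
  expect_equal(majority_vote(c("A", "A", "A", "B"), c(0.1, 0.2, 0.3, 0.9), lev),
               "A")
  ## 2-2 tie, mean score for A higher (mean p2 < 0.5) -> A
  expect_equal(majority_vote(c("A", "A", "B", "B"), c(0.1, 0.2, 0.6, 0.7), lev),
               "A")
  ## 2-2 tie, mean score for B higher -> B
  expect_equal(majority_vote(c("A", "A", "B", "B"), c(0.4, 0.45, 0.9, 0.95), lev),
               "B")
  ## exact score tie -> lexicographic
  expect_equal(majority_vote(c("A", "A", "B", "B"), c(0.5, 0.5, 0.5, 0.5), lev),
               "A")
  ## invariant under permutation of learner order
  perm <- c(3, 1, 4, 2)
  expect_equal(
    majority_vote(c("A", "A", "B", "B")[perm], c(0.1, 0.2, 0.6, 0.7)[perm], lev),
    "A")
})

test_that("nearest shrunken centroid separates and shrinks as intended", {
  tc <- make_two_class(n_genes = 40, n_per_class = 10, n_de = 8, shift = 4,
                       seed = 12)
  xs <- t(tc$x)
  y <- factor(tc$classes)
  m0 <- gliosig:::nsc_train(xs, y, delta = 0)
  pr <- gliosig:::nsc_predict(m0, xs)
  expect_equal(pr$class, as.character(y))
  ## heavy shrinkage pulls every centroid to the overall mean:
  ## prediction collapses to the larger/first prior
  m_big <- gliosig:::nsc_train(xs, y, delta = 1e6)
  expect_equal(max(abs(m_big$cent[, 1] - m_big$cent[, 2])), 0)
})

test_that("LOOCV ensemble: separable accuracy, gene recovery, fallback", {
  tc <- make_two_class(n_genes = 80, n_per_class = 10, n_de = 15, shift = 5,
                       seed = 4)
  cv <- loocv_ensemble_classify(tc$x, tc$classes, seed = 1)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$n_folds, 20)
  ## no fold may leak: predictions exist for every sample
  expect_false(any(is.na(cv$predictions$vote)))
  rk <- rank_genes_by_selection_frequency(cv)
  ## planted genes selected in every fold -> frequency 1 at the top
  expect_true(all(rk$frequency[rk$gene %in% tc$de_genes] == 1))
  expect_true(all(utils::head(rk$gene, 10) %in% tc$de_genes))
  ## never-selected genes have frequency 0
  expect_true(any(rk$frequency == 0))
  expect_equal(rk$rank, seq_len(nrow(rk)))
})

test_that("left-out sample's label never influences its own fold", {
  tc <- make_two_class(n_genes = 40, n_per_class = 7, n_de = 8, shift = 3,
                       seed = 8)
  specs <- learner_specs(svm_cost = c(0.1, 1), rf_trees = 100,
                         knn_k = c(3, 5), nsc_n_delta = 4, inner_folds = 3)
  cv1 <- loocv_ensemble_classify(tc$x, tc$classes, specs, seed = 2)
  flipped <- tc$classes
  flipped[1] <- setdiff(unique(tc$classes), flipped[1])
  cv2 <- loocv_ensemble_classify(tc$x, flipped, specs, seed = 2)
  ## fold 1 selected the same genes and produced the same prediction
  expect_identical(cv1$selected[[1]], cv2$selected[[1]])
  expect_identical(cv1$predictions$vote[1], cv2$predictions$vote[1])
})

test_that("zero-gene folds fall back to the top-|t| genes", {
  ## pure noise with a tiny sample: many folds select nothing at p < 1e-6
  withr::with_seed(30, {
    x <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(paste0("g", 1:30), NULL))
  })
  cl <- rep(c("A", "B"), each = 6)
  specs <- learner_specs(svm_cost = 1, rf_trees = 100, knn_k = 3,
                         nsc_n_delta = 3, inner_folds = 3)
  cv <- loocv_ensemble_classify(x, cl, specs, alpha = 1e-6, seed = 3)
  expect_gt(cv$n_fallback, 0)
  expect_true(all(lengths(cv$selected) == 10))
})
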