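#' Empirical-Bayes moderated t-statistic
#'
#' Two-class differential expression with variance shrinkage: per-gene
#' pooled residual variances s^2 (d = n - 2 df) are shrunk toward a global
#' prior s0^2 with d0 prior df, `s2_post = (d0 s0^2 + d s^2) / (d0 + d)`,
#' and the moderated t uses the posterior sd with d + d0 degrees of
#' freedom. The hyperparameters (d0, s0^2) are estimated by closed-form
#' moment matching of log s^2 against a scaled-F prior.
#'
#' @param expression Genes x samples matrix.
#' @param classes Binary labels (factor or coercible), each class with >= 2
#'   samples. The contrast is second level minus first.
#' @param d0,s0_2 Optional hyperparameter overrides. `d0 = 0` gives the
#'   ordinary pooled two-sample t; very large `d0` pools all genes to
#'   s0^2. Estimated d0 is capped at 1e6 ("effectively infinite").
#' @return Data frame of class `moderated_t`: `gene`, `mean_diff`, `s2`,
#'   `s2_post`, `t`, `p`. Hyperparameters in `attr(, "d0")`,
#'   `attr(, "s0_2")`.
#' @export
moderated_t <- function(expression, classes, d0 = NULL, s0_2 = NULL) {
  x <- as.matrix(expression)
  cl <- factor(classes)
  stop_if(nlevels(cl) != 2, "moderated_t: exactly two classes required")
  n1 <- sum(cl == levels(cl)[1]); n2 <- sum(cl == levels(cl)[2])
  stop_if(min(n1, n2) < 2, "moderated_t: each class needs >= 2 samples")
  stop_if(ncol(x) != length(cl), "moderated_t: class labels do not match columns")
  i1 <- cl == levels(cl)[1]
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, !i1, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, !i1, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  if (is.null(d0)) {
    hp <- fit_f_prior(s2, d)
    d0 <- hp$d0; s0_2 <- s0_2 %||% hp$s0_2
  } else if (is.null(s0_2)) {
    s0_2 <- stats::median(s2)
  }
  if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- (m2 - m1) / se
  df_total <- min(d + d0, 1e6)
  out <- data.frame(gene = rownames(x) %||% as.character(seq_len(nrow(x))),
                    mean_diff = m2 - m1, s2 = s2, s2_post = s2_post,
                    t = tt, p = 2 * stats::pt(-abs(tt), df = df_total),
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "df_total") <- df_total
  class(out) <- c("moderated_t", "data.frame")
  out
}

## Moment matching of log s^2 against a scaled F_{d, d0} prior: the
## standard empirical-Bayes recipe. Returns d0 (possibly capped at 1e6)
## and s0_2.
fit_f_prior <- function(s2, d) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0) || d0 > 1e6) d0 <- 1e6
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- 1e6
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

## Newton inversion of the trigamma function.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Learner specifications for the ensemble classifier
#'
#' Tuning grids and inner-CV settings for the four base learners:
#' linear-kernel support vector machine, random forest, k-nearest
#' neighbours and nearest shrunken centroid.
#'
#' @param svm_cost SVM margin-penalty grid.
#' @param rf_trees Random-forest tree-count grid.
#' @param knn_k Neighbour-count grid.
#' @param nsc_n_delta Number of shrinkage thresholds tried (quantiles of
#'   the centroid offsets).
#' @param inner_folds Folds of the inner tuning cross-validation.
#' @return List of class `learner_specs`.
#' @export
learner_specs <- function(svm_cost = c(0.01, 0.1, 1, 10),
                          rf_trees = c(100, 300),
                          knn_k = c(1, 3, 5, 7),
                          nsc_n_delta = 10,
                          inner_folds = 5) {
  structure(list(svm_cost = svm_cost, rf_trees = rf_trees, knn_k = knn_k,
                 nsc_n_delta = nsc_n_delta,
                 inner_folds = as.integer(inner_folds)),
            class = "learner_specs")
}

## ---- nearest shrunken centroid (hand-rolled; no installed PAM) --------

nsc_train <- function(x, y, delta) {
  ## x: samples x genes; y: 2-level factor
  lev <- levels(y)
  n <- nrow(x); p <- ncol(x)
  xbar <- colMeans(x)
  cent <- vapply(lev, function(l) colMeans(x[y == l, , drop = FALSE]),
                 numeric(p))
  if (p == 1L) cent <- matrix(cent, 1, dimnames = list(NULL, lev))
  nk <- table(y)
  ss <- Reduce(`+`, lapply(lev, function(l)
    colSums((x[y == l, , drop = FALSE] -
               matrix(cent[, l], sum(y == l), p, byrow = TRUE))^2)))
  si <- sqrt(ss / (n - length(lev)))
  s0 <- stats::median(si)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  dik <- sweep(cent - xbar, 1, si + s0, "/")
  dik <- sweep(dik, 2, mk, "/")
  dshr <- sign(dik) * pmax(abs(dik) - delta, 0)
  cent_shr <- xbar + sweep(sweep(dshr, 2, mk, "*"), 1, si + s0, "*")
  list(levels = lev, cent = cent_shr, si = si, s0 = s0,
       prior = as.numeric(nk) / n, dik = dik)
}

nsc_predict <- function(model, x) {
  ## returns list(class, p2): p2 = posterior prob of second level
  x <- as.matrix(x)
  delta_k <- sapply(seq_along(model$levels), function(k) {
    rowSums(sweep(x, 2, model$cent[, k], "-")^2 /
              matrix((model$si + model$s0)^2, nrow(x), ncol(x), byrow = TRUE)) -
      2 * log(model$prior[k])
  })
  if (is.null(dim(delta_k))) delta_k <- matrix(delta_k, nrow = 1)
  post <- exp(-(delta_k - apply(delta_k, 1, min)) / 2)
  post <- post / rowSums(post)
  cls <- model$levels[apply(delta_k, 1, which.min)]
  list(class = cls, p2 = post[, 2])
}

## ---- base learners: fit on (x, y), predict left-out with a class-2
## probability-like score ------------------------------------------------

fit_predict_svm <- function(x_tr, y_tr, x_te, cost) {
  m <- e1071::svm(x_tr, y_tr, kernel = "linear", cost = cost, scale = FALSE)
  pr <- stats::predict(m, x_te, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  ## decision value is oriented toward the class named first in the colname
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s2 <- if (first == levels(y_tr)[2]) sigmoid(dv[, 1]) else sigmoid(-dv[, 1])
  list(class = as.character(pr), p2 = as.numeric(s2))
}

fit_predict_rf <- function(x_tr, y_tr, x_te, trees, seed) {
  d_tr <- data.frame(x_tr, .y = y_tr, check.names = FALSE)
  m <- ranger::ranger(dependent.variable.name = ".y", data = d_tr,
                      num.trees = trees, probability = TRUE,
                      seed = seed, num.threads = 1)
  p <- stats::predict(m, data.frame(x_te, check.names = FALSE),
                      num.threads = 1)$predictions
  p2 <- p[, levels(y_tr)[2]]
  list(class = levels(y_tr)[1 + (p2 > 0.5)], p2 = as.numeric(p2))
}

fit_predict_knn <- function(x_tr, y_tr, x_te, k) {
  k <- min(k, nrow(x_tr))
  pr <- class::knn(x_tr, x_te, y_tr, k = k, prob = TRUE)
  pwin <- attr(pr, "prob")
  p2 <- ifelse(as.character(pr) == levels(y_tr)[2], pwin, 1 - pwin)
  list(class = as.character(pr), p2 = as.numeric(p2))
}

fit_predict_nsc <- function(x_tr, y_tr, x_te, delta) {
  m <- nsc_train(x_tr, y_tr, delta)
  nsc_predict(m, x_te)
}

## Inner-CV accuracy of one learner over its grid; returns best parameter.
tune_learner <- function(fitfun, grid, x, y, folds, seed) {
  acc <- vapply(seq_along(grid), function(gi) {
    ok <- 0; tot <- 0
    for (f in unique(folds)) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2) next
      pr <- tryCatch(
        fitfun(x[tr, , drop = FALSE], droplevels(y[tr]),
               x[!tr, , drop = FALSE], grid[gi]),
        error = function(e) NULL)
      if (is.null(pr)) next
      ok <- ok + sum(pr$class == as.character(y[!tr]))
      tot <- tot + sum(!tr)
    }
    if (tot == 0) -Inf else ok / tot
  }, numeric(1))
  grid[which.max(acc)]
}

#' Majority vote over base-learner predictions
#'
#' A tie (equal vote counts) goes to the class with the higher mean
#' predicted score across learners, then lexicographic. Invariant under
#' permutation of learner order.
#'
#' @param votes Character vector of predicted classes, one per learner.
#' @param p2 Per-learner score for the second class level (probability or
#'   probability-like).
#' @param levels The two class levels (first, second).
#' @return The winning class label.
#' @export
majority_vote <- function(votes, p2, levels) {
  tab <- table(factor(votes, levels = levels))
  if (tab[1] != tab[2]) return(names(tab)[which.max(tab)])
  m <- mean(p2)
  if (m > 0.5) levels[2] else if (m < 0.5) levels[1] else sort(levels)[1]
}

#' Leave-one-out cross-validated majority-vote ensemble classification
#'
#' For every left-out sample: differentially expressed genes are selected
#' on the training portion only (moderated t, p < `alpha`; if none, the
#' top 10 genes by |t| are used as a fallback), four learners (linear SVM,
#' random forest, kNN, nearest shrunken centroid) are tuned by grid search
#' within an inner cross-validation on the training portion, and the
#' left-out sample is predicted by each. The ensemble prediction is the
#' majority vote; a 2-2 tie goes to the class with the higher mean
#' predicted score across learners, then lexicographic.
#'
#' @param expression Genes x samples matrix.
#' @param classes Two-class labels per sample (n >= 10).
#' @param specs A [learner_specs].
#' @param alpha Gene-selection threshold on the moderated-t p-value.
#' @param seed Base seed; inner folds and forests are seeded from it.
#' @return List of class `ensemble_cv`: `predictions` (data frame with
#'   truth, the four base predictions, `vote`), `accuracy`,
#'   `selected` (per-fold gene lists), `gene_p_sum` / `gene_sel_count`
#'   (per-gene aggregates over folds), `n_folds`, `n_fallback`.
#' @export
loocv_ensemble_classify <- function(expression, classes,
                                    specs = learner_specs(),
                                    alpha = 0.05, seed = 1) {
  x <- as.matrix(expression)
  cl <- factor(classes)
  n <- ncol(x)
  stop_if(n < 10, "loocv_ensemble_classify: need at least 10 samples")
  stop_if(nlevels(cl) != 2, "loocv_ensemble_classify: exactly two classes required")
  genes <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rownames(x) <- genes
  sel_list <- vector("list", n)
  gene_p_sum <- stats::setNames(numeric(length(genes)), genes)
  gene_sel <- stats::setNames(integer(length(genes)), genes)
  preds <- data.frame(truth = as.character(cl), svm = NA_character_,
                      rf = NA_character_, knn = NA_character_,
                      nsc = NA_character_, vote = NA_character_,
                      stringsAsFactors = FALSE)
  n_fallback <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mt <- moderated_t(x[, tr, drop = FALSE], cl[tr])
    gene_p_sum <- gene_p_sum + mt$p[match(genes, mt$gene)]
    sel <- mt$gene[mt$p < alpha]
    if (length(sel) == 0) {
      sel <- mt$gene[order(-abs(mt$t))][seq_len(min(10, nrow(mt)))]
      n_fallback <- n_fallback + 1L
    }
    sel_list[[i]] <- sel
    gene_sel[sel] <- gene_sel[sel] + 1L
    x_tr <- t(x[sel, tr, drop = FALSE])
    x_te <- t(x[sel, i, drop = FALSE])
    y_tr <- droplevels(cl[tr])
    folds <- withr::with_seed(child_seed(seed, i),
                              sample(rep(seq_len(specs$inner_folds),
                                         length.out = length(tr))))
    ## nearest-shrunken-centroid shrinkage grid: quantiles of the
    ## unshrunken standardized centroid offsets on this training set
    d0 <- nsc_train(x_tr, y_tr, 0)
    delta_grid <- unique(stats::quantile(abs(d0$dik),
                                         probs = seq(0, 0.9,
                                                     length.out = specs$nsc_n_delta),
                                         names = FALSE))
    best_cost <- tune_learner(fit_predict_svm, specs$svm_cost, x_tr, y_tr, folds, seed)
    best_tree <- tune_learner(function(a, b, c, g)
      fit_predict_rf(a, b, c, g, seed = child_seed(seed, i, 3L)),
      specs$rf_trees, x_tr, y_tr, folds, seed)
    best_k <- tune_learner(fit_predict_knn, specs$knn_k, x_tr, y_tr, folds, seed)
    best_delta <- tune_learner(fit_predict_nsc, delta_grid, x_tr, y_tr, folds, seed)
    pr <- list(
      svm = fit_predict_svm(x_tr, y_tr, x_te, best_cost),
      rf = fit_predict_rf(x_tr, y_tr, x_te, best_tree, child_seed(seed, i, 4L)),
      knn = fit_predict_knn(x_tr, y_tr, x_te, best_k),
      nsc = fit_predict_nsc(x_tr, y_tr, x_te, best_delta))
    votes <- vapply(pr, `[[`, character(1), "class")
    preds[i, c("svm", "rf", "knn", "nsc")] <- votes
    preds$vote[i] <- majority_vote(votes,
                                   vapply(pr, `[[`, numeric(1), "p2"),
                                   levels(cl))
  }
  structure(list(predictions = preds,
                 accuracy = mean(preds$vote == preds$truth),
                 selected = sel_list,
                 gene_p_sum = gene_p_sum,
                 gene_sel_count = gene_sel,
                 n_folds = n, n_fallback = n_fallback),
            class = "ensemble_cv")
}

#' Rank genes by cross-validation selection frequency
#'
#' Frequency = folds in which the gene passed differential-expression
#' selection / total folds, ranked descending; ties are broken by the
#' smaller mean fold p-value.
#'
#' @param result An [loocv_ensemble_classify] result.
#' @return Data frame of class `gene_ranking`: `gene`, `frequency`,
#'   `mean_p`, `rank`.
#' @export
rank_genes_by_selection_frequency <- function(result) {
  stopifnot(inherits(result, "ensemble_cv"))
  freq <- result$gene_sel_count / result$n_folds
  mean_p <- result$gene_p_sum / result$n_folds
  out <- data.frame(gene = names(freq), frequency = unname(freq),
                    mean_p = unname(mean_p), row.names = NULL)
  out <- out[order(-out$frequency, out$mean_p, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}
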