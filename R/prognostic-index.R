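#' Combine per-cohort Cox coefficients
#'
#' The combined prognostic-index weight for a gene is the arithmetic mean of
#' its log hazard ratios (Cox beta) from the two cohorts' final multivariate
#' models.
#'
#' @param beta_test,beta_validation Finite log hazard ratios from the test
#'   and validation cohorts.
#' @return `mean(beta_test, beta_validation)`, vectorized over genes.
#' @export
combine_betas <- function(beta_test, beta_validation) {
  stop_if(any(!is.finite(beta_test)) || any(!is.finite(beta_validation)),
          "combine_betas: non-finite beta")
  (beta_test + beta_validation) / 2
}

#' Prognostic-index model
#'
#' A per-gene table of dichotomization cutpoints and Cox coefficients
#' defining the score `PI = sum_g 1(expression_g > cutpoint_g) * beta_g`,
#' where `beta_g` is the combined (mean) coefficient.
#'
#' @param gene Gene symbols.
#' @param probe Probe IDs measuring each gene.
#' @param cutpoint Expression cutpoint per gene ("high" = strictly above).
#' @param direction Level associated with worse survival ("low"/"high").
#' @param beta_test,beta_validation Per-cohort log hazard ratios.
#' @param beta_combined Optional; defaults to [combine_betas] of the two.
#' @return Data frame of class `pi_model`.
#' @export
pi_model <- function(gene, probe, cutpoint, direction,
                     beta_test, beta_validation,
                     beta_combined = combine_betas(beta_test, beta_validation)) {
  stop_if(length(gene) == 0, "pi_model: empty gene set")
  stop_if(any(!is.finite(beta_combined)), "pi_model: non-finite combined beta")
  stop_if(!all(direction %in% c("low", "high")),
          "pi_model: direction must be 'low' or 'high'")
  out <- data.frame(gene = as.character(gene), probe = as.character(probe),
                    cutpoint = as.numeric(cutpoint),
                    direction = as.character(direction),
                    beta_test = as.numeric(beta_test),
                    beta_validation = as.numeric(beta_validation),
                    beta_combined = as.numeric(beta_combined))
  class(out) <- c("pi_model", "data.frame")
  out
}

#' Reference five-gene DNA-repair prognostic model
#'
#' The published combined coefficients of the five-gene glioblastoma
#' DNA-repair index (APE1, PMS2, NBN, MGMT, PTEN), with their U133A probes.
#' Cutpoints are cohort-specific and therefore `NA` here; use the model with
#' indicator input (see [compute_pi]) or set cutpoints from your own screen.
#'
#' @return A `pi_model` with `beta_combined` filled and cutpoints `NA`.
#' @export
reference_pi_model <- function() {
  out <- data.frame(
    gene = c("APE1", "PMS2", "NBN", "MGMT", "PTEN"),
    probe = c("210027_s_at", "209805_at", "202905_x_at", "204880_at", "204054_at"),
    cutpoint = NA_real_,
    direction = c("low", "high", "low", "high", "low"),
    beta_test = NA_real_,
    beta_validation = NA_real_,
    beta_combined = c(-0.524, 0.498, -0.620, 0.391, -0.439))
  class(out) <- c("pi_model", "data.frame")
  out
}

#' Compute prognostic-index scores
#'
#' `PI = sum_g indicator_g * beta_combined_g`, where the indicator is 1 when
#' the gene is expressed above its cutpoint ("high") and 0 otherwise.
#'
#' @param model A [pi_model].
#' @param expression Either a genes x samples numeric matrix of expression
#'   (rownames must cover the model's genes; indicators derived from the
#'   model cutpoints) or, with `indicators = TRUE`, a 0/1 matrix or named
#'   vector of high-expression indicators.
#' @param indicators Set `TRUE` when `expression` already holds 0/1
#'   indicator values.
#' @return Named numeric vector of PI scores, one per sample.
#' @export
compute_pi <- function(model, expression, indicators = FALSE) {
  stopifnot(inherits(model, "pi_model"))
  if (is.vector(expression)) expression <- cbind(sample = expression)
  expression <- as.matrix(expression)
  missing <- setdiff(model$gene, rownames(expression))
  stop_if(length(missing) > 0, "compute_pi: missing gene value(s): ",
          paste(missing, collapse = ", "))
  x <- expression[model$gene, , drop = FALSE]
  if (indicators) {
    stop_if(!all(x %in% c(0, 1)), "compute_pi: indicators must be 0/1")
    ind <- x
  } else {
    stop_if(any(is.na(model$cutpoint)),
            "compute_pi: model has no cutpoints; supply indicators")
    ind <- (x > model$cutpoint) * 1
  }
  drop(crossprod(ind, model$beta_combined)[, 1])
}

#' Stratify patients into prognostic groups by PI score
#'
#' Default grouping is k quantile bins of the score distribution with tied
#' scores kept together; groups are labelled 1..k by ascending median score
#' (group 1 = best prognosis when positive coefficients dominate risk). An
#' alternative mode chooses the two interior cut positions maximizing the
#' ordered-group log-rank statistic. Per-group Kaplan-Meier curves and the
#' extreme-group (1 vs k) log-rank test are attached.
#'
#' @param scores Numeric PI score per patient (>= k distinct values).
#' @param data A [surv_data] aligned with `scores`.
#' @param k Number of groups (default 3).
#' @param mode `"quantile"` (default) or `"logrank"` (exhaustive search of
#'   cut pairs; k must be 3).
#' @return List of class `risk_groups`: `group` (integer 1..k per patient),
#'   `breaks`, `medians` (median score per group), `km` (list of `km_curve`
#'   per group), `extreme_logrank` (`logrank_test` of group 1 vs k), `surv`.
#' @export
assign_risk_groups <- function(scores, data, k = 3,
                               mode = c("quantile", "logrank")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "surv_data"))
  scores <- as.numeric(scores)
  stop_if(length(scores) != length(data$time),
          "assign_risk_groups: scores do not match samples")
  stop_if(length(unique(scores)) < k,
          "assign_risk_groups: fewer than k distinct score values")
  if (mode == "quantile") {
    breaks <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = k + 1),
                                     names = FALSE))
    grp <- as.integer(cut(scores, breaks = breaks, include.lowest = TRUE))
    stop_if(length(unique(grp)) < k,
            "assign_risk_groups: ties collapse the quantile bins below k groups")
  } else {
    stop_if(k != 3, "assign_risk_groups: mode 'logrank' supports k = 3 only")
    cand <- sort(unique(scores))
    cand <- cand[-length(cand)]
    best <- NULL; best_chi <- -Inf
    for (i in seq_along(cand)) for (j in seq_along(cand)) {
      if (j <= i) next
      g <- 1L + (scores > cand[i]) + (scores > cand[j])
      if (length(unique(g)) < 3) next
      lr <- tryCatch(logrank_test(surv_data(data$time, data$event, g)),
                     error = function(e) NULL)
      if (!is.null(lr) && lr$chisq > best_chi) {
        best_chi <- lr$chisq; best <- c(cand[i], cand[j])
      }
    }
    stop_if(is.null(best), "assign_risk_groups: no valid cut pair found")
    breaks <- c(min(scores), best, max(scores))
    grp <- 1L + (scores > best[1]) + (scores > best[2])
  }
  ## relabel by ascending median score
  med <- tapply(scores, grp, stats::median)
  relab <- rank(med, ties.method = "first")
  grp <- as.integer(relab[as.character(grp)])
  med <- tapply(scores, grp, stats::median)
  km <- lapply(sort(unique(grp)), function(g)
    km_estimate(surv_data(data$time[grp == g], data$event[grp == g])))
  ext <- grp %in% c(1L, max(grp))
  extreme <- logrank_test(surv_data(data$time[ext], data$event[ext], grp[ext]))
  structure(list(group = grp, breaks = breaks, medians = as.numeric(med),
                 km = km, extreme_logrank = extreme, surv = data),
            class = "risk_groups")
}

#' Fit the year-survival prediction curve
#'
#' Reads the Kaplan-Meier percent survival at a fixed horizon (1, 2 or 3
#' years) in each of three prognostic groups, and fits the unique
#' interpolating quadratic of percent survival against the groups' median
#' PI scores. With three anchor points and three coefficients the fit is
#' exact.
#'
#' @param groups A [assign_risk_groups] result with exactly 3 groups of
#'   distinct median scores.
#' @param horizon_days Horizon in days (e.g. 365, 730, 1095).
#' @return List of class `year_curve`: `coef` (a, b, c of
#'   `a x^2 + b x + c`), `anchors` (median score, percent survival),
#'   `horizon_days`.
#' @export
fit_year_survival_curve <- function(groups, horizon_days) {
  stopifnot(inherits(groups, "risk_groups"))
  ngrp <- max(groups$group)
  stop_if(ngrp != 3, "fit_year_survival_curve: exactly 3 groups required")
  med <- groups$medians
  stop_if(anyDuplicated(med) > 0,
          "fit_year_survival_curve: duplicate group median scores")
  pct <- vapply(1:3, function(g) {
    idx <- groups$group == g
    100 * km_survival_at(surv_data(groups$surv$time[idx], groups$surv$event[idx]),
                         horizon_days)
  }, numeric(1))
  A <- cbind(unname(med)^2, unname(med), 1)
  coef <- unname(solve(A, pct))
  structure(list(coef = c(a = coef[1], b = coef[2], c = coef[3]),
                 anchors = data.frame(median_score = med, percent = pct),
                 horizon_days = horizon_days),
            class = "year_curve")
}

#' Predict percent survival from a PI score
#'
#' Evaluates a fitted [fit_year_survival_curve] quadratic at the given
#' scores, clamps the result to \[0, 100\] and flags extrapolation beyond
#' the anchor score range.
#'
#' @param fit A `year_curve`.
#' @param score PI score(s).
#' @return Data frame: `score`, `percent` (clamped), `raw` (unclamped
#'   quadratic value), `extrapolated`.
#' @export
predict_survival <- function(fit, score) {
  stopifnot(inherits(fit, "year_curve"))
  raw <- fit$coef["a"] * score^2 + fit$coef["b"] * score + fit$coef["c"]
  rng <- range(fit$anchors$median_score)
  data.frame(score = score,
             percent = pmin(100, pmax(0, unname(raw))),
             raw = unname(raw),
             extrapolated = score < rng[1] | score > rng[2])
}
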