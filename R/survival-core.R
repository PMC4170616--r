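#' Survival data container
#'
#' Bundles follow-up time, event indicator and an optional group label into a
#' validated structure used throughout the package. Times are in days.
#'
#' @param time Positive, finite follow-up times (days).
#' @param event Event indicator, 0 = censored, 1 = event (death).
#' @param group Optional per-sample categorical label (e.g. "low"/"high", a
#'   treatment arm or a risk group).
#' @return An object of class `surv_data`: a list with elements `time`,
#'   `event` and `group` (factor or `NULL`).
#' @export
surv_data <- function(time, event, group = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  stop_if(length(time) == 0L, "surv_data: empty input")
  stop_if(length(event) != length(time),
          "surv_data: 'time' and 'event' lengths differ")
  stop_if(any(!is.finite(time)) || any(time <= 0),
          "surv_data: times must be positive and finite")
  stop_if(!all(event %in% c(0, 1)), "surv_data: 'event' must be 0/1")
  if (!is.null(group)) {
    stop_if(length(group) != length(time),
            "surv_data: 'group' length does not match 'time'")
    group <- if (is.factor(group)) group else factor(group)
  }
  structure(list(time = time, event = event, group = group),
            class = "surv_data")
}

#' @export
print.surv_data <- function(x, ...) {
  cat(sprintf("<surv_data> n=%d, events=%d (%.1f%%)\n", length(x$time),
              sum(x$event), 100 * mean(x$event)))
  if (!is.null(x$group)) cat("  groups:", paste(levels(x$group), collapse = ", "), "\n")
  invisible(x)
}

as_Surv <- function(data) survival::Surv(data$time, data$event)

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function, as a plain life table.
#'
#' @param data A [surv_data] object. If `data$group` is set, a separate curve
#'   is computed per group.
#' @return A data frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (and `group` when grouped), one row per
#'   observed time. `S(0) = 1` is implicit; `surv` is nonincreasing within a
#'   group.
#' @export
km_estimate <- function(data) {
  stopifnot(inherits(data, "surv_data"))
  if (is.null(data$group)) {
    fit <- survival::survfit(as_Surv(data) ~ 1)
    out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  } else {
    fit <- survival::survfit(as_Surv(data) ~ data$group)
    strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
    strata <- sub("^data\\$group=", "", strata)
    out <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at a fixed horizon
#'
#' Reads S(t) at `horizon` from a Kaplan-Meier fit, carrying the last
#' estimate forward beyond the final observed time.
#'
#' @param data A [surv_data] object.
#' @param horizon Time (days) at which to evaluate survival.
#' @return Survival probability in \[0, 1\].
#' @export
km_survival_at <- function(data, horizon) {
  stopifnot(inherits(data, "surv_data"), is.finite(horizon), horizon >= 0)
  fit <- survival::survfit(as_Surv(data) ~ 1)
  s <- summary(fit, times = horizon, extend = TRUE)
  as.numeric(s$surv)
}

#' Log-rank test
#'
#' Observed-minus-expected log-rank test across k >= 2 groups.
#'
#' @param data A [surv_data] object with a non-null `group` of k >= 2 levels,
#'   each nonempty, and at least one event overall.
#' @return A list of class `logrank_test`: `chisq`, `df` (k - 1), `p`.
#' @export
logrank_test <- function(data) {
  stopifnot(inherits(data, "surv_data"))
  stop_if(is.null(data$group), "logrank_test: 'group' is required")
  tab <- table(data$group)
  stop_if(any(tab == 0), "logrank_test: empty group: ",
          paste(names(tab)[tab == 0], collapse = ", "))
  stop_if(nlevels(data$group) < 2, "logrank_test: need at least 2 groups")
  stop_if(sum(data$event) == 0, "logrank_test: no events observed")
  sd <- survival::survdiff(as_Surv(data) ~ data$group)
  df <- nlevels(data$group) - 1L
  structure(list(chisq = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank: chisq = %.4g on %d df, p = %.4g\n", x$chisq, x$df, x$p))
  invisible(x)
}

## Fast two-group log-rank chi-square used by the cutpoint scan, where
## survdiff's formula/model overhead dominates. `grp` is logical ("high").
## Returns the statistic and the O-E for the TRUE group (its sign says which
## group died more than expected). Cross-checked against survival::survdiff
## in the test suite.
logrank2_chisq <- function(time, event, grp) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; grp <- grp[ord]
  n <- length(time)
  dtimes <- unique(time[event == 1])
  ## at-risk totals and group-1 at-risk just before each death time
  idx_before <- findInterval(dtimes, time, left.open = TRUE)
  n_risk <- n - idx_before
  cum_g <- c(0, cumsum(grp))
  n_risk1 <- sum(grp) - cum_g[idx_before + 1L]
  ## events at each death time, total and in group 1:
  ev_idx <- which(event == 1)
  d_tot <- as.numeric(rowsum(rep(1, length(ev_idx)), time[ev_idx])[, 1])
  d_g1 <- as.numeric(rowsum(as.numeric(grp[ev_idx]), time[ev_idx])[, 1])
  e1 <- d_tot * n_risk1 / n_risk
  v_ok <- n_risk > 1
  v <- d_tot * (n_risk1 / n_risk) * (1 - n_risk1 / n_risk) *
    (n_risk - d_tot) / (n_risk - 1)
  v[!v_ok] <- 0
  OmE <- sum(d_g1 - e1)
  V <- sum(v)
  chisq <- if (V > 0) OmE^2 / V else 0
  list(chisq = chisq, obs_minus_exp_high = OmE)
}

#' Cox proportional-hazards fit
#'
#' Multivariable Cox regression by maximum partial likelihood, with Efron
#' handling of tied event times by default (Breslow available for parity with
#' older software defaults) and Wald confidence intervals
#' `exp(beta +/- 1.96 se)`.
#'
#' @param covariates Numeric matrix or data frame, samples in rows. No column
#'   may be constant; the number of events must be at least the number of
#'   covariates.
#' @param data A [surv_data] object aligned with `covariates` rows.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A data frame of class `cox_fit` with one row per covariate:
#'   `term`, `beta`, `hr`, `se`, `ci_low`, `ci_high`, `p` (Wald). The model
#'   log partial likelihood is in `attr(, "loglik")`.
#' @export
cox_fit <- function(covariates, data, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "surv_data"))
  x <- as.matrix(covariates)
  stop_if(is.null(colnames(x)), "cox_fit: covariates must be named columns")
  stop_if(nrow(x) != length(data$time),
          "cox_fit: covariate rows do not match samples")
  const <- apply(x, 2, function(v) length(unique(v)) < 2)
  stop_if(any(const), "cox_fit: constant covariate(s): ",
          paste(colnames(x)[const], collapse = ", "))
  stop_if(sum(data$event) < ncol(x),
          "cox_fit: fewer events than covariates")
  fit <- withCallingHandlers(
    survival::coxph(as_Surv(data) ~ x, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        warning("cox_fit: possible separation/non-convergence: ",
                conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  if (any(is.na(beta)))
    warning("cox_fit: singular fit (collinear covariates): ",
            paste(colnames(x)[is.na(beta)], collapse = ", "), call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(
    term = colnames(x),
    beta = beta,
    hr = exp(beta),
    se = unname(se),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    row.names = NULL
  )
  attr(out, "loglik") <- unname(fit$loglik[2])
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up or Bonferroni correction.
#'
#' @param p P-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @param m Number of comparisons; defaults to `length(p)`. The Bonferroni
#'   adjustment is `min(1, m * p)`.
#' @return Adjusted p-values, elementwise >= the raw values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni"), m = length(p)) {
  method <- match.arg(method)
  stop_if(any(!is.finite(p)) || any(p < 0) || any(p > 1),
          "adjust_pvalues: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method, n = max(m, length(p)))
}
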