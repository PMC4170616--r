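#' Optimal survival cutpoint for a continuous marker
#'
#' X-tile-style dichotomization: every unique expression value inside a
#' quantile band is tried as a split ("high" = value strictly above the
#' candidate cut), the two-group log-rank chi-square is computed for each,
#' and the maximizing split is returned. Ties among equally maximal
#' cutpoints are broken toward the split closest to the cohort median.
#' Because the cutpoint is chosen to maximize the statistic, the naive
#' log-rank p is optimistic; a Miller-Siegmund minimum-p corrected p over
#' the scanned band is reported alongside.
#'
#' @param expression Numeric marker values, one per sample (log-scale
#'   expression or an H-score); must not be constant; >= 10 samples.
#' @param data A [surv_data] object aligned with `expression`.
#' @param quantile_bounds Band of candidate cutpoints, as quantiles of
#'   `expression` (default 10th-90th percentile).
#' @return A list of class `cutpoint_result`: `cutpoint`, `direction`
#'   ("low"/"high" = level associated with worse survival), `chisq`, `p`
#'   (uncorrected), `p_minp` (Miller-Siegmund corrected), `n_candidates`.
#' @export
optimal_cutpoint <- function(expression, data, quantile_bounds = c(0.1, 0.9)) {
  stopifnot(inherits(data, "surv_data"))
  x <- as.numeric(expression)
  stop_if(length(x) != length(data$time),
          "optimal_cutpoint: expression length does not match samples")
  stop_if(length(x) < 10, "optimal_cutpoint: need at least 10 samples")
  stop_if(length(unique(x)) < 2, "optimal_cutpoint: expression is constant")
  stop_if(sum(data$event) == 0, "optimal_cutpoint: no events observed")
  qb <- stats::quantile(x, quantile_bounds, names = FALSE)
  cand <- sort(unique(x))
  cand <- cand[cand >= qb[1] & cand <= qb[2]]
  ## a valid cut must leave both sides nonempty under high = x > cut
  cand <- cand[cand < max(x)]
  stop_if(length(cand) == 0,
          "optimal_cutpoint: no valid split inside the quantile band")
  chis <- numeric(length(cand))
  ome <- numeric(length(cand))
  for (i in seq_along(cand)) {
    lr <- logrank2_chisq(data$time, data$event, x > cand[i])
    chis[i] <- lr$chisq
    ome[i] <- lr$obs_minus_exp_high
  }
  best <- which(chis == max(chis))
  if (length(best) > 1) {  # tie-break: split nearest the median
    med <- stats::median(x)
    best <- best[which.min(abs(cand[best] - med))]
  }
  chisq <- chis[best]
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(list(
    cutpoint = cand[best],
    direction = if (ome[best] > 0) "high" else "low",
    chisq = chisq,
    p = p,
    p_minp = minp_correct(p, quantile_bounds),
    n_candidates = length(cand)
  ), class = "cutpoint_result")
}

## Miller-Siegmund correction of a minimum p-value selected by scanning
## cutpoints over the quantile band (eps_lo, eps_hi):
##   p_cor = phi(z) (z - 1/z) log[ q_hi (1-q_lo) / ((1-q_hi) q_lo) ] + 4 phi(z)/z
## with z = Phi^{-1}(1 - p_min/2). Clamped to [p_min, 1].
minp_correct <- function(p_min, quantile_bounds = c(0.1, 0.9)) {
  if (p_min >= 1) return(1)
  z <- stats::qnorm(1 - p_min / 2)
  if (z <= 0) return(1)
  q_lo <- quantile_bounds[1]; q_hi <- quantile_bounds[2]
  lg <- log(q_hi * (1 - q_lo) / ((1 - q_hi) * q_lo))
  pc <- stats::dnorm(z) * (z - 1 / z) * lg + 4 * stats::dnorm(z) / z
  min(1, max(p_min, pc))
}

#' Panel-wide survival screen of probes
#'
#' Runs [optimal_cutpoint] for every probe of a panel against overall
#' survival, then adjusts the per-probe log-rank p-values across the panel
#' by Benjamini-Hochberg.
#'
#' @param expression Probes x samples numeric matrix (log-scale), rownames =
#'   probe IDs.
#' @param data A [surv_data] object aligned with the columns.
#' Because each probe's p-value is minimized over candidate cutpoints, the
#' value entering the BH adjustment is by default the Miller-Siegmund
#' corrected minimum p (as X-tile-style software reports); the raw minimum
#' log-rank p is kept alongside and can be used instead via `p_source`.
#'
#' @param probes Probe IDs to screen; defaults to all rows.
#' @param alpha Significance level on the BH-adjusted p (default 0.05).
#' @param quantile_bounds Passed to [optimal_cutpoint].
#' @param p_source P-value fed to the BH adjustment: `"minp"` (corrected,
#'   default) or `"raw"`.
#' @return A data frame of class `probe_screen`: `probe`, `cutpoint`,
#'   `direction`, `chisq`, `p`, `p_minp`, `p_adj`, `significant`. Probes
#'   whose cutpoint search fails are skipped with a warning and recorded
#'   in `attr(, "skipped")`.
#' @export
screen_probes <- function(expression, data, probes = rownames(expression),
                          alpha = 0.05, quantile_bounds = c(0.1, 0.9),
                          p_source = c("minp", "raw")) {
  p_source <- match.arg(p_source)
  stopifnot(is.matrix(expression), inherits(data, "surv_data"))
  stop_if(sum(data$event) == 0, "screen_probes: cohort has zero events")
  probes <- as.character(probes)
  if (length(probes) == 0) {
    out <- data.frame(probe = character(), cutpoint = numeric(),
                      direction = character(), chisq = numeric(),
                      p = numeric(), p_minp = numeric(), p_adj = numeric(),
                      significant = logical())
    class(out) <- c("probe_screen", "data.frame")
    return(out)
  }
  missing <- setdiff(probes, rownames(expression))
  stop_if(length(missing) > 0, "screen_probes: probes not in matrix: ",
          paste(utils::head(missing, 5), collapse = ", "))
  rows <- lapply(probes, function(pr) {
    cp <- tryCatch(optimal_cutpoint(expression[pr, ], data, quantile_bounds),
                   error = function(e) e)
    if (inherits(cp, "error")) {
      warning("screen_probes: skipping ", pr, ": ", conditionMessage(cp),
              call. = FALSE)
      return(NULL)
    }
    data.frame(probe = pr, cutpoint = cp$cutpoint, direction = cp$direction,
               chisq = cp$chisq, p = cp$p, p_minp = cp$p_minp)
  })
  skipped <- probes[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(probe = character(), cutpoint = numeric(),
                                      direction = character(), chisq = numeric(),
                                      p = numeric(), p_minp = numeric())
  out$p_adj <- adjust_pvalues(if (p_source == "minp") out$p_minp else out$p,
                              "BH")
  out$significant <- out$p_adj <= alpha
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("probe_screen", "data.frame")
  out
}

#' Cross-cohort consensus probes
#'
#' Probes significant (BH-adjusted) in both cohort screens with the same
#' direction of association (the level linked to worse survival agrees).
#'
#' @param screen_a,screen_b `probe_screen` results over a shared probe
#'   universe.
#' @return Data frame: `probe`, `direction`, per-cohort cutpoints and
#'   adjusted p-values (`cutpoint_a`, `cutpoint_b`, `p_adj_a`, `p_adj_b`).
#' @export
consensus_probes <- function(screen_a, screen_b) {
  stopifnot(inherits(screen_a, "probe_screen"), inherits(screen_b, "probe_screen"))
  a <- screen_a[screen_a$significant, ]
  b <- screen_b[screen_b$significant, ]
  common <- intersect(a$probe, b$probe)
  a <- a[match(common, a$probe), ]
  b <- b[match(common, b$probe), ]
  keep <- a$direction == b$direction
  data.frame(probe = common[keep],
             direction = a$direction[keep],
             cutpoint_a = a$cutpoint[keep],
             cutpoint_b = b$cutpoint[keep],
             p_adj_a = a$p_adj[keep],
             p_adj_b = b$p_adj[keep],
             row.names = NULL)
}

#' Dichotomize expression at per-probe cutpoints
#'
#' @param expression Probes x samples matrix.
#' @param cutpoints Named numeric vector of cutpoints (names = probe IDs).
#' @return 0/1 matrix (probes x samples); 1 = strictly above the cutpoint
#'   ("high").
#' @export
dichotomize_expression <- function(expression, cutpoints) {
  stopifnot(is.matrix(expression), !is.null(names(cutpoints)))
  probes <- names(cutpoints)
  missing <- setdiff(probes, rownames(expression))
  stop_if(length(missing) > 0, "dichotomize_expression: missing probes: ",
          paste(missing, collapse = ", "))
  z <- (expression[probes, , drop = FALSE] > cutpoints) * 1L
  storage.mode(z) <- "integer"
  z
}

#' Iterative multivariate Cox model reduction
#'
#' Backward elimination over dichotomized probes: per cohort, fit a
#' multivariable Cox model on all current probes, drop every probe with
#' Wald p > alpha in one batch, refit, and repeat until all remaining
#' probes are significant (or none remain). With two cohorts the loop is
#' run to convergence in each, the surviving sets are intersected, and both
#' cohorts are refit once on the common set — the cross-cohort consensus
#' model.
#'
#' @param z_list List (length 1 or 2) of 0/1 probes x samples matrices, as
#'   produced by [dichotomize_expression].
#' @param surv_list List of [surv_data] objects matching `z_list`.
#' @param probes Starting probe set (must be rows of every matrix).
#' @param alpha Wald significance level (default 0.05).
#' @return List of class `backward_elim`: `probes_final` (possibly empty),
#'   `fits` (per-cohort `cox_fit` on the final set, `NULL` when empty),
#'   `per_cohort` (probe sets surviving each cohort's own loop), `rounds`
#'   (iterations per cohort), `empty` flag.
#' @export
backward_eliminate <- function(z_list, surv_list, probes, alpha = 0.05) {
  stopifnot(is.list(z_list), is.list(surv_list),
            length(z_list) %in% c(1L, 2L),
            length(z_list) == length(surv_list))
  probes <- as.character(probes)
  stop_if(length(probes) < 1, "backward_eliminate: empty starting probe set")
  run_one <- function(z, sv) {
    active <- probes
    rounds <- 0L
    repeat {
      rounds <- rounds + 1L
      x <- t(z[active, , drop = FALSE])
      usable <- apply(x, 2, function(v) length(unique(v)) >= 2)
      active <- active[usable]
      if (length(active) == 0) return(list(probes = character(), rounds = rounds))
      fit <- cox_fit(t(z[active, , drop = FALSE]), sv)
      sig <- fit$term[fit$p <= alpha]
      if (length(sig) == length(active)) return(list(probes = active, rounds = rounds))
      if (length(sig) == 0) return(list(probes = character(), rounds = rounds))
      active <- sig
    }
  }
  per <- Map(run_one, z_list, surv_list)
  sets <- lapply(per, `[[`, "probes")
  final <- Reduce(intersect, sets)
  fits <- NULL
  if (length(final) > 0) {
    fits <- Map(function(z, sv) cox_fit(t(z[final, , drop = FALSE]), sv),
                z_list, surv_list)
  }
  structure(list(probes_final = final, fits = fits,
                 per_cohort = sets,
                 rounds = vapply(per, `[[`, integer(1), "rounds"),
                 empty = length(final) == 0),
            class = "backward_elim")
}
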