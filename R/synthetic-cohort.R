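#' Specification of a synthetic expression cohort
#'
#' Describes a cohort with the statistical structure the downstream
#' analyses assume: log2-scale Gaussian expression, a planted set of
#' prognostic probes acting on survival through a proportional-hazards
#' model on their cohort-median high/low indicator, independent
#' exponential censoring calibrated to a target fraction, optional
#' hub-driven correlated expression blocks (for network-inference
#' validation) and an optional two-class differential-expression block
#' (for classifier validation).
#'
#' @param n_samples,n_probes Cohort dimensions (positive).
#' @param prognostic_effects Named numeric vector: probe ID -> log hazard
#'   ratio of the high (above cohort median) level.
#' @param baseline Survival baseline: `list(family = "exponential", rate =)`
#'   or `list(family = "weibull", shape =, scale =)`; time unit days.
#' @param censoring_rate Target censoring fraction in \[0, 1).
#' @param treatment_prob Named probabilities of the `chemotherapy` and
#'   `radiotherapy` flags.
#' @param hub_block Optional list of blocks, each
#'   `list(hub =, targets =, link = "linear"|"quadratic"|"sigmoid",
#'   coupling =, noise_sd =)` wiring target probes to a hub probe.
#' @param de_block Optional `list(probes =, shift =, prop =)`: mean shift
#'   added to `probes` in class-1 samples, class-1 proportion `prop`.
#' @param expression_mean,expression_sd Marginal log2 expression mean and
#'   sd (microarray-like defaults 8 and 1).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, n_probes,
                        prognostic_effects = stats::setNames(numeric(0), character(0)),
                        baseline = list(family = "exponential", rate = 1 / 365),
                        censoring_rate = 0.2,
                        treatment_prob = c(chemotherapy = 0.6, radiotherapy = 0.8),
                        hub_block = NULL, de_block = NULL,
                        expression_mean = 8, expression_sd = 1,
                        seed = 1) {
  stop_if(n_samples < 1 || n_probes < 1,
          "cohort_spec: 'n_samples' and 'n_probes' must be positive")
  stop_if(censoring_rate < 0 || censoring_rate >= 1,
          "cohort_spec: 'censoring_rate' must lie in [0, 1)")
  stop_if(expression_sd <= 0, "cohort_spec: 'expression_sd' must be > 0")
  stop_if(!baseline$family %in% c("exponential", "weibull"),
          "cohort_spec: 'baseline$family' must be exponential or weibull")
  if (baseline$family == "exponential")
    stop_if(is.null(baseline$rate) || baseline$rate <= 0,
            "cohort_spec: exponential 'baseline$rate' must be > 0")
  else
    stop_if(is.null(baseline$shape) || is.null(baseline$scale) ||
              baseline$shape <= 0 || baseline$scale <= 0,
            "cohort_spec: weibull 'baseline' needs positive shape and scale")
  probes <- sprintf("probe_%04d", seq_len(n_probes))
  if (length(prognostic_effects) > 0) {
    stop_if(is.null(names(prognostic_effects)) ||
              !all(names(prognostic_effects) %in% probes),
            "cohort_spec: 'prognostic_effects' references unknown probes")
    stop_if(any(!is.finite(prognostic_effects)),
            "cohort_spec: non-finite value in 'prognostic_effects'")
  }
  for (hb in hub_block %||% list()) {
    stop_if(!all(c(hb$hub, hb$targets) %in% probes),
            "cohort_spec: 'hub_block' references unknown probes")
    stop_if(!hb$link %in% c("linear", "quadratic", "sigmoid"),
            "cohort_spec: unknown 'hub_block' link tag: ", hb$link)
    stop_if(!is.finite(hb$coupling) || !is.finite(hb$noise_sd) || hb$noise_sd < 0,
            "cohort_spec: 'hub_block' coupling/noise_sd must be finite")
  }
  if (!is.null(de_block)) {
    stop_if(!all(de_block$probes %in% probes),
            "cohort_spec: 'de_block' references unknown probes")
    stop_if(de_block$prop <= 0 || de_block$prop >= 1,
            "cohort_spec: 'de_block$prop' must lie in (0, 1)")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_probes = as.integer(n_probes), probes = probes,
                 prognostic_effects = prognostic_effects,
                 baseline = baseline, censoring_rate = censoring_rate,
                 treatment_prob = treatment_prob, hub_block = hub_block,
                 de_block = de_block, expression_mean = expression_mean,
                 expression_sd = expression_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

## Link functions for hub-target coupling; input is coupling * centered hub.
hub_link <- function(v, tag) {
  switch(tag,
         linear = v,
         quadratic = v^2,
         sigmoid = 4 * (sigmoid(v) - 0.5),
         stop("unknown link tag: ", tag, call. = FALSE))
}

#' Draw survival times under a proportional-hazards model
#'
#' Event times follow the spec's baseline distribution with hazard scaled
#' by `exp(lp)`; an independent exponential censoring time is drawn with
#' its rate solved (deterministically, from the drawn event times) so the
#' realized censoring fraction is close to `spec$censoring_rate`. Observed
#' time is the minimum; event = 1 when death precedes censoring.
#'
#' @param linear_predictor Finite per-sample log-hazard offsets.
#' @param spec A [cohort_spec] (baseline and censoring settings are used).
#' @return A [surv_data] object.
#' @export
generate_survival_times <- function(linear_predictor, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lp <- as.numeric(linear_predictor)
  stop_if(any(!is.finite(lp)), "generate_survival_times: non-finite linear predictor")
  n <- length(lp)
  u <- stats::runif(n)
  t_death <- if (spec$baseline$family == "exponential") {
    -log(u) / (spec$baseline$rate * exp(lp))
  } else {
    spec$baseline$scale * (-log(u) / exp(lp))^(1 / spec$baseline$shape)
  }
  if (spec$censoring_rate == 0) {
    return(surv_data(t_death, rep(1, n)))
  }
  ## solve for the exponential censoring rate hitting the target fraction:
  ## P(C < T) averaged over the drawn death times = censoring_rate
  f <- function(log_rc) mean(1 - exp(-exp(log_rc) * t_death)) - spec$censoring_rate
  root <- stats::uniroot(f, lower = log(1e-12 / mean(t_death)),
                         upper = log(1e12 / mean(t_death)))$root
  t_cens <- stats::rexp(n, rate = exp(root))
  surv_data(pmin(t_death, t_cens), as.numeric(t_death <= t_cens))
}

#' Draw a hub-driven expression block
#'
#' Hub probes are drawn independently; each target is
#' `expression_mean + link(coupling * centered hub) + Gaussian noise`.
#' Used standalone for network-inference validation; [generate_cohort]
#' plants the same structure inside the full matrix.
#'
#' @param spec A [cohort_spec] with a nonempty `hub_block`.
#' @return Matrix (hub + target probes) x samples.
#' @export
plant_network_block <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  stop_if(is.null(spec$hub_block) || length(spec$hub_block) == 0,
          "plant_network_block: 'hub_block' is empty")
  withr::with_seed(spec$seed, {
    rows <- list()
    for (hb in spec$hub_block) {
      hub <- stats::rnorm(spec$n_samples, spec$expression_mean, spec$expression_sd)
      rows[[hb$hub]] <- hub
      hc <- hub - mean(hub)
      for (tg in hb$targets) {
        rows[[tg]] <- spec$expression_mean +
          hub_link(hb$coupling * hc, hb$link) +
          stats::rnorm(spec$n_samples, 0, hb$noise_sd)
      }
    }
    out <- do.call(rbind, rows)
    colnames(out) <- sprintf("sample_%04d", seq_len(spec$n_samples))
    out
  })
}

#' Generate a synthetic cohort
#'
#' Draws the expression matrix (Gaussian log2-scale marginals), overwrites
#' hub-block and differential-expression structure where specified,
#' computes each sample's log-hazard linear predictor from the planted
#' effects on cohort-median high/low indicators, draws survival with
#' calibrated independent censoring and assigns treatment flags. Byte
#' identical across calls with the same spec.
#'
#' @param spec A [cohort_spec].
#' @return List of class `synthetic_cohort`: `expression` (probes x
#'   samples), `survival` ([surv_data]), `clinical` (data frame:
#'   sample_id, time, event, age, sex, chemotherapy, radiotherapy),
#'   `class_labels` (0/1 per sample; all 0 without a `de_block`),
#'   `truth` (the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    expr <- matrix(stats::rnorm(spec$n_probes * n, spec$expression_mean,
                                spec$expression_sd),
                   nrow = spec$n_probes,
                   dimnames = list(spec$probes,
                                   sprintf("sample_%04d", seq_len(n))))
    for (hb in spec$hub_block %||% list()) {
      hc <- expr[hb$hub, ] - mean(expr[hb$hub, ])
      for (tg in hb$targets) {
        expr[tg, ] <- spec$expression_mean +
          hub_link(hb$coupling * hc, hb$link) +
          stats::rnorm(n, 0, hb$noise_sd)
      }
    }
    class_labels <- rep(0L, n)
    if (!is.null(spec$de_block)) {
      class_labels <- stats::rbinom(n, 1, spec$de_block$prop)
      expr[spec$de_block$probes, class_labels == 1] <-
        expr[spec$de_block$probes, class_labels == 1, drop = FALSE] +
        spec$de_block$shift
    }
    lp <- rep(0, n)
    for (pr in names(spec$prognostic_effects)) {
      ind <- expr[pr, ] > stats::median(expr[pr, ])
      lp <- lp + spec$prognostic_effects[[pr]] * ind
    }
    survival <- generate_survival_times(lp, spec)
    age <- round(pmin(89, pmax(18, stats::rnorm(n, 57, 12))))
    sex <- ifelse(stats::runif(n) < 0.39, "F", "M")
    chemo <- ifelse(stats::runif(n) < spec$treatment_prob[["chemotherapy"]],
                    "yes", "no")
    radio <- ifelse(stats::runif(n) < spec$treatment_prob[["radiotherapy"]],
                    "yes", "no")
    clinical <- data.frame(sample_id = colnames(expr),
                           time = survival$time, event = survival$event,
                           age = age, sex = sex,
                           chemotherapy = chemo, radiotherapy = radio)
    structure(list(expression = expr, survival = survival,
                   clinical = clinical, class_labels = class_labels,
                   truth = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d probes x %d samples, %d events (%.0f%% censored)\n",
              nrow(x$expression), ncol(x$expression), sum(x$survival$event),
              100 * (1 - mean(x$survival$event))))
  if (length(x$truth$prognostic_effects))
    cat("  planted prognostic probes:",
        paste(names(x$truth$prognostic_effects), collapse = ", "), "\n")
  invisible(x)
}
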