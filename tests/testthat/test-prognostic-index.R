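test_that("combined coefficients reproduce the published five-gene weights", {
  ## PMS2: HRs 1.84 and 1.47 in the two cohorts -> mean ln(HR) = 0.498
  expect_equal(round(combine_betas(log(1.84), log(1.47)), 3), 0.498)
  ## MGMT: HRs 1.55 and 1.41 -> 0.391
  expect_equal(round(combine_betas(log(1.55), log(1.41)), 3), 0.391)
  ## PTEN: HRs 0.62 and 0.67 -> -0.439
  expect_equal(round(combine_betas(log(0.62), log(0.67)), 3), -0.439)
  ## identical inputs are a fixed point
  expect_equal(combine_betas(0.3, 0.3), 0.3)
  expect_error(combine_betas(Inf, 1), "non-finite")
})

test_that("PI score: additivity, printed-coefficient sums, missing genes", {
  m <- reference_pi_model()
  ind <- function(v) matrix(v, 5, 1, dimnames = list(m$gene, "s"))
  ## all five genes low -> 0
  expect_equal(unname(compute_pi(m, ind(rep(0, 5)), indicators = TRUE)), 0)
  ## all five high -> sum of the printed coefficients = -0.694
  expect_equal(unname(compute_pi(m, ind(rep(1, 5)), indicators = TRUE)),
               -0.694, tolerance = 1e-12)
  ## only MGMT high -> its coefficient alone
  v <- rep(0, 5); v[m$gene == "MGMT"] <- 1
  expect_equal(unname(compute_pi(m, ind(v), indicators = TRUE)), 0.391)
  ## additive over genes: score(a) + score(b) = score(a+b) for disjoint sets
  v2 <- rep(0, 5); v2[m$gene == "PMS2"] <- 1
  expect_equal(
    compute_pi(m, ind(v), indicators = TRUE) +
      compute_pi(m, ind(v2), indicators = TRUE),
    compute_pi(m, ind(v + v2), indicators = TRUE))
  ## missing gene is named in the error
  bad <- matrix(0, 4, 1, dimnames = list(m$gene[-3], "s"))
  expect_error(compute_pi(m, bad, indicators = TRUE), m$gene[3])
})

test_that("attainable reference-model scores stay inside the coefficient bounds", {
  m <- reference_pi_model()
  withr::with_seed(31, {
    ind <- matrix(rbinom(5 * 500, 1, 0.5), 5, 500,
                  dimnames = list(m$gene, NULL))
  })
  scores <- compute_pi(m, ind, indicators = TRUE)
  ## bounds: sum of negative coefficients / sum of positive coefficients
  expect_true(all(scores >= -1.583 - 1e-12))
  expect_true(all(scores <= 0.889 + 1e-12))
})

test_that("risk grouping: hand quantile example, failure modes, invariances", {
  sc <- c(-1, -1, 0, 0, 1, 1)
  d <- surv_data(c(100, 90, 60, 55, 30, 25), rep(1, 6))
  rg <- assign_risk_groups(sc, d, k = 3)
  expect_equal(rg$group, c(1, 1, 2, 2, 3, 3))
  expect_equal(rg$medians, c(-1, 0, 1))
  ## permutation of patients does not change group boundaries
  perm <- c(3, 1, 6, 2, 5, 4)
  rg_p <- assign_risk_groups(sc[perm], surv_data(d$time[perm], d$event[perm]),
                             k = 3)
  expect_equal(rg_p$breaks, rg$breaks)
  expect_equal(rg_p$group, rg$group[perm])
  ## identical scores cannot be grouped
  expect_error(assign_risk_groups(rep(1, 6), d, k = 3), "distinct")
})

test_that("strong planted effects yield ordered groups with separated survival", {
  eff <- stats::setNames(c(1.2, 1.0, -1.1), sprintf("probe_%04d", 1:3))
  co <- generate_cohort(cohort_spec(500, 10, prognostic_effects = eff,
                                    censoring_rate = 0.15, seed = 19))
  cuts <- apply(co$expression[names(eff), ], 1, stats::median)
  m <- pi_model(gene = names(eff), probe = names(eff), cutpoint = cuts,
                direction = ifelse(eff > 0, "high", "low"),
                beta_test = eff, beta_validation = eff)
  scores <- compute_pi(m, co$expression[names(eff), ])
  rg <- assign_risk_groups(scores, co$survival, k = 3)
  ## group 1 (lowest score) must dominate group 3 at 1 year
  s1 <- km_survival_at(surv_data(co$survival$time[rg$group == 1],
                                 co$survival$event[rg$group == 1]), 365)
  s3 <- km_survival_at(surv_data(co$survival$time[rg$group == 3],
                                 co$survival$event[rg$group == 3]), 365)
  expect_gt(s1, s3)
  expect_lt(rg$extreme_logrank$p, 0.001)
})

test_that("year-survival quadratic: hand-solved system, degeneracy, exactness", {
  ## anchors (-1, 80), (0, 50), (1, 30) -> 5x^2 - 25x + 50
  fit <- structure(list(coef = c(a = 5, b = -25, c = 50),
                        anchors = data.frame(median_score = c(-1, 0, 1),
                                             percent = c(80, 50, 30)),
                        horizon_days = 365), class = "year_curve")
  ## the solver reproduces the hand coefficients from the anchor system
  A <- cbind(c(-1, 0, 1)^2, c(-1, 0, 1), 1)
  expect_equal(unname(solve(A, c(80, 50, 30))), c(5, -25, 50))
  ## evaluation: x = 2 -> 20; anchors returned exactly; clamping flags
  p <- predict_survival(fit, 2)
  expect_equal(p$percent, 20)
  expect_true(p$extrapolated)
  pa <- predict_survival(fit, fit$anchors$median_score)
  expect_equal(pa$percent, fit$anchors$percent)
  expect_false(any(pa$extrapolated))
  ## raw value below 0 clamps with the flag
  fit$coef <- c(a = 0, b = 50, c = 20)
  p2 <- predict_survival(fit, -2)
  expect_equal(p2$percent, 0)
  expect_equal(p2$raw, -80)
  expect_true(p2$extrapolated)
})

test_that("fitted year curves interpolate the KM anchors exactly", {
  eff <- stats::setNames(c(1.3, -1.2), c("probe_0001", "probe_0002"))
  co <- generate_cohort(cohort_spec(400, 5, prognostic_effects = eff,
                                    baseline = list(family = "exponential",
                                                    rate = 1 / 500),
                                    censoring_rate = 0.1, seed = 23))
  cuts <- apply(co$expression[names(eff), ], 1, stats::median)
  m <- pi_model(gene = names(eff), probe = names(eff), cutpoint = cuts,
                direction = c("high", "low"),
                beta_test = eff, beta_validation = eff)
  scores <- compute_pi(m, co$expression[names(eff), ])
  rg <- assign_risk_groups(scores, co$survival, k = 3)
  fit <- fit_year_survival_curve(rg, 365)
  ## residuals at the anchors are zero to machine precision
  pred <- predict_survival(fit, fit$anchors$median_score)
  expect_equal(pred$raw, fit$anchors$percent, tolerance = 1e-9)
  ## collinear anchors give a vanishing quadratic term
  rg_lin <- rg
  rg_lin$medians <- c(-1, 0, 1)
  fit_lin <- fit_year_survival_curve(rg_lin, 365)
  anchors_lin <- fit_lin$anchors$percent
  ## force collinearity explicitly and re-solve
  A <- cbind(c(-1, 0, 1)^2, c(-1, 0, 1), 1)
  co_lin <- solve(A, c(70, 50, 30))
  expect_equal(co_lin[1], 0, tolerance = 1e-12)
})
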