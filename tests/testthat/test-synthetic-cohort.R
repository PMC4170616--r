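test_that("generation is deterministic given the spec seed", {
  sp <- cohort_spec(50, 15,
                    prognostic_effects = stats::setNames(0.5, "probe_0003"),
                    de_block = list(probes = c("probe_0004", "probe_0005"),
                                    shift = 2, prop = 0.5),
                    seed = 9)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$survival$time, c2$survival$time)
  expect_identical(c1$class_labels, c2$class_labels)
  ## the generator must not disturb the caller's RNG stream
  withr::with_seed(1, x1 <- runif(1))
  withr::with_seed(1, { generate_cohort(sp); x2 <- runif(1) })
  expect_identical(x1, x2)
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(0, 10), "n_samples")
  expect_error(cohort_spec(10, 10, censoring_rate = 1), "censoring_rate")
  expect_error(cohort_spec(10, 10, expression_sd = 0), "expression_sd")
  expect_error(cohort_spec(10, 10,
                           prognostic_effects = stats::setNames(1, "nope")),
               "prognostic_effects")
  expect_error(cohort_spec(10, 10,
                           hub_block = list(list(hub = "probe_0001",
                                                 targets = "probe_0002",
                                                 link = "cubic", coupling = 1,
                                                 noise_sd = 0.1))),
               "link")
  expect_error(cohort_spec(10, 5,
                           de_block = list(probes = "probe_0009", shift = 1,
                                           prop = 0.5)),
               "de_block")
  expect_error(cohort_spec(10, 10, baseline = list(family = "gamma")),
               "family")
})

test_that("survival times follow the scaled baseline and censoring contract", {
  ## exponential mean 1/lambda under null predictors, no censoring
  sp <- cohort_spec(10000, 1, baseline = list(family = "exponential",
                                              rate = 1 / 200),
                    censoring_rate = 0, seed = 1)
  sv <- withr::with_seed(1, generate_survival_times(rep(0, 10000), sp))
  expect_equal(mean(sv$time), 200, tolerance = 0.05)
  expect_true(all(sv$event == 1))

  ## +ln 2 on half the cohort: that half dies stochastically earlier
  lp <- rep(c(0, log(2)), each = 4000)
  sv2 <- withr::with_seed(2, generate_survival_times(lp, sp))
  w <- stats::wilcox.test(sv2$time[lp > 0], sv2$time[lp == 0],
                          alternative = "less")
  expect_lt(w$p.value, 1e-6)

  ## achieved censoring within +/- 0.05 of the target at n >= 1000
  for (target in c(0.2, 0.5)) {
    spc <- cohort_spec(2000, 1, censoring_rate = target, seed = 3)
    svc <- withr::with_seed(3, generate_survival_times(rep(0, 2000), spc))
    expect_equal(1 - mean(svc$event), target, tolerance = 0.05)
  }

  ## weibull branch: shape 2 median = scale * (ln 2)^(1/2)
  spw <- cohort_spec(20000, 1,
                     baseline = list(family = "weibull", shape = 2,
                                     scale = 300),
                     censoring_rate = 0, seed = 4)
  svw <- withr::with_seed(4, generate_survival_times(rep(0, 20000), spw))
  expect_equal(stats::median(svw$time), 300 * log(2)^(1 / 2), tolerance = 0.03)

  expect_error(generate_survival_times(c(0, NA), sp), "non-finite")
})

test_that("planted proportional-hazards effects are recoverable by Cox", {
  ## null model: no probe's hazard differs between high/low groups
  sp0 <- cohort_spec(400, 5, censoring_rate = 0.2, seed = 1)
  co0 <- generate_cohort(sp0)
  z <- (co0$expression["probe_0002", ] >
          stats::median(co0$expression["probe_0002", ])) * 1
  f0 <- cox_fit(cbind(z = z), co0$survival)
  expect_gt(f0$p, 0.01)

  ## beta = 0.7 planted on one probe, n = 500: mean recovery within 0.15
  betas <- vapply(1:15, function(s) {
    sp <- cohort_spec(500, 5,
                      prognostic_effects = stats::setNames(0.7, "probe_0001"),
                      censoring_rate = 0.2, seed = 500 + s)
    co <- generate_cohort(sp)
    zi <- (co$expression["probe_0001", ] >
             stats::median(co$expression["probe_0001", ])) * 1
    cox_fit(cbind(zi = zi), co$survival)$beta
  }, numeric(1))
  expect_equal(mean(betas), 0.7, tolerance = 0.15 / 0.7)
})

test_that("hub blocks produce the planted correlation structure", {
  ## zero coupling: independence
  sp0 <- cohort_spec(500, 3,
                     hub_block = list(list(hub = "probe_0001",
                                           targets = "probe_0002",
                                           link = "linear", coupling = 0,
                                           noise_sd = 1)),
                     seed = 5)
  m0 <- plant_network_block(sp0)
  expect_lt(abs(stats::cor(m0["probe_0001", ], m0["probe_0002", ])), 0.1)

  ## strong linear coupling: r > 0.9
  sp1 <- cohort_spec(300, 3,
                     hub_block = list(list(hub = "probe_0001",
                                           targets = "probe_0002",
                                           link = "linear", coupling = 2,
                                           noise_sd = 0.1)),
                     seed = 6)
  m1 <- plant_network_block(sp1)
  expect_gt(stats::cor(m1["probe_0001", ], m1["probe_0002", ]), 0.9)

  ## sigmoid link keeps the monotone association
  sp2 <- cohort_spec(300, 3,
                     hub_block = list(list(hub = "probe_0001",
                                           targets = "probe_0002",
                                           link = "sigmoid", coupling = 1.5,
                                           noise_sd = 0.2)),
                     seed = 7)
  m2 <- plant_network_block(sp2)
  expect_gt(stats::cor(m2["probe_0001", ], m2["probe_0002", ],
                       method = "spearman"), 0)

  ## the full-cohort generator plants the same wiring inside the matrix
  co <- generate_cohort(sp1)
  expect_gt(stats::cor(co$expression["probe_0001", ],
                       co$expression["probe_0002", ]), 0.9)

  expect_error(plant_network_block(cohort_spec(10, 2, seed = 1)), "empty")
})

test_that("the differential-expression block shifts only class-1 samples", {
  sp <- cohort_spec(400, 10,
                    de_block = list(probes = c("probe_0001", "probe_0002"),
                                    shift = 3, prop = 0.4),
                    seed = 8)
  co <- generate_cohort(sp)
  expect_equal(mean(co$class_labels), 0.4, tolerance = 0.1)
  gap <- mean(co$expression["probe_0001", co$class_labels == 1]) -
    mean(co$expression["probe_0001", co$class_labels == 0])
  expect_equal(gap, 3, tolerance = 0.3)
  gap_null <- mean(co$expression["probe_0005", co$class_labels == 1]) -
    mean(co$expression["probe_0005", co$class_labels == 0])
  expect_lt(abs(gap_null), 0.5)
})
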