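# Distribution fitting, parameter sampling, PSA, CEAC, tornado.

test_that("moment-matched fits preserve the mean for each family", {
  b <- fit_distribution(probability_estimate(0.5, 0.46, 0.54))
  expect_identical(b$family, "beta")
  expect_equal(b$par$shape1 / (b$par$shape1 + b$par$shape2), 0.5, tolerance = 1e-9)
  g <- fit_distribution(hazard_ratio_estimate(4.41, 3.63, 5.36, "gamma"))
  expect_equal(g$par$shape / g$par$rate, 4.41, tolerance = 1e-9)
  ln <- fit_distribution(hazard_ratio_estimate(1.97, 1.79, 2.16, "lognormal"))
  expect_equal(exp(ln$par$meanlog + ln$par$sdlog^2 / 2), 1.97, tolerance = 1e-9)
  f <- fit_distribution(probability_estimate(1, distribution = "fixed"))
  expect_identical(f$family, "fixed")
  # missing CI falls back to a 30% standard error
  nb <- fit_distribution(probability_estimate(0.1, distribution = "beta"))
  v <- with(nb$par, shape1 * shape2 / ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  expect_equal(sqrt(v), 0.03, tolerance = 1e-6)
  # infeasible beta variance is refused with the parameter named
  expect_error(fit_distribution(probability_estimate(0.001, 0, 0.5, "beta",
                                                     label = "tiny")),
               "beta-feasible.*tiny")
})

test_that("sampling a fitted spec recovers the input mean (Monte Carlo)", {
  set.seed(42)
  n <- 2e5
  specs <- list(
    fit_distribution(probability_estimate(0.0048, 0.0001, 0.0096)),
    fit_distribution(hazard_ratio_estimate(2.60, 2.20, 5.60, "gamma")),
    fit_distribution(hazard_ratio_estimate(1.97, 1.79, 2.16, "lognormal")))
  for (s in specs) {
    x <- sample_distribution(s, n)
    expect_lt(abs(mean(x) - s$mean), 3 * stats::sd(x) / sqrt(n))
  }
  # Dirichlet event split: joint draw sums to one, means recovered
  ps <- fixture_params()
  dsp <- fit_distribution(ps_estimates(ps)[["event_split"]])
  sw <- sample_distribution(dsp, n)
  expect_equal(unname(rowSums(sw)), rep(1, n), tolerance = 1e-12)
  for (j in 1:3)
    expect_lt(abs(mean(sw[, j]) - ps$event_split[j]),
              3 * stats::sd(sw[, j]) / sqrt(n))
})

test_that("parameter-set sampling is seed-reproducible and respects fixed entries", {
  ps <- fixture_params()
  a <- sample_parameter_set(ps, seed = 11)
  b <- sample_parameter_set(ps, seed = 11)
  attr(a, "redraws") <- attr(b, "redraws") <- NULL
  attr(a, "seed") <- attr(b, "seed") <- NULL
  expect_identical(a, b)
  d <- sample_parameter_set(ps, seed = 12)
  expect_false(isTRUE(all.equal(a$mb$no_treatment$mean, d$mb$no_treatment$mean)))
  # the fixed CRNMB-interruption risk never moves
  expect_identical(a$interruption_crnmb$mean, 1)
  expect_identical(d$interruption_crnmb$mean, 1)
  # sampled probabilities stay valid
  reg <- ps_estimates(a)
  probs <- vapply(reg[grepl("^(recurrence|mb\\.|crnmb\\.)", names(reg))],
                  function(e) e$mean, 0)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(sum(a$event_split), 1, tolerance = 1e-9)
})

test_that("sampled parameter means concentrate on the base values", {
  ps <- fixture_params()
  n <- 60
  draws <- vapply(seq_len(n), function(i) {
    s <- sample_parameter_set(ps, seed = 1000 + i, include_values = FALSE)
    c(s$mb$no_treatment$mean, s$crnmb$apixaban$mean, s$mortality_hr$index_dvt$mean)
  }, numeric(3))
  base <- c(ps$mb$no_treatment$mean, ps$crnmb$apixaban$mean,
            ps$mortality_hr$index_dvt$mean)
  for (j in 1:3)
    expect_lt(abs(mean(draws[j, ]) - base[j]),
              3 * stats::sd(draws[j, ]) / sqrt(n) + 0.01 * base[j])
})

test_that("the PSA is reproducible and centred near the deterministic result", {
  ps <- fixture_params(); lt <- fixture_life_table()
  arms <- list(new = arm_spec("apixaban", 500, horizon_cycles = 60),
               ref = arm_spec("no_treatment", 500, horizon_cycles = 60))
  r1 <- run_psa(ps, lt, n = 8, master_seed = 3, arm_new = arms$new,
                arm_ref = arms$ref)
  r2 <- run_psa(ps, lt, n = 8, master_seed = 3, arm_new = arms$new,
                arm_ref = arms$ref)
  expect_identical(r1$draws, r2$draws)
  expect_equal(nrow(r1$draws), 8)
  # incremental effect stays positive and of the deterministic magnitude
  expect_true(all(r1$draws$d_effect > 0))
  expect_lt(abs(median(r1$draws$d_effect) - r1$base_d_effect),
            max(3 * stats::sd(r1$draws$d_effect), 0.05))
})

test_that("the CEAC is the NMB exceedance curve and is monotone for gains", {
  draws <- data.frame(iteration = 1:4, seed = 1:4,
                      d_cost = c(-100, 500, 1500, 3000),
                      d_effect = c(0.1, 0.1, 0.1, 0.1))
  res <- structure(list(draws = draws, n_iterations = 4), class = "vte_psa_result")
  cc <- ceac(res, thresholds = c(0, 5000, 15000, 30000, 1e6))
  expect_equal(cc$probability[1], 0.25)          # cost-saving fraction at wtp 0
  expect_equal(cc$probability, cummax(cc$probability))
  expect_equal(cc$probability[5], 1)
  # identical draws with a gain: step function at the ICER
  one <- structure(list(draws = data.frame(iteration = 1, seed = 1,
                                           d_cost = 1000, d_effect = 0.1)),
                   class = "vte_psa_result")
  step <- ceac(one, thresholds = c(9999, 10000, 10001))
  expect_equal(step$probability, c(0, 1, 1))
})

test_that("the univariate sweep brackets the base ICER and sorts by range", {
  ps <- fixture_params(); lt <- fixture_life_table()
  arms <- list(new = arm_spec("apixaban", 500, horizon_cycles = 60),
               ref = arm_spec("no_treatment", 500, horizon_cycles = 60))
  tor <- univariate_sweep(ps, lt,
                          param_names = c("utilities.baseline",
                                          "costs.drug_per_day.apixaban_extended",
                                          "mb.no_treatment"),
                          arm_new = arms$new, arm_ref = arms$ref)
  expect_equal(nrow(tor), 3)
  expect_equal(length(unique(tor$base_icer)), 1)
  expect_equal(tor$range, sort(tor$range, decreasing = TRUE))
  # ICER is monotone in the drug unit cost (effect unchanged, cost linear)
  drug <- tor[tor$parameter == "costs.drug_per_day.apixaban_extended", ]
  expect_lt(drug$icer_lower, drug$base_icer)
  expect_gt(drug$icer_upper, drug$base_icer)
  expect_error(univariate_sweep(ps, lt, param_names = "not.a.param"),
               "unknown parameter")
})
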