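# Cohort engine: matrices, traces, counters.

test_that("transition matrices are row-stochastic over the twelve states", {
  ps <- fixture_params(); lt <- fixture_life_table()
  arm <- arm_spec("apixaban", 1000)
  for (cyc in c(1, 4, 5, 40, 170)) {
    for (st in c("index_dvt", "index_pe")) {
      M <- build_matrix(arm, cyc, ps, lt, stratum = st)
      expect_equal(dim(M), c(12, 12))
      expect_equal(unname(rowSums(M)), rep(1, 12), tolerance = 1e-12)
      expect_true(all(M >= 0))
      expect_setequal(rownames(M), health_states())
    }
  }
  # death states are absorbing
  M <- build_matrix(arm, 10, ps, lt)
  expect_identical(M["VTE_DEATH", "VTE_DEATH"], 1)
  expect_identical(M["OTHER_DEATH", "OTHER_DEATH"], 1)
})

test_that("pre-composition recurrence mass equals the interval risk", {
  # the untreated arm's cycle covering months 6-9 must place a total of
  # 0.0277 on {recurrent events + VTE death} before competing-risk
  # composition; after composition the mass shrinks by < 2%
  ps <- fixture_params(); lt <- fixture_life_table()
  arm <- arm_spec("no_treatment", 1000)
  M <- build_matrix(arm, 1, ps, lt, stratum = "index_dvt")
  mass <- M["OFF_TREATMENT_NO_EVENT", "RECURRENT_DVT"] +
    M["OFF_TREATMENT_NO_EVENT", "RECURRENT_PE"] +
    M["OFF_TREATMENT_NO_EVENT", "VTE_DEATH"]
  expect_lt(mass, 0.0277)
  expect_gt(mass, 0.0277 * 0.98)
  # the allocation is exit * lam_rec / lam_tot with lam_rec = -log(1 - 0.0277)
  # and lam_tot = -log(stay): the pre-composition risk is recovered exactly
  expect_equal(mass / (1 - M["OFF_TREATMENT_NO_EVENT", "OFF_TREATMENT_NO_EVENT"]),
               -log(1 - 0.0277) /
                 -log(M["OFF_TREATMENT_NO_EVENT", "OFF_TREATMENT_NO_EVENT"]),
               tolerance = 1e-9)
})

test_that("zero risks and zero mortality give an identity treatment row", {
  ps <- fixture_params()
  for (arm_nm in c("apixaban", "no_treatment"))
    for (iv in c("m6_9", "m9_12", "m12_15", "m15_18"))
      ps <- ps_set(ps, paste("recurrence", arm_nm, iv, sep = "."), 0)
  for (p in c("mb.apixaban", "mb.no_treatment", "crnmb.apixaban",
              "crnmb.no_treatment", "other_discontinuation", "cteph_annual"))
    ps <- ps_set(ps, p, 0)
  z <- make_life_table(male = list(makeham = 1e-300, scale = 1e-300, shape = 1e-3),
                       female = list(makeham = 1e-300, scale = 1e-300, shape = 1e-3))
  M <- build_matrix(arm_spec("apixaban", 10), 2, ps, z)
  expect_equal(M["ON_TREATMENT_NO_EVENT", "ON_TREATMENT_NO_EVENT"], 1,
               tolerance = 1e-12)
  expect_equal(M["OFF_TREATMENT_NO_EVENT", "OFF_TREATMENT_NO_EVENT"], 1,
               tolerance = 1e-12)
})

test_that("mass is conserved at every cycle and counters are non-decreasing", {
  ps <- fixture_params(); lt <- fixture_life_table()
  tr <- run_cohort(arm_spec("apixaban", 1000, horizon_cycles = 60), ps, lt)
  expect_equal(unname(rowSums(tr$occupancy)), rep(1000, 61), tolerance = 1e-9)
  expect_true(all(tr$cumulative >= -1e-12))
  expect_true(all(diff(tr$cumulative) >= -1e-9))
  expect_true(all(tr$pts_affected >= 0 & tr$pts_affected <= 1000))
})

test_that("a zero-person cohort produces an all-zero trace", {
  ps <- fixture_params(); lt <- fixture_life_table()
  tr <- run_cohort(arm_spec("apixaban", 0, horizon_cycles = 8), ps, lt)
  expect_equal(sum(tr$occupancy), 0)
  expect_equal(sum(tr$events), 0)
  expect_equal(count_events(tr)$events, rep(0, 12))
})

test_that("raising a single event risk never decreases that event's count", {
  ps <- fixture_params(); lt <- fixture_life_table()
  arm <- arm_spec("no_treatment", 1000, horizon_cycles = 12)
  base <- run_cohort(arm, ps, lt)
  bumps <- list(
    c("crnmb.no_treatment", "crnmb"),
    c("mb.no_treatment", "mb_total"),
    c("cteph_annual", "cteph"))
  for (b in bumps) {
    reg <- ps_estimates(ps)
    up <- run_cohort(arm, ps_set(ps, b[1], min(reg[[b[1]]]$mean * 1.5, 0.9)), lt)
    expect_gte(event_total(up, b[2]), event_total(base, b[2]))
  }
})

test_that("equalised treatment-specific risks make the arms coincide", {
  ps <- fixture_params()
  for (iv in c("m6_9", "m9_12", "m12_15", "m15_18"))
    ps <- ps_set(ps, paste("recurrence.apixaban", iv, sep = "."),
                 ps$recurrence$no_treatment[[iv]]$mean)
  ps <- ps_set(ps, "mb.apixaban", ps$mb$no_treatment$mean)
  ps <- ps_set(ps, "crnmb.apixaban", ps$crnmb$no_treatment$mean)
  ps <- ps_set(ps, "other_discontinuation", 0)
  lt <- fixture_life_table()
  ta <- run_cohort(arm_spec("apixaban", 1000, horizon_cycles = 4), ps, lt)
  tn <- run_cohort(arm_spec("no_treatment", 1000, horizon_cycles = 4), ps, lt)
  expect_equal(ta$cumulative, tn$cumulative, tolerance = 1e-9)
  expect_equal(ta$alive, tn$alive, tolerance = 1e-9)
})

test_that("a horizon beyond the maximum age is truncated with a warning", {
  ps <- fixture_params(); lt <- fixture_life_table()
  expect_warning(tr <- run_cohort(arm_spec("apixaban", 10, horizon_cycles = 500),
                                  ps, lt), "truncated")
  expect_lt(nrow(tr$events), 500)
  expect_equal(tr$alive[length(tr$alive)], 0, tolerance = 1e-9)
})

test_that("the initial phase requires acute parameters and runs when given", {
  ps <- fixture_params(); lt <- fixture_life_table()
  arm <- arm_spec("apixaban", 100, horizon_cycles = 4, include_initial_phase = TRUE)
  expect_error(run_cohort(arm, ps, lt), "acute parameters required")
  ps$acute <- synthetic_acute_block()
  tr <- run_cohort(arm, ps, lt)
  expect_equal(nrow(tr$events), 6)   # 2 initial + 4 extended cycles
  expect_equal(unname(rowSums(tr$occupancy)), rep(100, 7), tolerance = 1e-9)
  # index states are only occupied during the initial phase
  expect_gt(sum(tr$occupancy[1:2, c("INDEX_DVT", "INDEX_PE")]), 0)
  expect_equal(sum(tr$occupancy[4:7, c("INDEX_DVT", "INDEX_PE")]), 0,
               tolerance = 1e-9)
})
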