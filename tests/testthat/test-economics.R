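# Cost/QALY accounting and the ICER.

test_that("discount factors follow the discrete closed form", {
  expect_identical(discount_factor(0, 0.04), 1)
  expect_equal(discount_factor(1, 0.04), 1 / 1.04, tolerance = 1e-12)
  expect_equal(discount_factor(2, 0.015), 1.015^-2, tolerance = 1e-12)
  expect_identical(discount_factor(5, 0), 1)
  expect_error(discount_factor(-1, 0.04), "non-negative")
})

test_that("discounting never increases a total at a positive rate", {
  ps <- fixture_params(); lt <- fixture_life_table()
  tr <- run_cohort(arm_spec("apixaban", 1000, horizon_cycles = 40), ps, lt)
  c0 <- accumulate_costs(tr, ps$costs, "societal", 0)
  c4 <- accumulate_costs(tr, ps$costs, "societal", 0.04)
  expect_lt(c4$total, c0$total)
  e0 <- accumulate_qalys(tr, ps$utilities, 0)
  e15 <- accumulate_qalys(tr, ps$utilities, 0.015)
  expect_lt(e15$qalys, e0$qalys)
})

test_that("cost breakdown sums, divides by the cohort, and respects the perspective", {
  ps <- fixture_params(); lt <- fixture_life_table()
  tr <- run_cohort(arm_spec("no_treatment", 1000, horizon_cycles = 20), ps, lt)
  soc <- accumulate_costs(tr, ps$costs, "societal", 0.04)
  pay <- accumulate_costs(tr, ps$costs, "healthcare_payer", 0.04)
  cats <- setdiff(names(soc), "total")
  expect_equal(soc$total, sum(unlist(soc[cats])), tolerance = 1e-6)
  expect_lte(pay$total, soc$total)
  # perspective switch zeroes exactly the outside-healthcare categories
  expect_identical(pay$productivity_loss, 0)
  expect_identical(pay$transportation, 0)
  inside <- setdiff(cats, c("productivity_loss", "transportation"))
  for (ct in inside) expect_equal(pay[[ct]], soc[[ct]], tolerance = 1e-12)
})

test_that("a single costed event in a large cohort divides through", {
  # zero all risks except one recurrence interval, so the event cost is
  # attributable: expected recurrent events x unit cost / cohort
  ps <- fixture_params()
  z <- make_life_table(male = list(makeham = 1e-300, scale = 1e-300, shape = 1e-3),
                       female = list(makeham = 1e-300, scale = 1e-300, shape = 1e-3))
  for (p in c("mb.no_treatment", "crnmb.no_treatment", "cteph_annual", "pts_5y"))
    ps <- ps_set(ps, p, 0)
  for (iv in c("m9_12", "m12_15", "m15_18"))
    ps <- ps_set(ps, paste("recurrence.no_treatment", iv, sep = "."), 0)
  tr <- run_cohort(arm_spec("no_treatment", 1000, horizon_cycles = 1), ps, z)
  events <- 1000 * 0.0277
  bd <- accumulate_costs(tr, ps$costs, "societal", 0)   # t = 0, no discounting
  unit_dvt <- ps$costs[["event.recurrent_dvt"]]$mean
  expect_equal(bd$recurrent_dvt,
               events * ps$event_split[["recurrent_dvt"]] * unit_dvt / 1000,
               tolerance = 1e-9)
})

test_that("zero-cost registry and zero-person cohort give zero breakdowns", {
  ps <- fixture_params(); lt <- fixture_life_table()
  tr0 <- run_cohort(arm_spec("apixaban", 0, horizon_cycles = 4), ps, lt)
  expect_equal(accumulate_costs(tr0, ps$costs)$total, 0)
  expect_equal(accumulate_qalys(tr0, ps$utilities)$qalys, 0)
  zc <- ps$costs
  for (nm in names(zc)) zc[[nm]]$mean <- 0
  tr <- run_cohort(arm_spec("apixaban", 100, horizon_cycles = 4), ps, lt)
  expect_equal(accumulate_costs(tr, zc)$total, 0)
})

test_that("QALYs equal alive person-time at utility one and track the baseline", {
  ps <- fixture_params()
  z <- make_life_table(male = list(makeham = 1e-300, scale = 1e-300, shape = 1e-3),
                       female = list(makeham = 1e-300, scale = 1e-300, shape = 1e-3))
  for (p in c("mb.apixaban", "crnmb.apixaban", "cteph_annual", "pts_5y",
              "other_discontinuation"))
    ps <- ps_set(ps, p, 0)
  for (iv in c("m6_9", "m9_12", "m12_15", "m15_18"))
    ps <- ps_set(ps, paste("recurrence.apixaban", iv, sep = "."), 0)
  tr <- run_cohort(arm_spec("apixaban", 100, horizon_cycles = 4), ps, z)
  u1 <- ps$utilities; u1$baseline$mean <- 1
  expect_equal(accumulate_qalys(tr, u1, 0)$qalys, 1, tolerance = 1e-9)
  u08 <- ps$utilities; u08$baseline$mean <- 0.8
  expect_equal(accumulate_qalys(tr, u08, 0)$qalys, 0.8, tolerance = 1e-9)
  # QALYs never exceed life-years
  res <- accumulate_qalys(tr, ps$utilities, 0.015)
  expect_lte(res$qalys, res$life_years)
})

test_that("QALYs are monotone non-increasing in any utility decrement", {
  ps <- fixture_params(); lt <- fixture_life_table()
  tr <- run_cohort(arm_spec("no_treatment", 1000, horizon_cycles = 40), ps, lt)
  base <- accumulate_qalys(tr, ps$utilities, 0.015)$qalys
  for (key in c("recurrent_pe", "crnmb")) {
    u <- ps$utilities
    u$event_decrement[[key]]$mean <- u$event_decrement[[key]]$mean + 0.1
    expect_lte(accumulate_qalys(tr, u, 0.015)$qalys, base)
  }
  for (key in c("cteph", "pts")) {
    u <- ps$utilities
    u$state_decrement[[key]]$mean <- u$state_decrement[[key]]$mean + 0.1
    expect_lte(accumulate_qalys(tr, u, 0.015)$qalys, base)
  }
})

test_that("ICER quadrants and the published-totals example", {
  # direct division of the published per-patient totals
  ic <- icer(10110, 6643, 10.971, 10.612)
  expect_equal(ic$d_cost, 3467)
  expect_equal(ic$d_effect, 0.359, tolerance = 1e-12)
  expect_equal(ic$icer, 9657.3816, tolerance = 1e-4)
  expect_identical(ic$label, "trade-off")
  expect_identical(icer(10, 10, 1, 1)$label, "no difference")
  expect_true(is.na(icer(10, 10, 1, 1)$icer))
  expect_identical(icer(5, 10, 2, 1)$label, "dominant")
  expect_identical(icer(10, 5, 1, 2)$label, "dominated")
})

test_that("net monetary benefit crosses zero at the ICER", {
  expect_identical(net_monetary_benefit(0, 0, 50000), 0)
  expect_equal(net_monetary_benefit(3468, 0.359, 20000), 3712)
  ic <- 3468 / 0.359
  expect_equal(net_monetary_benefit(3468, 0.359, ic), 0, tolerance = 1e-9)
  # sign convention: NMB > 0 iff wtp > ICER when the effect gain is positive
  expect_gt(net_monetary_benefit(3468, 0.359, ic + 1), 0)
  expect_lt(net_monetary_benefit(3468, 0.359, ic - 1), 0)
  expect_error(net_monetary_benefit(1, 1, -5), "non-negative")
})
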