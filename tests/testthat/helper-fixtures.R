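# Shared fixtures, built once per test run.

fixture_params <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- default_fixture_parameters()
    ps
  }
})

fixture_life_table <- local({
  lt <- NULL
  function() {
    if (is.null(lt)) lt <<- default_life_table()
    lt
  }
})

# extension-trial validation arms (12-month horizon, 4 extended cycles)
ext_arms <- function() {
  list(treated = arm_spec("apixaban", cohort_size = 804, horizon_cycles = 4),
       untreated = arm_spec("no_treatment", cohort_size = 829, horizon_cycles = 4))
}

event_total <- function(trace, outcome, rounded = FALSE) {
  ce <- count_events(trace, rounded = rounded)
  ce$events[ce$outcome == outcome]
}

# a small synthetic acute-phase block (flagged synthetic: it stands in for
# the initial-treatment model's parameters, which are not shipped)
synthetic_acute_block <- function() {
  list(apixaban = list(recurrence_cycle = 0.012, mb_cycle = 0.003,
                       crnmb_cycle = 0.020),
       lmwh_vka = list(recurrence_cycle = 0.014, mb_cycle = 0.009,
                       crnmb_cycle = 0.041))
}
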