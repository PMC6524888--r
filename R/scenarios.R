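# Scenario definitions, the trial-validation harness and the censored
# interval-risk estimator.

#' Scenario configuration
#'
#' The packaged analyses: `"base"` (extended apixaban vs no treatment,
#' societal perspective, initial 6 months excluded); `"s1"` adds the initial
#' treatment phase (apixaban vs LMWH/VKA; requires an acute-phase parameter
#' block); `"s2"` is the base case from the healthcare payers' perspective;
#' `"s3"`/`"s4"`/`"s5"` equalise the untreated arm's major-bleeding risk,
#' CRNMB risk, or both, to the treated values.
#'
#' @param id One of `"base"`, `"s1"` ... `"s5"`.
#' @return Object of class `vte_scenario`.
#' @export
scenario_config <- function(id = c("base", "s1", "s2", "s3", "s4", "s5")) {
  id <- match.arg(id)
  structure(list(
    id = id,
    perspective = if (id == "s2") "healthcare_payer" else "societal",
    include_initial_phase = id == "s1",
    override_mb = id %in% c("s3", "s5"),
    override_crnmb = id %in% c("s4", "s5")), class = "vte_scenario")
}

#' Apply a scenario to a parameter set
#'
#' Returns a modified copy; the base set is untouched. Scenario 1 errors when
#' no acute-phase parameter block is present.
#'
#' @param base A `vte_parameter_set`.
#' @param sc A [scenario_config()] or scenario id string.
#' @return A `vte_parameter_set`.
#' @export
apply_scenario <- function(base, sc) {
  if (is.character(sc)) sc <- scenario_config(sc)
  stopifnot(inherits(sc, "vte_scenario"))
  ps <- base
  if (sc$include_initial_phase && is.null(ps$acute))
    stop("acute parameters required: scenario 1 needs an 'acute' block ",
         "transcribed from the initial-treatment model")
  if (sc$override_mb) ps$mb$no_treatment <- ps$mb$apixaban
  if (sc$override_crnmb) ps$crnmb$no_treatment <- ps$crnmb$apixaban
  attr(ps, "scenario") <- sc$id
  ps
}

#' Trial validation settings
#'
#' @param n_treated,n_untreated Arm sizes.
#' @param horizon_months Treatment duration and time horizon.
#' @param phase `"extended"` (12-month extension trial settings) or
#'   `"initial"` (6-month acute trial; requires acute parameters).
#' @param start_age,male_fraction,index_pe_fraction Cohort demographics.
#' @return Object of class `vte_trial_settings`.
#' @export
trial_settings <- function(n_treated = 804, n_untreated = 829,
                           horizon_months = 12,
                           phase = c("extended", "initial"),
                           start_age = 56.9, male_fraction = 0.58,
                           index_pe_fraction = 0.34) {
  phase <- match.arg(phase)
  if (n_treated <= 0 || n_untreated <= 0) stop("arm sizes must be positive")
  if (horizon_months %% 3 != 0)
    stop("horizon must be a whole number of 3-month cycles")
  structure(list(n_treated = n_treated, n_untreated = n_untreated,
                 horizon_months = horizon_months, phase = phase,
                 start_age = start_age, male_fraction = male_fraction,
                 index_pe_fraction = index_pe_fraction),
            class = "vte_trial_settings")
}

# trial outcome counts used as reference columns in the validation report
# (extension trial: N = 804 vs 829 over 12 months; acute trial: N = 2691 vs
# 2704 over 6 months)
trial_reference <- function(phase = "extended") {
  if (phase == "extended")
    data.frame(
      outcome = c("recurrent_vte_total", "mb_total", "crnmb", "all_cause_death"),
      trial_treated = c(14, 2, 25, 32),
      trial_untreated = c(73, 4, 19, 96),
      trial_rr = c(0.19, 0.49, 1.29, 0.33))
  else
    data.frame(
      outcome = c("recurrent_vte_total", "mb_total", "crnmb",
                  "discontinuation", "all_cause_death"),
      trial_treated = c(59, 15, 103, 162, 41),
      trial_untreated = c(71, 49, 215, 199, 52),
      trial_rr = c(0.83, 0.31, 0.48, 0.82, 0.79))
}

#' Relative risk from two event counts
#'
#' `(a_events / a_n) / (b_events / b_n)`. When the reference arm has zero
#' events the ratio is undefined and `NA` is returned with an attribute
#' `undefined = TRUE`.
#'
#' @param a_events,a_n Events and denominator, comparison arm.
#' @param b_events,b_n Events and denominator, reference arm.
#' @return Relative risk.
#' @export
relative_risk <- function(a_events, a_n, b_events, b_n) {
  if (a_n <= 0 || b_n <= 0) stop("denominators must be positive")
  if (b_events == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (a_events / a_n) / (b_events / b_n)
}

#' Validate the model against trial settings
#'
#' Runs both arms at the trial's size and horizon and reports modelled event
#' counts and relative risks next to the trial's published counts. All-cause
#' death is reported for completeness but depends on the background life
#' table, so it is not part of the model's pass/fail surface.
#'
#' @param settings A [trial_settings()].
#' @param params A `vte_parameter_set`.
#' @param life_table A `vte_life_table`.
#' @param control Engine options.
#' @return `data.frame` of class `vte_validation_report`: outcome, trial and
#'   modelled counts (modelled counts rounded; RRs computed on unrounded
#'   counts, reported to two decimals).
#' @export
validate_trial <- function(settings, params, life_table,
                           control = engine_control()) {
  stopifnot(inherits(settings, "vte_trial_settings"))
  cycles <- settings$horizon_months / params$cohort$cycle_months
  initial <- settings$phase == "initial"
  if (initial && is.null(params$acute))
    stop("acute parameters required: the initial-phase validation needs an ",
         "'acute' block transcribed from the initial-treatment model")
  mk <- function(name, n) arm_spec(
    name, cohort_size = n,
    horizon_cycles = if (initial) 0 else cycles,
    start_age = settings$start_age, male_fraction = settings$male_fraction,
    index_pe_fraction = settings$index_pe_fraction,
    include_initial_phase = initial)
  tt <- run_cohort(mk("apixaban", settings$n_treated), params, life_table, control)
  tu <- run_cohort(mk("no_treatment", settings$n_untreated), params, life_table, control)
  et <- count_events(tt, rounded = FALSE)
  eu <- count_events(tu, rounded = FALSE)
  ref <- trial_reference(settings$phase)
  raw_t <- et$events[match(ref$outcome, et$outcome)]
  raw_u <- eu$events[match(ref$outcome, eu$outcome)]
  rr <- mapply(relative_risk, raw_t, settings$n_treated, raw_u, settings$n_untreated)
  out <- data.frame(ref,
                    model_treated = round(raw_t),
                    model_untreated = round(raw_u),
                    model_rr = round(rr, 2))
  attr(out, "unrounded") <- data.frame(outcome = ref$outcome,
                                       model_treated = raw_t,
                                       model_untreated = raw_u)
  attr(out, "settings") <- settings
  class(out) <- c("vte_validation_report", "data.frame")
  out
}

#' Interval risks from censored trial counts
#'
#' The interval-risk estimator behind the published transition probabilities:
#' interval `j`'s risk is the number of first events in interval `j` divided
#' by the population still event-free at its start, i.e. the full
#' intention-to-treat denominator for the first interval, then `n - sum of
#' prior events` thereafter (`"itt"`). With `denominator = "mitt"` patients
#' censored for other reasons are also removed via `censored_by_interval`.
#'
#' @param events_by_interval First-event counts per interval.
#' @param n_itt Intention-to-treat denominator.
#' @param denominator `"itt"` (default) or `"mitt"`.
#' @param censored_by_interval Non-event censorings per interval (mITT only).
#' @return List of [probability_estimate()]s (one per interval) whose means
#'   are the interval risks.
#' @export
interval_risk_from_counts <- function(events_by_interval, n_itt,
                                      denominator = c("itt", "mitt"),
                                      censored_by_interval = NULL) {
  denominator <- match.arg(denominator)
  ev <- events_by_interval
  if (any(ev < 0) || n_itt < sum(ev))
    stop("n_itt must be at least the cumulative number of events")
  cens <- censored_by_interval %||% rep(0, length(ev))
  if (length(cens) != length(ev)) stop("censoring vector length mismatch")
  out <- vector("list", length(ev))
  at_risk <- n_itt
  for (j in seq_along(ev)) {
    if (at_risk <= 0) stop(sprintf("denominator exhausted at interval %d", j))
    p <- ev[j] / at_risk
    # Wilson-score interval for the per-interval binomial risk
    ciw <- stats::prop.test(round(ev[j]), round(at_risk), correct = FALSE)$conf.int
    out[[j]] <- probability_estimate(p, max(ciw[1], 0), min(ciw[2], 1),
                                     distribution = "beta", basis_months = 3,
                                     label = sprintf("interval %d risk", j))
    at_risk <- at_risk - ev[j] - if (denominator == "mitt") cens[j] else 0
  }
  out
}
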