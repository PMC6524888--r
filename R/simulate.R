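# Patient-level simulators. Two oracles live here: a per-patient event-stream
# generator with the censoring structure the interval-risk estimator assumes,
# and a microsimulation that pushes individual walkers through the exact
# per-cycle matrices the cohort engine uses.

#' Simulate patient-level trial event histories
#'
#' Per patient and per 3-month interval, draws (in competing fashion, with
#' the same survival-scale composition the cohort engine uses) a first
#' efficacy event, a discontinuation or a death. Patients are censored from
#' the efficacy risk set after their first event, matching the censored
#' interval-risk estimator's design.
#'
#' @param n Number of patients.
#' @param interval_hazards Per-interval efficacy event risks (one per cycle).
#' @param discontinuation_risk Per-cycle discontinuation risk.
#' @param death_risk Per-cycle background death risk.
#' @param seed Integer seed.
#' @return Object of class `vte_simulated_cohort`: data frame `patients` with
#'   `event_cycle`, `discontinuation_cycle`, `death_cycle` (NA when the event
#'   did not occur), plus `events_by_interval` counts and the generator
#'   settings.
#' @export
simulate_patients <- function(n, interval_hazards, discontinuation_risk = 0,
                              death_risk = 0, seed = 1) {
  if (any(interval_hazards < 0 | interval_hazards >= 1) ||
      discontinuation_risk < 0 || discontinuation_risk >= 1 ||
      death_risk < 0 || death_risk >= 1)
    stop("all risks must lie in [0, 1)")
  set.seed(seed)
  interval_hazards <- unname(interval_hazards)
  k <- length(interval_hazards)
  event_cycle <- rep(NA_integer_, n)
  disc_cycle <- rep(NA_integer_, n)
  death_cycle <- rep(NA_integer_, n)
  at_risk <- rep(TRUE, n)          # event-free and alive
  on_study <- rep(TRUE, n)
  for (j in seq_len(k)) {
    idx <- which(at_risk & on_study)
    if (!length(idx)) break
    cr <- compose_risks(c(event = interval_hazards[j],
                          disc = discontinuation_risk, death = death_risk))
    u <- stats::runif(length(idx))
    p_ev <- cr$alloc[["event"]]
    p_d <- p_ev + cr$alloc[["disc"]]
    p_x <- p_d + cr$alloc[["death"]]
    ev <- u < p_ev
    dc <- !ev & u < p_d
    dx <- !ev & !dc & u < p_x
    event_cycle[idx[ev]] <- j
    disc_cycle[idx[dc]] <- j
    death_cycle[idx[dx]] <- j
    at_risk[idx[ev | dx]] <- FALSE
    on_study[idx[dc]] <- FALSE     # discontinuers stop contributing events
  }
  events <- tabulate(event_cycle[!is.na(event_cycle)], nbins = k)
  structure(list(
    patients = data.frame(event_cycle = event_cycle,
                          discontinuation_cycle = disc_cycle,
                          death_cycle = death_cycle),
    events_by_interval = events, n = n,
    interval_hazards = interval_hazards, seed = seed),
    class = "vte_simulated_cohort")
}

#' Microsimulate the cohort model
#'
#' Walks `n` individual patients through exactly the per-cycle transition
#' matrices used by [run_cohort()] (multinomial draws of each state's
#' occupants), producing a stochastic counterpart of the deterministic trace.
#' Serves as the engine's independent validation oracle: expected occupancy
#' and event counts must agree within Monte-Carlo error.
#'
#' @param arm A [arm_spec()] (its `cohort_size` is replaced by `n`).
#' @param params A `vte_parameter_set`.
#' @param life_table A `vte_life_table`.
#' @param n Number of simulated patients.
#' @param seed Integer seed.
#' @param control Engine options.
#' @return A list shaped like a `vte_cohort_trace` (integer occupancy and
#'   per-cycle event counts) with class `vte_microsim_trace`.
#' @export
microsimulate_cohort <- function(arm, params, life_table, n = 1e5, seed = 1,
                                 control = engine_control()) {
  set.seed(seed)
  arm$cohort_size <- n
  cyc_yr <- params$cohort$cycle_months / 12
  n_initial <- if (arm$include_initial_phase) round(6 / params$cohort$cycle_months) else 0
  lifetime <- ceiling((params$cohort$max_age - arm$start_age) / cyc_yr) + 1
  horizon <- (arm$horizon_cycles %||% (lifetime - n_initial)) + n_initial

  nms <- full_state_names()
  occ <- stats::setNames(integer(length(nms)), nms)
  n_pe <- round(arm$index_pe_fraction * n)
  if (arm$include_initial_phase) {
    occ[fs_index("dvt", "IDX")] <- n - n_pe; occ[fs_index("pe", "IDX")] <- n_pe
  } else if (arm$name == "apixaban") {
    occ[fs_index("dvt", "ON")] <- n - n_pe; occ[fs_index("pe", "ON")] <- n_pe
  } else {
    occ[fs_index("dvt", "OFF")] <- n - n_pe; occ[fs_index("pe", "OFF")] <- n_pe
  }

  ev_cats <- c("recurrent_dvt", "recurrent_pe", "vte_death", "mb_fatal",
               "mb_ic", "mb_extracranial", "crnmb", "cteph", "discontinuation",
               "other_death")
  events <- matrix(0, horizon, length(ev_cats), dimnames = list(NULL, ev_cats))
  occ_hist <- matrix(0L, horizon + 1, length(nms), dimnames = list(NULL, nms))
  occ_hist[1, ] <- occ
  col_of <- function(state) which(sub("^[a-z]+\\.", "", nms) == state)
  onlike_rows <- which(sub("^[a-z]+\\.", "", nms) %in%
                         c("ON", "REC_DVT", "REC_PE", "MB_ON", "CRNMB_ON"))

  for (k in seq_len(horizon)) {
    M <- build_full_matrix(arm, k, params, life_table, control)
    Fl <- matrix(0, length(nms), length(nms))
    for (i in which(occ > 0))
      Fl[i, ] <- stats::rmultinom(1, occ[i], M[i, ])
    occ_new <- colSums(Fl)

    events[k, "recurrent_dvt"] <- sum(Fl[, col_of("REC_DVT")])
    events[k, "recurrent_pe"] <- sum(Fl[, col_of("REC_PE")])
    events[k, "vte_death"] <- sum(Fl[, col_of("VTE_DEATH")]) - sum(occ[col_of("VTE_DEATH")])
    events[k, "mb_fatal"] <- sum(Fl[, col_of("MB_DEATH")]) - sum(occ[col_of("MB_DEATH")])
    ic_cols <- col_of("IC")
    events[k, "mb_ic"] <- sum(Fl[-ic_cols, ic_cols])
    events[k, "mb_extracranial"] <- sum(Fl[, c(col_of("MB_ON"), col_of("MB_OFF"))])
    events[k, "crnmb"] <- sum(Fl[, c(col_of("CRNMB_ON"), col_of("CRNMB_OFF"))])
    ct_cols <- col_of("CTEPH")
    events[k, "cteph"] <- sum(Fl[-ct_cols, ct_cols])
    events[k, "discontinuation"] <- sum(Fl[onlike_rows, col_of("OFF")])
    events[k, "other_death"] <- sum(Fl[, col_of("OTHER_DEATH")]) - sum(occ[col_of("OTHER_DEATH")])

    occ <- stats::setNames(as.integer(occ_new), nms)
    occ_hist[k + 1, ] <- occ
  }

  structure(list(arm = arm, occupancy_full = occ_hist, events = events,
                 cumulative = apply(events, 2, cumsum), seed = seed,
                 cohort_size = n, cycle_years = cyc_yr),
            class = "vte_microsim_trace")
}
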