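# Cost and QALY accounting: turns a cohort trace into discounted per-patient
# costs by category (societal or healthcare-payer perspective) and QALYs, and
# computes the incremental cost-effectiveness ratio.

#' Discrete-time discount factor
#'
#' `(1 + rate)^(-t)`, evaluated at each cycle's start time.
#'
#' @param t Time in years.
#' @param rate Annual discount rate (fraction, >= 0).
#' @return Discount factor in (0, 1].
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0)) stop("time must be non-negative")
  if (any(rate < 0)) stop("discount rate must be non-negative")
  (1 + rate)^(-t)
}

cost_categories <- function() {
  c("vte_death", "recurrent_pe", "recurrent_dvt", "mb_fatal", "mb_ic",
    "mb_extracranial", "crnmb", "cteph", "pts", "drug", "monitoring",
    "productivity_loss", "transportation")
}

# categories outside the healthcare sector, excluded from the payer view
outside_categories <- function() c("productivity_loss", "transportation")

cost_of <- function(costs, key) {
  v <- costs[[key]]
  if (is.null(v)) stop(sprintf("cost registry is missing key '%s'", key))
  v$mean
}

#' Accumulate discounted per-patient costs
#'
#' Event costs accrue at the event's cycle; state costs (drug, monitoring,
#' CTEPH and PTS maintenance) accrue per occupied person-cycle; travel
#' tariffs accrue per qualifying visit (hospital visit for a recurrent PE or
#' DVT, IC bleed or CTEPH onset, and each INR monitoring visit); productivity
#' losses follow the friction-cost method. Everything is discounted at the
#' cycle-start time and divided by the cohort size.
#'
#' @param trace A `vte_cohort_trace`.
#' @param costs A `vte_cost_registry` (element `$costs` of a parameter set).
#' @param perspective `"societal"` (default) or `"healthcare_payer"`, which
#'   drops the categories outside the healthcare sector.
#' @param discount_rate Annual discount rate for costs.
#' @return Object of class `vte_cost_breakdown`: named per-patient costs by
#'   category plus `total`.
#' @export
accumulate_costs <- function(trace, costs, perspective = c("societal", "healthcare_payer"),
                             discount_rate = 0.04) {
  perspective <- match.arg(perspective)
  n <- trace$cohort_size
  if (n == 0) {
    out <- stats::setNames(numeric(length(cost_categories()) + 1),
                           c(cost_categories(), "total"))
    return(structure(as.list(out), class = "vte_cost_breakdown",
                     perspective = perspective))
  }
  H <- nrow(trace$events)
  df <- discount_factor(trace$times[seq_len(H)], discount_rate)
  ev <- trace$events
  days_per_cycle <- trace$cycle_years * 365.25

  cat_total <- stats::setNames(numeric(length(cost_categories())), cost_categories())

  # one-off event costs
  ev_cost <- c(vte_death = cost_of(costs, "event.vte_death"),
               recurrent_pe = cost_of(costs, "event.recurrent_pe"),
               recurrent_dvt = cost_of(costs, "event.recurrent_dvt"),
               mb_fatal = cost_of(costs, "event.mb_fatal"),
               mb_ic = cost_of(costs, "event.mb_ic"),
               mb_extracranial = cost_of(costs, "event.mb_extracranial"),
               crnmb = cost_of(costs, "event.crnmb"))
  for (nm in names(ev_cost))
    cat_total[nm] <- sum(ev[, nm] * df) * ev_cost[nm]
  cat_total["cteph"] <- sum(ev[, "cteph"] * df) * cost_of(costs, "event.cteph_onset") +
    sum(trace$occupancy[seq_len(H), "CTEPH"] * df) * cost_of(costs, "per_cycle.cteph")
  cat_total["pts"] <- sum(trace$pts_affected * df) * cost_of(costs, "per_cycle.pts")

  # drug costs per person-cycle on each regimen, net of bleeding interruptions
  drug_day <- c(apixaban = cost_of(costs, "drug_per_day.apixaban_extended"),
                vka = cost_of(costs, "drug_per_day.vka"),
                apixaban_initial = cost_of(costs, "drug_per_day.apixaban_initial"),
                lmwh_vka_initial = cost_of(costs, "drug_per_day.lmwh") / 6 +
                  cost_of(costs, "drug_per_day.vka"))
  drug_cost_cycle <- numeric(H)
  for (d in colnames(trace$on_drug))
    drug_cost_cycle <- drug_cost_cycle +
      trace$on_drug[, d] * days_per_cycle * drug_day[[d]]
  # interruption: expected days off drug after non-IC MB (p x 14 d) and CRNMB (2 d)
  maint_day <- if (trace$arm$name == "apixaban") drug_day[["apixaban"]] else drug_day[["vka"]]
  interrupt <- (ev[, "mb_extracranial"] * trace$interruption$p_mb * trace$interruption$days_mb +
                  ev[, "crnmb"] * trace$interruption$p_crnmb * trace$interruption$days_crnmb)
  cat_total["drug"] <- sum(pmax(drug_cost_cycle - interrupt * maint_day, 0) * df)

  # monitoring: INR visits for VKA person-cycles, a light check for DOAC use
  inr_visits <- trace$on_drug[, "vka"] * cost_of(costs, "monitoring.inr_visits_per_cycle")
  cat_total["monitoring"] <- sum(inr_visits * df) * cost_of(costs, "monitoring.inr_visit_cost") +
    sum(trace$on_drug[, "apixaban"] * df) * cost_of(costs, "per_cycle.doac_monitoring")

  # travel: qualifying visits (events + INR monitoring)
  visit_events <- ev[, "recurrent_pe"] + ev[, "recurrent_dvt"] + ev[, "mb_ic"] +
    ev[, "cteph"]
  cat_total["transportation"] <- sum((visit_events + inr_visits) * df) *
    cost_of(costs, "travel_per_visit")

  # productivity losses, friction-cost method
  wage <- cost_of(costs, "productivity.hourly_wage")
  emp <- cost_of(costs, "productivity.employment_prob")
  friction <- cost_of(costs, "productivity.friction_days")
  hpd <- cost_of(costs, "productivity.hours_per_day")
  absence <- function(key) min(cost_of(costs, paste0("productivity.absence_days.", key)),
                               friction)
  prod_events <- ev[, "recurrent_dvt"] * absence("recurrent_dvt") +
    ev[, "recurrent_pe"] * absence("recurrent_pe") +
    ev[, "mb_extracranial"] * absence("mb") +
    ev[, "mb_ic"] * absence("mb_ic") +
    ev[, "crnmb"] * absence("crnmb") +
    ev[, "cteph"] * absence("cteph") +
    (ev[, "vte_death"] + ev[, "mb_fatal"]) * absence("death")
  cat_total["productivity_loss"] <- sum(prod_events * df) * wage * hpd * emp

  if (perspective == "healthcare_payer")
    cat_total[outside_categories()] <- 0

  cat_total <- cat_total / n
  out <- as.list(cat_total)
  out$total <- sum(cat_total)
  structure(out, class = "vte_cost_breakdown", perspective = perspective)
}

#' Accumulate discounted QALYs and life-years
#'
#' Per cycle: alive occupancy x (baseline utility - applicable state
#' decrements, floored at 0) x cycle length x discount factor, minus one-off
#' event disutilities (decrement x duration) at their event cycle, divided by
#' the cohort size.
#'
#' @param trace A `vte_cohort_trace`.
#' @param utilities A `vte_utility_registry` (element `$utilities`).
#' @param discount_rate Annual discount rate for effects.
#' @return List of class `vte_effect_result` with `qalys` and `life_years`.
#' @export
accumulate_qalys <- function(trace, utilities, discount_rate = 0.015) {
  n <- trace$cohort_size
  if (n == 0)
    return(structure(list(qalys = 0, life_years = 0), class = "vte_effect_result"))
  H <- nrow(trace$events)
  df <- discount_factor(trace$times[seq_len(H)], discount_rate)
  cyc <- trace$cycle_years
  base <- utilities$baseline$mean
  if (base < 0 || base > 1) {
    warning("baseline utility clamped into [0, 1]")
    base <- min(max(base, 0), 1)
  }
  alive <- trace$alive[seq_len(H)]
  if (isTRUE(trace$control$half_cycle))
    alive <- (alive + trace$alive[seq_len(H) + 1]) / 2

  sdec <- function(key) utilities$state_decrement[[key]]$mean
  u_ic <- max(base - sdec("ic_bleed"), 0)
  u_cteph <- max(base - sdec("cteph"), 0)
  occ <- trace$occupancy[seq_len(H), , drop = FALSE]
  util_py <- alive * base -
    occ[, "IC_BLEED"] * (base - u_ic) -
    occ[, "CTEPH"] * (base - u_cteph) -
    trace$pts_affected * min(sdec("pts"), base)

  edec <- function(key) {
    d <- utilities$event_decrement[[key]]
    d$mean * d$duration_years
  }
  ev <- trace$events
  event_loss <- ev[, "recurrent_dvt"] * edec("recurrent_dvt") +
    ev[, "recurrent_pe"] * edec("recurrent_pe") +
    (ev[, "mb_extracranial"] + ev[, "mb_ic"]) * edec("mb") +
    ev[, "crnmb"] * edec("crnmb")

  qalys <- sum((util_py * cyc - event_loss) * df) / n
  life_years <- sum(alive * cyc * df) / n
  structure(list(qalys = max(qalys, 0), life_years = life_years),
            class = "vte_effect_result")
}

#' Incremental cost-effectiveness ratio
#'
#' @param c_new,c_ref Per-patient costs of the new and reference strategy.
#' @param e_new,e_ref Per-patient effects (QALYs).
#' @return Object of class `vte_icer`: unrounded increments, the ratio when
#'   defined, and a quadrant label (`"trade-off"`, `"dominant"`,
#'   `"dominated"`, `"no difference"`).
#' @export
icer <- function(c_new, c_ref, e_new, e_ref) {
  dc <- c_new - c_ref
  de <- e_new - e_ref
  if (de == 0) {
    label <- if (dc == 0) "no difference" else if (dc < 0) "dominant" else "dominated"
    return(structure(list(d_cost = dc, d_effect = de, icer = NA_real_,
                          label = label), class = "vte_icer"))
  }
  ratio <- dc / de
  label <- if (dc <= 0 && de > 0) "dominant"
  else if (dc >= 0 && de < 0) "dominated"
  else "trade-off"
  structure(list(d_cost = dc, d_effect = de, icer = ratio, label = label),
            class = "vte_icer")
}

#' @export
print.vte_icer <- function(x, ...) {
  cat(sprintf("incremental cost %.2f, incremental effect %.4f QALY -> %s",
              x$d_cost, x$d_effect,
              if (is.na(x$icer)) x$label
              else sprintf("ICER %.0f per QALY (%s)", x$icer, x$label)), "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * d_effect - d_cost`: positive when the strategy is cost-effective at
#' the willingness-to-pay threshold.
#'
#' @param d_cost Incremental cost.
#' @param d_effect Incremental effect (QALY).
#' @param wtp Willingness-to-pay threshold (currency per QALY, >= 0).
#' @export
net_monetary_benefit <- function(d_cost, d_effect, wtp) {
  if (any(wtp < 0)) stop("willingness-to-pay must be non-negative")
  wtp * d_effect - d_cost
}
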