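# Cohort state-transition engine. Public surface: the 12 canonical health
# states, per-cycle transition matrices, and the cohort trace. Internally the
# engine expands the state space to 3 history tracks (index DVT only, PE
# history, both) x 14 states so that CTEPH eligibility (PE history), PTS
# eligibility (DVT history), bleed-origin bookkeeping and fatal-bleed counting
# stay exact; the public trace aggregates back to the 12 states.

#' The twelve model health states
#' @return Character vector of canonical state names.
#' @export
health_states <- function() {
  c("INDEX_DVT", "INDEX_PE", "ON_TREATMENT_NO_EVENT", "RECURRENT_DVT",
    "RECURRENT_PE", "MB_NON_IC", "IC_BLEED", "CRNMB", "CTEPH",
    "OFF_TREATMENT_NO_EVENT", "VTE_DEATH", "OTHER_DEATH")
}

.tracks <- c("dvt", "pe", "dvtpe")
.istates <- c("IDX", "ON", "OFF", "REC_DVT", "REC_PE", "MB_ON", "MB_OFF",
              "CRNMB_ON", "CRNMB_OFF", "IC", "CTEPH", "VTE_DEATH", "MB_DEATH",
              "OTHER_DEATH")

full_state_names <- function() {
  as.vector(t(outer(.tracks, .istates, paste, sep = ".")))
}

fs_index <- function(track, state) match(paste(track, state, sep = "."), full_state_names())

# map internal state -> canonical 12-state label
canonical_of <- function(track, state) {
  switch(state,
    IDX = if (track == "pe") "INDEX_PE" else "INDEX_DVT",
    ON = "ON_TREATMENT_NO_EVENT", OFF = "OFF_TREATMENT_NO_EVENT",
    REC_DVT = "RECURRENT_DVT", REC_PE = "RECURRENT_PE",
    MB_ON = "MB_NON_IC", MB_OFF = "MB_NON_IC",
    CRNMB_ON = "CRNMB", CRNMB_OFF = "CRNMB",
    IC = "IC_BLEED", CTEPH = "CTEPH",
    VTE_DEATH = "VTE_DEATH", MB_DEATH = "OTHER_DEATH",
    OTHER_DEATH = "OTHER_DEATH")
}

#' Treatment-arm specification
#'
#' @param name `"apixaban"` (extended anticoagulation) or `"no_treatment"`.
#' @param cohort_size Number of patients entering the model.
#' @param horizon_cycles Number of 3-month cycles; `NULL` means lifetime (to
#'   the maximum tabulated age).
#' @param start_age Age in years at model entry.
#' @param male_fraction Fraction male (fixed sex mix throughout).
#' @param index_pe_fraction Fraction whose index event was a PE.
#' @param include_initial_phase Prepend the 6-month initial treatment phase
#'   (requires an `acute` block in the parameter set).
#' @return Object of class `vte_arm_spec`.
#' @export
arm_spec <- function(name = c("apixaban", "no_treatment"), cohort_size = 1000,
                     horizon_cycles = NULL, start_age = 56.9,
                     male_fraction = 0.58, index_pe_fraction = 0.34,
                     include_initial_phase = FALSE) {
  name <- match.arg(name)
  if (cohort_size < 0) stop("cohort size must be non-negative")
  if (!is.null(horizon_cycles) &&
      horizon_cycles < (if (include_initial_phase) 0 else 1))
    stop("horizon must be >= 1 cycle")
  if (start_age < 0 || start_age >= 100) stop("start age must lie within the life-table span")
  if (index_pe_fraction < 0 || index_pe_fraction > 1) stop("index PE fraction in [0, 1]")
  structure(list(name = name, cohort_size = cohort_size,
                 horizon_cycles = horizon_cycles, start_age = start_age,
                 male_fraction = male_fraction,
                 index_pe_fraction = index_pe_fraction,
                 include_initial_phase = include_initial_phase),
            class = "vte_arm_spec")
}

#' Engine options
#'
#' @param half_cycle Apply a half-cycle correction to person-time accrual
#'   (default `FALSE`; the validation counts are reproduced without it).
#' @param cteph_scope `"pe_history"` applies the CTEPH risk to everyone with a
#'   PE (index or recurrent); `"index_pe"` restricts it to the index-PE group.
#' @param post18_bleeding `"arm_specific"` keeps each arm's own bleeding risks
#'   beyond 18 months; `"no_treatment"` switches both arms to the untreated
#'   values there.
#' @param pts_accrual_years Window (from model entry) over which the 5-year
#'   severe-PTS risk accrues among DVT-history patients.
#' @return List of class `vte_engine_control`.
#' @export
engine_control <- function(half_cycle = FALSE,
                           cteph_scope = c("pe_history", "index_pe"),
                           post18_bleeding = c("arm_specific", "no_treatment"),
                           pts_accrual_years = 5) {
  structure(list(half_cycle = half_cycle,
                 cteph_scope = match.arg(cteph_scope),
                 post18_bleeding = match.arg(post18_bleeding),
                 pts_accrual_years = pts_accrual_years),
            class = "vte_engine_control")
}

# competing-risk composition: independent cause-specific probabilities are
# composed on the survival scale and each cause's share of the total exit is
# allocated proportionally to its rate (order-independent).
compose_risks <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  if (any(p >= 1 - 1e-12)) {               # an (effectively) certain cause takes all
    out <- numeric(length(p)); names(out) <- names(p)
    sure <- p >= 1 - 1e-12
    out[sure] <- 1 / sum(sure)
    return(list(alloc = out, stay = 0))
  }
  lam <- -log1p(-p)
  tot <- sum(lam)
  if (tot == 0) return(list(alloc = stats::setNames(numeric(length(p)), names(p)), stay = 1))
  exit <- 1 - exp(-tot)
  list(alloc = exit * lam / tot, stay = 1 - exit)
}

# per-cycle hazard bundle for one arm at one cycle (shared across tracks,
# except CTEPH eligibility and the mortality HR which are track-specific)
cycle_inputs <- function(arm, cycle, params, life_table, control) {
  cyc_mo <- params$cohort$cycle_months
  cyc_yr <- cyc_mo / 12
  n_initial <- if (arm$include_initial_phase) round(6 / cyc_mo) else 0
  cycle_ext <- cycle - n_initial
  t_model <- (cycle - 1) * cyc_yr
  t_ext <- (cycle_ext - 1) * cyc_yr            # years since extended-phase entry
  age <- arm$start_age + t_model
  base_age <- arm$start_age

  iv_names <- c("m6_9", "m9_12", "m12_15", "m15_18")
  iv <- function(arm_nm) vapply(params$recurrence[[arm_nm]][iv_names],
                                function(e) e$mean, 0)

  in_window <- cycle_ext >= 1 && cycle_ext <= length(iv_names)
  if (cycle_ext < 1) {                         # initial phase: ON/OFF unoccupied
    p_rec_on <- p_rec_off <- 0
  } else if (in_window) {
    p_rec_on <- unname(iv(arm$name)[cycle_ext])
    p_rec_off <- unname(iv("no_treatment")[cycle_ext])
  } else {
    # anticoagulated states: post-cessation hazard scaled by the trial's
    # treatment effect; a degenerate all-zero untreated arm leaves it neutral
    te <- if (all(iv("no_treatment") == 0)) 1
    else treatment_effect_rr(iv("apixaban"), iv("no_treatment"))
    p_off <- piecewise_recurrence_probability(params$post_cessation_curve,
                                              max(t_ext, 0), cyc_mo)
    p_rec_on <- 1 - (1 - p_off)^te
    p_rec_off <- p_off
  }

  bleed_arm_on <- arm$name
  if (!in_window && cycle_ext >= 1 && control$post18_bleeding == "no_treatment")
    bleed_arm_on <- "no_treatment"
  # trial-window bleeding risks are the trial's own; the per-decade aging
  # adjustment applies to the constant risks carried beyond 18 months
  adj_age <- if (cycle_ext > length(iv_names)) max(age, base_age) else base_age
  fac <- params$bleeding_age_factor$mean
  bleed <- function(est) age_adjust_bleeding(
    to_cycle_probability(est$mean, est$basis_months, cyc_mo), adj_age, base_age, fac)
  p_mb_on <- bleed(params$mb[[bleed_arm_on]])
  p_mb_off <- bleed(params$mb[["no_treatment"]])
  p_crnmb_on <- bleed(params$crnmb[[bleed_arm_on]])
  p_crnmb_off <- bleed(params$crnmb[["no_treatment"]])

  p_disc <- to_cycle_probability(params$other_discontinuation$mean,
                                 params$other_discontinuation$basis_months, cyc_mo)
  p_cteph <- to_cycle_probability(params$cteph_annual$mean,
                                  params$cteph_annual$basis_months, cyc_mo)
  hr <- vapply(params$mortality_hr, function(e) e$mean, 0)
  mort <- function(h) background_mortality(age, arm$male_fraction, life_table, h, cyc_mo)

  list(cycle_ext = cycle_ext, in_initial = cycle_ext < 1, age = age,
       p_rec_on = p_rec_on, p_rec_off = p_rec_off,
       p_mb_on = p_mb_on, p_mb_off = p_mb_off,
       p_crnmb_on = p_crnmb_on, p_crnmb_off = p_crnmb_off,
       p_disc = p_disc, p_cteph = p_cteph,
       split = params$event_split,
       p_fatal_mb = params$fatal_mb_proportion$mean,
       p_ic = params$nonfatal_ic_proportion$mean,
       mort_track = c(dvt = mort(hr[["index_dvt"]]), pe = mort(hr[["index_pe"]]),
                      dvtpe = mort(hr[["index_pe"]])),
       mort_ic = c(dvt = mort(hr[["index_dvt"]] * hr[["post_ic"]]),
                   pe = mort(hr[["index_pe"]] * hr[["post_ic"]]),
                   dvtpe = mort(hr[["index_pe"]] * hr[["post_ic"]])),
       mort_cteph = c(dvt = mort(hr[["index_dvt"]] * hr[["post_cteph"]]),
                      pe = mort(hr[["index_pe"]] * hr[["post_cteph"]]),
                      dvtpe = mort(hr[["index_pe"]] * hr[["post_cteph"]])),
       n_initial = if (arm$include_initial_phase) round(6 / cyc_mo) else 0)
}

# Build the full (expanded-state) transition matrix for one cycle.
build_full_matrix <- function(arm, cycle, params, life_table,
                              control = engine_control()) {
  ci <- cycle_inputs(arm, cycle, params, life_table, control)
  nms <- full_state_names()
  n <- length(nms)
  M <- matrix(0, n, n, dimnames = list(nms, nms))

  dest_pe_track <- c(dvt = "dvtpe", pe = "pe", dvtpe = "dvtpe")
  dest_dvt_track <- c(dvt = "dvt", pe = "dvtpe", dvtpe = "dvtpe")

  treated_row <- function(track) {
    eligible <- control$cteph_scope == "pe_history" && track %in% c("pe", "dvtpe") ||
      control$cteph_scope == "index_pe" && track == "pe"
    p <- c(rec = ci$p_rec_on, mb = ci$p_mb_on, crnmb = ci$p_crnmb_on,
           cteph = if (eligible) ci$p_cteph else 0,
           disc = ci$p_disc, mort = ci$mort_track[[track]])
    cr <- compose_risks(p)
    row <- numeric(length(nms))
    a <- cr$alloc
    row[fs_index(track, "VTE_DEATH")] <- a[["rec"]] * ci$split[["vte_death"]]
    row[fs_index(dest_pe_track[[track]], "REC_PE")] <- a[["rec"]] * ci$split[["recurrent_pe"]]
    row[fs_index(dest_dvt_track[[track]], "REC_DVT")] <- a[["rec"]] * ci$split[["recurrent_dvt"]]
    row[fs_index(track, "MB_DEATH")] <- a[["mb"]] * ci$p_fatal_mb
    row[fs_index(track, "IC")] <- a[["mb"]] * (1 - ci$p_fatal_mb) * ci$p_ic
    row[fs_index(track, "MB_ON")] <- a[["mb"]] * (1 - ci$p_fatal_mb) * (1 - ci$p_ic)
    row[fs_index(track, "CRNMB_ON")] <- a[["crnmb"]]
    row[fs_index(track, "CTEPH")] <- row[fs_index(track, "CTEPH")] + a[["cteph"]]
    row[fs_index(track, "OFF")] <- a[["disc"]]
    row[fs_index(track, "OTHER_DEATH")] <- a[["mort"]]
    row[fs_index(track, "ON")] <- row[fs_index(track, "ON")] + cr$stay
    row
  }

  untreated_row <- function(track) {
    eligible <- control$cteph_scope == "pe_history" && track %in% c("pe", "dvtpe") ||
      control$cteph_scope == "index_pe" && track == "pe"
    p <- c(rec = ci$p_rec_off, mb = ci$p_mb_off, crnmb = ci$p_crnmb_off,
           cteph = if (eligible) ci$p_cteph else 0,
           mort = ci$mort_track[[track]])
    cr <- compose_risks(p)
    row <- numeric(length(nms))
    a <- cr$alloc
    row[fs_index(track, "VTE_DEATH")] <- a[["rec"]] * ci$split[["vte_death"]]
    row[fs_index(dest_pe_track[[track]], "REC_PE")] <- a[["rec"]] * ci$split[["recurrent_pe"]]
    row[fs_index(dest_dvt_track[[track]], "REC_DVT")] <- a[["rec"]] * ci$split[["recurrent_dvt"]]
    row[fs_index(track, "MB_DEATH")] <- a[["mb"]] * ci$p_fatal_mb
    row[fs_index(track, "IC")] <- a[["mb"]] * (1 - ci$p_fatal_mb) * ci$p_ic
    row[fs_index(track, "MB_OFF")] <- a[["mb"]] * (1 - ci$p_fatal_mb) * (1 - ci$p_ic)
    row[fs_index(track, "CRNMB_OFF")] <- a[["crnmb"]]
    row[fs_index(track, "CTEPH")] <- row[fs_index(track, "CTEPH")] + a[["cteph"]]
    row[fs_index(track, "OTHER_DEATH")] <- a[["mort"]]
    row[fs_index(track, "OFF")] <- row[fs_index(track, "OFF")] + cr$stay
    row
  }

  chronic_row <- function(track, state, p_mort, eligible_cteph = FALSE) {
    p <- c(cteph = if (eligible_cteph) ci$p_cteph else 0, mort = p_mort)
    cr <- compose_risks(p)
    row <- numeric(length(nms))
    row[fs_index(track, "CTEPH")] <- cr$alloc[["cteph"]]
    row[fs_index(track, "OTHER_DEATH")] <- cr$alloc[["mort"]]
    row[fs_index(track, state)] <- row[fs_index(track, state)] + cr$stay
    row
  }

  idx_row <- function(track) {
    if (!ci$in_initial) return(treated_row(track))
    ac <- params$acute
    if (is.null(ac)) stop("acute parameters required for the initial phase")
    blk <- if (arm$name == "apixaban") ac$apixaban else ac$lmwh_vka
    p <- c(rec = blk$recurrence_cycle, mb = blk$mb_cycle, crnmb = blk$crnmb_cycle,
           mort = ci$mort_track[[track]])
    cr <- compose_risks(p)
    row <- numeric(length(nms))
    a <- cr$alloc
    row[fs_index(track, "VTE_DEATH")] <- a[["rec"]] * ci$split[["vte_death"]]
    row[fs_index(dest_pe_track[[track]], "REC_PE")] <- a[["rec"]] * ci$split[["recurrent_pe"]]
    row[fs_index(dest_dvt_track[[track]], "REC_DVT")] <- a[["rec"]] * ci$split[["recurrent_dvt"]]
    row[fs_index(track, "MB_DEATH")] <- a[["mb"]] * ci$p_fatal_mb
    row[fs_index(track, "IC")] <- a[["mb"]] * (1 - ci$p_fatal_mb) * ci$p_ic
    row[fs_index(track, "MB_ON")] <- a[["mb"]] * (1 - ci$p_fatal_mb) * (1 - ci$p_ic)
    row[fs_index(track, "CRNMB_ON")] <- a[["crnmb"]]
    row[fs_index(track, "OTHER_DEATH")] <- a[["mort"]]
    # stay: remain in the index state until the initial phase ends, then move
    # to the arm's extended-phase track (apixaban continues; LMWH/VKA stops)
    last_initial <- ci$cycle_ext == 0
    stay_state <- if (!last_initial) "IDX" else if (arm$name == "apixaban") "ON" else "OFF"
    row[fs_index(track, stay_state)] <- row[fs_index(track, stay_state)] + cr$stay
    row
  }

  for (track in .tracks) {
    M[fs_index(track, "IDX"), ] <- idx_row(track)
    on_r <- treated_row(track)
    off_r <- untreated_row(track)
    M[fs_index(track, "ON"), ] <- on_r
    for (s in c("REC_DVT", "REC_PE", "MB_ON", "CRNMB_ON"))
      M[fs_index(track, s), ] <- on_r
    M[fs_index(track, "OFF"), ] <- off_r
    for (s in c("MB_OFF", "CRNMB_OFF"))
      M[fs_index(track, s), ] <- off_r
    eligible <- control$cteph_scope == "pe_history" && track %in% c("pe", "dvtpe") ||
      control$cteph_scope == "index_pe" && track == "pe"
    M[fs_index(track, "IC"), ] <- chronic_row(track, "IC", ci$mort_ic[[track]], eligible)
    M[fs_index(track, "CTEPH"), ] <- chronic_row(track, "CTEPH", ci$mort_cteph[[track]], FALSE)
    for (s in c("VTE_DEATH", "MB_DEATH", "OTHER_DEATH")) {
      i <- fs_index(track, s); M[i, i] <- 1
    }
  }

  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative transition probability %s -> %s",
                 nms[bad[1]], nms[bad[2]]))
  }
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9))
    stop(sprintf("transition row '%s' sums to %.12f", nms[which.max(abs(rs - 1))],
                 rs[which.max(abs(rs - 1))]))
  M
}

#' Per-cycle transition matrix over the twelve health states
#'
#' Returns the row-stochastic 12 x 12 matrix for one stratum (index event
#' group) at one cycle. Event states are one-cycle states whose outgoing risks
#' equal the treatment track they belong to; `run_cohort()` additionally
#' splits bleeding states by treatment status internally so that a bleed never
#' changes a patient's treatment status.
#'
#' @param arm A [arm_spec()].
#' @param cycle Cycle index (1-based).
#' @param params A `vte_parameter_set`.
#' @param life_table A `vte_life_table`.
#' @param stratum `"index_dvt"` or `"index_pe"`.
#' @param control Engine options, see [engine_control()].
#' @return 12 x 12 matrix with rows/columns named by [health_states()].
#' @export
build_matrix <- function(arm, cycle, params, life_table,
                         stratum = c("index_dvt", "index_pe"),
                         control = engine_control()) {
  stratum <- match.arg(stratum)
  track <- if (stratum == "index_dvt") "dvt" else "pe"
  Mf <- build_full_matrix(arm, cycle, params, life_table, control)
  hs <- health_states()
  M <- matrix(0, 12, 12, dimnames = list(hs, hs))
  # representative internal state per canonical row (treated variant for the
  # shared event states; index rows for the entry states)
  rep_state <- c(INDEX_DVT = "IDX", INDEX_PE = "IDX",
                 ON_TREATMENT_NO_EVENT = "ON", RECURRENT_DVT = "REC_DVT",
                 RECURRENT_PE = "REC_PE", MB_NON_IC = "MB_ON", IC_BLEED = "IC",
                 CRNMB = "CRNMB_ON", CTEPH = "CTEPH",
                 OFF_TREATMENT_NO_EVENT = "OFF", VTE_DEATH = "VTE_DEATH",
                 OTHER_DEATH = "OTHER_DEATH")
  for (h in hs) {
    tr_row <- if (h == "INDEX_PE") "pe" else if (h == "INDEX_DVT") "dvt" else track
    src <- Mf[fs_index(tr_row, rep_state[[h]]), ]
    for (j in seq_along(src)) {
      if (src[j] == 0) next
      parts <- strsplit(names(src)[j], ".", fixed = TRUE)[[1]]
      M[h, canonical_of(parts[1], parts[2])] <-
        M[h, canonical_of(parts[1], parts[2])] + src[j]
    }
  }
  M
}

#' Run the cohort through the model
#'
#' Iterates the cohort occupancy through the per-cycle transition matrices
#' from the index-event split, tracking state occupancy, cumulative event
#' counters, the background severe-PTS fraction and person-time on each drug.
#'
#' @inheritParams build_matrix
#' @return Object of class `vte_cohort_trace` with elements `occupancy`
#'   (cycle x 12 canonical states, persons), `events` (per-cycle event
#'   counts), `cumulative` (running totals), `pts_affected`, `on_drug`,
#'   `alive`, `times` (years since model entry at each cycle start).
#' @export
run_cohort <- function(arm, params, life_table, control = engine_control()) {
  cyc_yr <- params$cohort$cycle_months / 12
  n_initial <- if (arm$include_initial_phase) round(6 / params$cohort$cycle_months) else 0
  lifetime <- ceiling((params$cohort$max_age - arm$start_age) / cyc_yr) + 1
  horizon <- arm$horizon_cycles %||% (lifetime - n_initial)
  horizon <- horizon + n_initial
  if (horizon > lifetime + n_initial) {
    warning("horizon exceeds the maximum age; truncated")
    horizon <- lifetime + n_initial
  }

  nms <- full_state_names()
  occ <- stats::setNames(numeric(length(nms)), nms)
  pe <- arm$index_pe_fraction * arm$cohort_size
  dvt <- (1 - arm$index_pe_fraction) * arm$cohort_size
  if (arm$include_initial_phase) {
    if (is.null(params$acute)) stop("acute parameters required for the initial phase")
    occ[fs_index("dvt", "IDX")] <- dvt
    occ[fs_index("pe", "IDX")] <- pe
  } else if (arm$name == "apixaban") {
    occ[fs_index("dvt", "ON")] <- dvt
    occ[fs_index("pe", "ON")] <- pe
  } else {
    occ[fs_index("dvt", "OFF")] <- dvt
    occ[fs_index("pe", "OFF")] <- pe
  }

  ev_cats <- c("recurrent_dvt", "recurrent_pe", "vte_death", "mb_fatal",
               "mb_ic", "mb_extracranial", "crnmb", "cteph", "discontinuation",
               "other_death")
  events <- matrix(0, horizon, length(ev_cats), dimnames = list(NULL, ev_cats))
  occ_hist <- matrix(0, horizon + 1, length(nms), dimnames = list(NULL, nms))
  occ_hist[1, ] <- occ
  pts_affected <- numeric(horizon)
  drugs <- c("apixaban", "vka", "lmwh_vka_initial", "apixaban_initial")
  on_drug <- matrix(0, horizon, length(drugs), dimnames = list(NULL, drugs))

  dead_states <- c("VTE_DEATH", "MB_DEATH", "OTHER_DEATH")
  alive_cols <- which(!sub("^[a-z]+\\.", "", nms) %in% dead_states)
  treated_states <- c("IDX", "ON", "REC_DVT", "REC_PE", "MB_ON", "CRNMB_ON", "CTEPH")
  treated_cols <- which(sub("^[a-z]+\\.", "", nms) %in% treated_states)
  idx_cols <- which(sub("^[a-z]+\\.", "", nms) == "IDX")
  onlike_rows <- which(sub("^[a-z]+\\.", "", nms) %in%
                         c("ON", "REC_DVT", "REC_PE", "MB_ON", "CRNMB_ON"))
  col_of <- function(state) which(sub("^[a-z]+\\.", "", nms) == state)
  pts_tracks_cols <- which(sub("\\..*$", "", nms) %in% c("dvt", "dvtpe") &
                             !sub("^[a-z]+\\.", "", nms) %in% dead_states)

  # background severe-PTS process among DVT-history patients
  p_pts <- to_cycle_probability(params$pts_5y$mean, params$pts_5y$basis_months,
                                params$cohort$cycle_months)
  pts_frac <- 0

  for (k in seq_len(horizon)) {
    M <- build_full_matrix(arm, k, params, life_table, control)
    Fl <- occ * M                                   # flows: row = from, col = to
    occ_new <- colSums(Fl)

    events[k, "recurrent_dvt"] <- sum(Fl[, col_of("REC_DVT")])
    events[k, "recurrent_pe"] <- sum(Fl[, col_of("REC_PE")])
    events[k, "vte_death"] <- sum(Fl[, col_of("VTE_DEATH")]) -
      sum(occ[col_of("VTE_DEATH")])
    events[k, "mb_fatal"] <- sum(Fl[, col_of("MB_DEATH")]) -
      sum(occ[col_of("MB_DEATH")])
    ic_cols <- col_of("IC")
    events[k, "mb_ic"] <- sum(Fl[-ic_cols, ic_cols])
    events[k, "mb_extracranial"] <- sum(Fl[, c(col_of("MB_ON"), col_of("MB_OFF"))])
    events[k, "crnmb"] <- sum(Fl[, c(col_of("CRNMB_ON"), col_of("CRNMB_OFF"))])
    ct_cols <- col_of("CTEPH")
    events[k, "cteph"] <- sum(Fl[-ct_cols, ct_cols])
    events[k, "discontinuation"] <- sum(Fl[onlike_rows, col_of("OFF")])
    events[k, "other_death"] <- sum(Fl[, col_of("OTHER_DEATH")]) -
      sum(occ[col_of("OTHER_DEATH")])

    # PTS accrues among alive DVT-history patients within the accrual window
    t_model <- (k - 1) * cyc_yr
    if (t_model < control$pts_accrual_years)
      pts_frac <- pts_frac + (1 - pts_frac) * p_pts
    pts_affected[k] <- pts_frac * sum(occ[pts_tracks_cols])

    drug_now <- if (arm$name == "apixaban") "apixaban" else "vka"
    on_drug[k, drug_now] <- sum(occ[setdiff(treated_cols, idx_cols)])
    if (n_initial > 0 && k <= n_initial) {
      init_drug <- if (arm$name == "apixaban") "apixaban_initial" else "lmwh_vka_initial"
      on_drug[k, init_drug] <- sum(occ[idx_cols])
    }

    occ <- occ_new
    occ_hist[k + 1, ] <- occ
  }

  agg <- matrix(0, horizon + 1, 12, dimnames = list(NULL, health_states()))
  for (j in seq_along(nms)) {
    parts <- strsplit(nms[j], ".", fixed = TRUE)[[1]]
    cn <- canonical_of(parts[1], parts[2])
    agg[, cn] <- agg[, cn] + occ_hist[, j]
  }

  structure(list(
    arm = arm, control = control,
    occupancy = agg, occupancy_full = occ_hist,
    events = events, cumulative = apply(events, 2, cumsum),
    pts_affected = pts_affected, on_drug = on_drug,
    interruption = list(
      p_mb = params$interruption_non_ic_mb$mean,
      days_mb = params$interruption_days[["non_ic_mb"]],
      p_crnmb = params$interruption_crnmb$mean,
      days_crnmb = params$interruption_days[["crnmb"]]),
    alive = rowSums(occ_hist[, alive_cols, drop = FALSE]),
    times = (seq_len(horizon + 1) - 1) * cyc_yr,
    cycle_years = cyc_yr, cohort_size = arm$cohort_size,
    n_initial = n_initial), class = "vte_cohort_trace")
}

#' Cumulative event counts from a trace
#'
#' Integer-rounded cumulative counts by clinical category, in the shape of the
#' published event tables.
#'
#' @param trace A `vte_cohort_trace`.
#' @param rounded Round to whole events (default) or return raw expectations.
#' @return `data.frame` with columns `outcome` and `events`.
#' @export
count_events <- function(trace, rounded = TRUE) {
  tot <- trace$cumulative[nrow(trace$cumulative), ]
  out <- c(
    vte_death = tot[["vte_death"]],
    recurrent_pe = tot[["recurrent_pe"]],
    recurrent_dvt = tot[["recurrent_dvt"]],
    recurrent_vte_total = tot[["vte_death"]] + tot[["recurrent_pe"]] +
      tot[["recurrent_dvt"]],
    mb_fatal = tot[["mb_fatal"]],
    mb_ic = tot[["mb_ic"]],
    mb_extracranial = tot[["mb_extracranial"]],
    mb_total = tot[["mb_fatal"]] + tot[["mb_ic"]] + tot[["mb_extracranial"]],
    crnmb = tot[["crnmb"]],
    cteph = tot[["cteph"]],
    discontinuation = tot[["discontinuation"]],
    all_cause_death = tot[["vte_death"]] + tot[["mb_fatal"]] + tot[["other_death"]])
  if (rounded) out <- round(out)
  data.frame(outcome = names(out), events = unname(out))
}

#' @export
print.vte_cohort_trace <- function(x, ...) {
  cat(sprintf("<vte_cohort_trace> arm '%s', %g patients, %d cycles\n",
              x$arm$name, x$cohort_size, nrow(x$events)))
  cat(sprintf("  alive at end: %.1f\n", x$alive[length(x$alive)]))
  ce <- count_events(x)
  cat("  cumulative events:\n")
  for (i in seq_len(nrow(ce))) cat(sprintf("    %-20s %6d\n", ce$outcome[i], ce$events[i]))
  invisible(x)
}
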