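# Parameter registry: typed estimates, the YAML loader with validation, and
# flat access paths used by the sensitivity analyses.

#' Probability estimate with uncertainty
#'
#' @param mean Point estimate in `[0, 1]`.
#' @param ci_low,ci_high 95% confidence bounds; `NA` when unavailable (a 30%
#'   standard error is then assumed at distribution-fitting time).
#' @param distribution One of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet_component"`, `"fixed"`.
#' @param basis_months Period in months the probability refers to.
#' @param label Optional human-readable name.
#' @return Object of class `vte_estimate`.
#' @export
probability_estimate <- function(mean, ci_low = NA_real_, ci_high = NA_real_,
                                 distribution = "beta", basis_months = 3,
                                 label = NULL) {
  distribution <- match.arg(distribution,
    c("beta", "gamma", "lognormal", "dirichlet_component", "fixed"))
  if (mean < 0 || mean > 1) stop(sprintf("probability mean %g outside [0, 1]", mean))
  if (!is.na(ci_low) && !is.na(ci_high)) {
    if (!(ci_low <= mean + 1e-12 && mean <= ci_high + 1e-12))
      stop(sprintf("CI ordering violated for '%s': (%g, %g, %g)",
                   label %||% "estimate", ci_low, mean, ci_high))
    if (ci_low < 0 || ci_high > 1) stop("probability CI outside [0, 1]")
  }
  if (distribution == "fixed") { ci_low <- mean; ci_high <- mean }
  if (basis_months <= 0) stop("basis_months must be positive")
  structure(list(mean = mean, ci_low = ci_low, ci_high = ci_high,
                 distribution = distribution, basis_months = basis_months,
                 kind = "probability", label = label),
            class = "vte_estimate")
}

#' Hazard-ratio estimate with uncertainty
#'
#' @inheritParams probability_estimate
#' @export
hazard_ratio_estimate <- function(mean, ci_low = NA_real_, ci_high = NA_real_,
                                  distribution = "gamma", label = NULL) {
  distribution <- match.arg(distribution, c("gamma", "lognormal", "fixed"))
  if (mean <= 0) stop("hazard ratio must be strictly positive")
  if (!is.na(ci_low) && !is.na(ci_high)) {
    if (!(0 < ci_low && ci_low <= mean + 1e-12 && mean <= ci_high + 1e-12))
      stop(sprintf("CI ordering violated for '%s'", label %||% "hazard ratio"))
  }
  structure(list(mean = mean, ci_low = ci_low, ci_high = ci_high,
                 distribution = distribution, basis_months = NA_real_,
                 kind = "hazard_ratio", label = label),
            class = "vte_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

est_from_yaml <- function(x, kind = "probability", label = NULL) {
  if (is.numeric(x)) x <- list(mean = x)
  if (kind == "probability") {
    probability_estimate(x$mean, x$ci_low %||% NA_real_, x$ci_high %||% NA_real_,
                         x$distribution %||% "beta", x$basis_months %||% 3, label)
  } else {
    hazard_ratio_estimate(x$mean, x$ci_low %||% NA_real_, x$ci_high %||% NA_real_,
                          x$distribution %||% "gamma", label)
  }
}

value_from_yaml <- function(x, label) {
  # cost/utility registry entry: mean + sampling family + provenance flag
  if (is.numeric(x)) x <- list(mean = x)
  structure(list(mean = x$mean, distribution = x$distribution %||% "gamma",
                 provenance = x$provenance %||% "placeholder",
                 duration_years = x$duration_years %||% NA_real_,
                 kind = "value", label = label),
            class = "vte_estimate")
}

#' Load a model parameter file
#'
#' Reads the YAML parameter file (transition probabilities, hazard ratios,
#' cost and utility registries, cohort settings and discount rates), validates
#' every entry (confidence-interval ordering, probability bounds, proportions
#' summing to one) and returns a `vte_parameter_set`. Known typographical
#' corrections applied during loading are recorded in `$corrections`, and all
#' placeholder-provenance cost/utility entries are listed in `$placeholders`.
#'
#' @param path Path to a parameter YAML file.
#' @return Object of class `vte_parameter_set`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path))
  raw <- yaml::read_yaml(path)
  tr <- raw$transitions
  if (is.null(tr)) stop(sprintf("%s: missing 'transitions' section", path))

  rec <- lapply(c(apixaban = "apixaban", no_treatment = "no_treatment"), function(arm) {
    iv <- tr$recurrence[[arm]]
    if (is.null(iv) || !all(c("m6_9", "m9_12", "m12_15", "m15_18") %in% names(iv)))
      stop(sprintf("recurrence intervals missing for arm '%s'", arm))
    lapply(names(iv), function(nm)
      est_from_yaml(iv[[nm]], label = paste("recurrence", arm, nm))) |>
      stats::setNames(names(iv))
  })

  split <- unlist(tr$event_split)
  if (abs(sum(split) - 1) > 1e-9)
    stop(sprintf("event-split proportions sum to %.10f, not 1", sum(split)))

  corrections <- character(0)
  knots <- lapply(tr$post_cessation_ci, function(k) {
    if (!is.null(k$printed_mean) && !identical(k$printed_mean, k$mean))
      corrections <<- c(corrections, sprintf(
        "post-cessation knot at %g y: printed value %g corrected to %g (CI %g-%g)",
        k$time_years, k$printed_mean, k$mean, k$ci_low, k$ci_high))
    est <- est_from_yaml(k, label = sprintf("post-cessation CI %g y", k$time_years))
    est$time_years <- k$time_years
    est
  })
  curve <- cumulative_incidence_curve(
    vapply(knots, function(k) k$time_years, 0),
    vapply(knots, function(k) k$mean, 0))

  idx_pe <- raw$cohort$index_pe_fraction
  if (abs(idx_pe + (1 - idx_pe) - 1) > 1e-9 || idx_pe < 0 || idx_pe > 1)
    stop("index-event proportions must sum to 1")
  if (raw$discounting$costs_annual < 0 || raw$discounting$effects_annual < 0)
    stop("discount rates must be non-negative")

  named_est <- function(section, kind = "probability")
    lapply(stats::setNames(names(section), names(section)), function(nm)
      est_from_yaml(section[[nm]], kind, nm))

  ps <- structure(list(
    cohort = raw$cohort,
    discounting = raw$discounting,
    recurrence = rec,
    event_split = split,
    event_split_n = tr$event_split_n %||% 101,
    post_cessation_knots = knots,
    post_cessation_curve = curve,
    mb = named_est(tr$mb),
    crnmb = named_est(tr$crnmb),
    fatal_mb_proportion = est_from_yaml(tr$fatal_mb_proportion, label = "fatal MB proportion"),
    nonfatal_ic_proportion = est_from_yaml(tr$nonfatal_ic_proportion, label = "nonfatal IC proportion"),
    bleeding_age_factor = est_from_yaml(tr$bleeding_age_factor, "hazard_ratio",
                                        "bleeding age factor per decade"),
    interruption_non_ic_mb = est_from_yaml(tr$interruption_non_ic_mb, label = "interruption after non-IC MB"),
    interruption_crnmb = est_from_yaml(tr$interruption_crnmb, label = "interruption after CRNMB"),
    interruption_days = c(
      non_ic_mb = tr$interruption_non_ic_mb$duration_days %||% 14,
      crnmb = tr$interruption_crnmb$duration_days %||% 2),
    other_discontinuation = est_from_yaml(tr$other_discontinuation, label = "other discontinuation"),
    cteph_annual = est_from_yaml(tr$cteph_annual, label = "annual CTEPH risk"),
    pts_5y = est_from_yaml(tr$pts_5y, label = "5-year severe PTS risk"),
    mortality_hr = named_est(tr$mortality_hr, "hazard_ratio"),
    costs = build_cost_registry(raw$costs),
    utilities = build_utility_registry(raw$utilities),
    acute = raw$acute,        # optional initial-phase block (scenario 1 / 6-month validation)
    corrections = corrections,
    source = path), class = "vte_parameter_set")
  ps$placeholders <- placeholder_entries(ps)
  ps
}

build_cost_registry <- function(x) {
  walk <- function(node, path) {
    if (is.list(node) && !is.null(node$mean))
      return(stats::setNames(list(value_from_yaml(node, path)), path))
    if (is.list(node))
      return(do.call(c, lapply(names(node), function(nm)
        walk(node[[nm]], if (nzchar(path)) paste(path, nm, sep = ".") else nm))))
    stats::setNames(list(value_from_yaml(node, path)), path)
  }
  reg <- walk(x, "")
  for (v in reg) if (v$mean < 0) stop(sprintf("negative cost for '%s'", v$label))
  structure(reg, class = "vte_cost_registry")
}

build_utility_registry <- function(x) {
  reg <- list(baseline = value_from_yaml(x$baseline, "baseline"))
  reg$event_decrement <- lapply(stats::setNames(names(x$event_decrement), names(x$event_decrement)),
    function(nm) {
      v <- value_from_yaml(x$event_decrement[[nm]], paste0("event_decrement.", nm))
      v$duration_years <- x$event_decrement[[nm]]$duration_years %||% 0.25
      v
    })
  reg$state_decrement <- lapply(stats::setNames(names(x$state_decrement), names(x$state_decrement)),
    function(nm) value_from_yaml(x$state_decrement[[nm]], paste0("state_decrement.", nm)))
  if (reg$baseline$mean < 0 || reg$baseline$mean > 1) stop("baseline utility outside [0, 1]")
  decs <- c(reg$event_decrement, reg$state_decrement)
  for (d in decs) if (d$mean < 0) stop(sprintf("negative utility decrement '%s'", d$label))
  structure(reg, class = "vte_utility_registry")
}

placeholder_entries <- function(ps) {
  out <- character(0)
  for (v in ps$costs) if (identical(v$provenance, "placeholder"))
    out <- c(out, paste0("costs.", v$label))
  u <- ps$utilities
  for (v in c(list(u$baseline), u$event_decrement, u$state_decrement))
    if (identical(v$provenance, "placeholder")) out <- c(out, paste0("utilities.", v$label))
  out
}

#' Packaged default parameter set
#'
#' Loads the parameter fixture shipped with the package: published transition
#' probabilities and hazard ratios plus a cost/utility registry whose entries
#' are deliberate placeholders (provenance `"placeholder"`), since the
#' authoritative unit values live in supplementary material outside this
#' package. `$placeholders` enumerates every non-authoritative entry.
#'
#' @param quiet Suppress the placeholder report message.
#' @return A `vte_parameter_set`.
#' @export
default_fixture_parameters <- function(quiet = TRUE) {
  ps <- load_parameters(system.file("extdata", "parameters.yaml", package = "vtecea",
                                    mustWork = TRUE))
  if (!quiet && length(ps$placeholders))
    message("placeholder cost/utility entries: ", paste(ps$placeholders, collapse = ", "))
  ps
}

#' Are all cost/utility entries authoritative?
#'
#' `TRUE` only when no registry entry carries placeholder provenance, i.e. the
#' user supplied a transcribed cost/utility file. Published cost-effectiveness
#' results are only comparable in that case.
#'
#' @param ps A `vte_parameter_set`.
#' @export
is_authoritative <- function(ps) length(placeholder_entries(ps)) == 0

#' @export
print.vte_parameter_set <- function(x, ...) {
  cat("<vte_parameter_set>\n")
  cat(sprintf("  cohort: start age %.1f y, %.0f%% male, %.0f%% index PE, cycle %d mo\n",
              x$cohort$start_age, 100 * x$cohort$male_fraction,
              100 * x$cohort$index_pe_fraction, x$cohort$cycle_months))
  cat(sprintf("  discounting: costs %.1f%%/y, effects %.1f%%/y\n",
              100 * x$discounting$costs_annual, 100 * x$discounting$effects_annual))
  cat(sprintf("  placeholder cost/utility entries: %d\n", length(x$placeholders)))
  if (length(x$corrections))
    cat("  corrections:", paste(x$corrections, collapse = "; "), "\n")
  invisible(x)
}

# ---- flat estimate registry (used by PSA / tornado) ------------------------

#' Flat registry of uncertain parameters
#'
#' Returns a named list of every `vte_estimate` in the set, keyed by a
#' dot-separated path (e.g. `"recurrence.apixaban.m6_9"`). The recurrent-event
#' split appears as a single `"event_split"` entry sampled jointly from a
#' Dirichlet distribution.
#'
#' @param ps A `vte_parameter_set`.
#' @param include_values Include cost/utility registry entries.
#' @return Named list of estimates.
#' @export
ps_estimates <- function(ps, include_values = TRUE) {
  out <- list()
  for (arm in names(ps$recurrence))
    for (iv in names(ps$recurrence[[arm]]))
      out[[paste("recurrence", arm, iv, sep = ".")]] <- ps$recurrence[[arm]][[iv]]
  out[["event_split"]] <- structure(
    list(mean = ps$event_split, n_eff = ps$event_split_n, kind = "dirichlet",
         distribution = "dirichlet", label = "event split"),
    class = "vte_estimate")
  for (i in seq_along(ps$post_cessation_knots))
    out[[sprintf("post_cessation_ci.%d", i)]] <- ps$post_cessation_knots[[i]]
  for (arm in names(ps$mb)) out[[paste0("mb.", arm)]] <- ps$mb[[arm]]
  for (arm in names(ps$crnmb)) out[[paste0("crnmb.", arm)]] <- ps$crnmb[[arm]]
  singles <- c("fatal_mb_proportion", "nonfatal_ic_proportion", "bleeding_age_factor",
               "interruption_non_ic_mb", "interruption_crnmb",
               "other_discontinuation", "cteph_annual", "pts_5y")
  for (nm in singles) out[[nm]] <- ps[[nm]]
  for (nm in names(ps$mortality_hr)) out[[paste0("mortality_hr.", nm)]] <- ps$mortality_hr[[nm]]
  if (include_values) {
    for (nm in names(ps$costs)) out[[paste0("costs.", nm)]] <- ps$costs[[nm]]
    u <- ps$utilities
    out[["utilities.baseline"]] <- u$baseline
    for (nm in names(u$event_decrement))
      out[[paste0("utilities.event_decrement.", nm)]] <- u$event_decrement[[nm]]
    for (nm in names(u$state_decrement))
      out[[paste0("utilities.state_decrement.", nm)]] <- u$state_decrement[[nm]]
  }
  out
}

#' Replace a parameter value by its registry path
#'
#' Sets the point value (mean) of one entry of [ps_estimates()]; used by the
#' sampling and univariate-sweep machinery. The `"event_split"` path expects a
#' three-component numeric vector summing to one.
#'
#' @param ps A `vte_parameter_set`.
#' @param path Registry path.
#' @param value New value.
#' @return Modified copy of `ps`.
#' @export
ps_set <- function(ps, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (path == "event_split") {
    if (abs(sum(value) - 1) > 1e-9) stop("event split must sum to 1")
    ps$event_split[] <- value
    return(ps)
  }
  if (parts[1] == "recurrence") {
    ps$recurrence[[parts[2]]][[parts[3]]]$mean <- value
  } else if (parts[1] == "post_cessation_ci") {
    i <- as.integer(parts[2])
    ps$post_cessation_knots[[i]]$mean <- value
    ps$post_cessation_curve <- cumulative_incidence_curve(
      vapply(ps$post_cessation_knots, function(k) k$time_years, 0),
      cummax(vapply(ps$post_cessation_knots, function(k) k$mean, 0)))
  } else if (parts[1] %in% c("mb", "crnmb", "mortality_hr")) {
    ps[[parts[1]]][[parts[2]]]$mean <- value
  } else if (parts[1] == "costs") {
    ps$costs[[paste(parts[-1], collapse = ".")]]$mean <- value
  } else if (parts[1] == "utilities") {
    if (parts[2] == "baseline") ps$utilities$baseline$mean <- value
    else ps$utilities[[parts[2]]][[parts[3]]]$mean <- value
  } else if (!is.null(ps[[parts[1]]]) && length(parts) == 1) {
    ps[[parts[1]]]$mean <- value
  } else stop(sprintf("unknown parameter path '%s'", path))
  ps
}
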