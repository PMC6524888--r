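# Probabilistic (PSA) and univariate (tornado) sensitivity analysis.
# Distributions are fitted by moment matching from (mean, 95% CI); when no CI
# is available a standard error of 30% of the mean is assumed.

#' Fit a sampling distribution to an estimate
#'
#' Beta, gamma and lognormal families are matched on mean and standard error,
#' with SE taken as (ci_high - ci_low)/3.92 (normal approximation) or 0.3 x
#' mean when no CI is stated. Dirichlet entries are scaled to the registry's
#' common effective sample size. `"fixed"` returns a degenerate spec.
#'
#' @param est A `vte_estimate` (probability, hazard ratio, value or the joint
#'   event-split entry).
#' @return Object of class `vte_dist_spec` with elements `family`, `par`,
#'   `mean`.
#' @export
fit_distribution <- function(est) {
  stopifnot(inherits(est, "vte_estimate"))
  fam <- est$distribution
  m <- est$mean
  if (identical(est$kind, "dirichlet") || fam == "dirichlet") {
    alpha <- est$mean * est$n_eff
    return(structure(list(family = "dirichlet", par = list(alpha = alpha),
                          mean = est$mean, label = est$label),
                     class = "vte_dist_spec"))
  }
  se <- if (!is.null(est$ci_low) && !is.na(est$ci_low) && !is.na(est$ci_high))
    (est$ci_high - est$ci_low) / 3.92 else 0.3 * m
  if (fam == "fixed" || se == 0)
    return(structure(list(family = "fixed", par = list(value = m), mean = m,
                          label = est$label), class = "vte_dist_spec"))
  v <- se^2
  par <- switch(fam,
    beta = {
      if (m <= 0 || m >= 1) stop(sprintf("beta fit needs mean in (0, 1) for '%s'", est$label))
      if (v >= m * (1 - m))
        stop(sprintf("implied variance exceeds the beta-feasible bound for '%s'", est$label))
      nu <- m * (1 - m) / v - 1
      list(shape1 = m * nu, shape2 = (1 - m) * nu)
    },
    gamma = list(shape = (m / se)^2, rate = m / v),
    lognormal = {
      sdlog <- sqrt(log(1 + (se / m)^2))
      list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    },
    dirichlet_component = stop("dirichlet components are sampled jointly via the registry"),
    stop(sprintf("unknown distribution family '%s'", fam)))
  spec <- structure(list(family = fam, par = par, mean = m, label = est$label),
                    class = "vte_dist_spec")
  if (abs(dist_mean(spec) - m) > 0.01 * max(abs(m), 1e-12))
    stop(sprintf("fitted mean deviates more than 1%% for '%s'", est$label))
  spec
}

dist_mean <- function(spec) {
  with(spec$par, switch(spec$family,
    fixed = value,
    beta = shape1 / (shape1 + shape2),
    gamma = shape / rate,
    lognormal = exp(meanlog + sdlog^2 / 2),
    dirichlet = alpha / sum(alpha)))
}

#' Sample from a fitted distribution
#'
#' @param spec A `vte_dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector (or matrix for the Dirichlet family).
#' @export
sample_distribution <- function(spec, n = 1) {
  with(spec$par, switch(spec$family,
    fixed = rep(value, n),
    beta = stats::rbeta(n, shape1, shape2),
    gamma = stats::rgamma(n, shape = shape, rate = rate),
    lognormal = stats::rlnorm(n, meanlog, sdlog),
    dirichlet = {
      g <- vapply(alpha, function(a) stats::rgamma(n, shape = a, rate = 1),
                  numeric(n))
      g <- matrix(g, nrow = n)
      sw <- g / rowSums(g)
      colnames(sw) <- names(alpha)
      sw
    }))
}

#' Quantile of a fitted distribution
#'
#' Used for the univariate sweep bounds when a parameter has no stated CI.
#'
#' @param spec A `vte_dist_spec`.
#' @param p Probability.
#' @export
quantile_distribution <- function(spec, p) {
  with(spec$par, switch(spec$family,
    fixed = rep(value, length(p)),
    beta = stats::qbeta(p, shape1, shape2),
    gamma = stats::qgamma(p, shape = shape, rate = rate),
    lognormal = stats::qlnorm(p, meanlog, sdlog),
    dirichlet = stop("no scalar quantile for the joint event split")))
}

#' Draw one sampled parameter set
#'
#' Independent draws for every uncertain parameter (the recurrent-event split
#' is drawn jointly from its Dirichlet); fixed entries are untouched. Draws
#' producing an invalid probability are redrawn and counted in the
#' `"redraws"` attribute. Fully reproducible for a given seed.
#'
#' @param base A `vte_parameter_set`.
#' @param seed Integer seed.
#' @param include_values Also sample cost/utility registry entries.
#' @return A new `vte_parameter_set`.
#' @export
sample_parameter_set <- function(base, seed, include_values = TRUE) {
  set.seed(seed)
  reg <- ps_estimates(base, include_values = include_values)
  ps <- base
  redraws <- 0L
  for (nm in names(reg)) {
    est <- reg[[nm]]
    spec <- fit_distribution(est)
    if (spec$family == "fixed") next
    if (spec$family == "dirichlet") {
      ps <- ps_set(ps, nm, drop(sample_distribution(spec, 1)))
      next
    }
    is_prob <- identical(est$kind, "probability") ||
      (identical(est$kind, "value") && spec$family == "beta")
    repeat {
      x <- sample_distribution(spec, 1)
      ok <- is.finite(x) && x >= 0 && (!is_prob || x <= 1)
      if (ok) break
      redraws <- redraws + 1L
      if (redraws > 1e4) stop(sprintf("persistent invalid draws for '%s'", nm))
    }
    ps <- ps_set(ps, nm, x)
  }
  attr(ps, "redraws") <- redraws
  attr(ps, "seed") <- seed
  ps
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets (both arms share each draw), runs the model for
#' both arms and records the incremental cost and effect pairs. Iteration `i`
#' uses seed `master_seed + i`, so any single iteration is reproducible in
#' isolation.
#'
#' @param params Base `vte_parameter_set`.
#' @param life_table A `vte_life_table`.
#' @param n Number of iterations.
#' @param master_seed Master seed.
#' @param arm_new,arm_ref Arm specifications (defaults: lifetime extended
#'   apixaban vs no treatment, 1,000 patients).
#' @param perspective Cost perspective.
#' @param control Engine options.
#' @return Object of class `vte_psa_result`: data frame `draws` with columns
#'   `iteration`, `seed`, `d_cost`, `d_effect`, plus `n_iterations` and the
#'   deterministic base-case increments.
#' @export
run_psa <- function(params, life_table, n = 2000, master_seed = 1,
                    arm_new = arm_spec("apixaban"),
                    arm_ref = arm_spec("no_treatment"),
                    perspective = "societal", control = engine_control()) {
  if (n < 1) stop("n must be >= 1")
  one <- function(ps) {
    tn <- run_cohort(arm_new, ps, life_table, control)
    tr <- run_cohort(arm_ref, ps, life_table, control)
    c(d_cost = accumulate_costs(tn, ps$costs, perspective,
                                ps$discounting$costs_annual)$total -
        accumulate_costs(tr, ps$costs, perspective, ps$discounting$costs_annual)$total,
      d_effect = accumulate_qalys(tn, ps$utilities, ps$discounting$effects_annual)$qalys -
        accumulate_qalys(tr, ps$utilities, ps$discounting$effects_annual)$qalys)
  }
  base_inc <- one(params)
  draws <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("d_cost", "d_effect")))
  redraws <- 0L
  for (i in seq_len(n)) {
    ps_i <- sample_parameter_set(params, seed = master_seed + i)
    redraws <- redraws + attr(ps_i, "redraws")
    draws[i, ] <- one(ps_i)
  }
  structure(list(
    draws = data.frame(iteration = seq_len(n), seed = master_seed + seq_len(n),
                       d_cost = draws[, "d_cost"], d_effect = draws[, "d_effect"]),
    n_iterations = n, master_seed = master_seed,
    base_d_cost = unname(base_inc["d_cost"]),
    base_d_effect = unname(base_inc["d_effect"]),
    redraws = redraws), class = "vte_psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness at each willingness-to-pay threshold:
#' the fraction of draws with non-negative net monetary benefit.
#'
#' @param result A `vte_psa_result`.
#' @param thresholds Willingness-to-pay thresholds (currency/QALY).
#' @return `data.frame` with columns `wtp` and `probability`.
#' @export
ceac <- function(result, thresholds = seq(0, 100000, by = 2500)) {
  stopifnot(inherits(result, "vte_psa_result"))
  d <- result$draws
  if (nrow(d) == 0) stop("empty PSA result")
  prob <- vapply(thresholds, function(w)
    mean(net_monetary_benefit(d$d_cost, d$d_effect, w) >= 0), 0)
  data.frame(wtp = thresholds, probability = prob)
}

#' Univariate (tornado) sensitivity analysis
#'
#' Re-runs the deterministic model twice per parameter with that parameter at
#' the bounds of its 95% CI (stated CI where available, otherwise the 2.5/97.5
#' percentiles of the fitted distribution), everything else at base values.
#' Entries are sorted by the width of the resulting ICER range.
#'
#' @param params Base `vte_parameter_set`.
#' @param life_table A `vte_life_table`.
#' @param param_names Registry paths to vary (default: every uncertain entry).
#' @param arm_new,arm_ref Arm specifications.
#' @param perspective Cost perspective.
#' @param control Engine options.
#' @return `data.frame` of class `vte_tornado`: parameter, bounds, ICER at
#'   each bound, base ICER, range.
#' @export
univariate_sweep <- function(params, life_table, param_names = NULL,
                             arm_new = arm_spec("apixaban"),
                             arm_ref = arm_spec("no_treatment"),
                             perspective = "societal",
                             control = engine_control()) {
  reg <- ps_estimates(params)
  if (is.null(param_names)) {
    param_names <- names(reg)[vapply(names(reg), function(nm) {
      s <- fit_distribution(reg[[nm]])
      !s$family %in% c("fixed", "dirichlet")
    }, TRUE)]
  } else {
    missing <- setdiff(param_names, names(reg))
    if (length(missing))
      stop(sprintf("unknown parameter(s): %s", paste(missing, collapse = ", ")))
  }
  run_icer <- function(ps) {
    tn <- run_cohort(arm_new, ps, life_table, control)
    tr <- run_cohort(arm_ref, ps, life_table, control)
    icer(accumulate_costs(tn, ps$costs, perspective, ps$discounting$costs_annual)$total,
         accumulate_costs(tr, ps$costs, perspective, ps$discounting$costs_annual)$total,
         accumulate_qalys(tn, ps$utilities, ps$discounting$effects_annual)$qalys,
         accumulate_qalys(tr, ps$utilities, ps$discounting$effects_annual)$qalys)$icer
  }
  base_icer <- run_icer(params)
  rows <- lapply(param_names, function(nm) {
    est <- reg[[nm]]
    spec <- fit_distribution(est)
    if (spec$family == "fixed") {
      lo <- hi <- est$mean
    } else if (!is.null(est$ci_low) && !is.na(est$ci_low) && !is.na(est$ci_high) &&
               est$ci_high > est$ci_low) {
      lo <- est$ci_low; hi <- est$ci_high
    } else {
      lo <- quantile_distribution(spec, 0.025)
      hi <- quantile_distribution(spec, 0.975)
    }
    data.frame(parameter = nm, lower = lo, upper = hi,
               icer_lower = run_icer(ps_set(params, nm, lo)),
               icer_upper = run_icer(ps_set(params, nm, hi)),
               base_icer = base_icer)
  })
  out <- do.call(rbind, rows)
  out$range <- abs(out$icer_upper - out$icer_lower)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  class(out) <- c("vte_tornado", "data.frame")
  out
}
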