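# Probability/rate conversion calculus. All adjustments (period rescaling,
# hazard ratios, age factors) act on the rate (complement-log) scale so
# results stay in [0, 1].

#' Convert a probability between period bases
#'
#' Rescales a risk stated over `basis_months` to the model cycle length under
#' a constant-hazard assumption: `1 - (1 - p)^(cycle_months / basis_months)`.
#'
#' @param p Probability in `[0, 1)` (a value of exactly 1 is only accepted
#'   when no rescaling is needed, since it implies an infinite rate).
#' @param basis_months Period, in months, that `p` refers to.
#' @param cycle_months Target period in months (default 3, the model cycle).
#' @return Probability on the `cycle_months` basis.
#' @examples
#' to_cycle_probability(0.03, 12, 3)   # annual 3% risk per 3-month cycle
#' @export
to_cycle_probability <- function(p, basis_months, cycle_months = 3) {
  if (!is.numeric(p) || !is.numeric(basis_months) || !is.numeric(cycle_months))
    stop("inputs must be numeric")
  if (any(basis_months <= 0) || any(cycle_months <= 0))
    stop("period bases must be positive")
  if (any(p < 0)) stop("probability must be non-negative")
  if (any(p > 1)) stop("probability cannot exceed 1")
  if (any(p == 1 & basis_months != cycle_months))
    stop("cannot rescale a probability of 1 (infinite rate)")
  n <- max(length(p), length(basis_months), length(cycle_months))
  p <- rep_len(p, n); bm <- rep_len(basis_months, n); cm <- rep_len(cycle_months, n)
  out <- 1 - (1 - p)^(cm / bm)
  out[bm == cm] <- p[bm == cm]           # identity basis: return p exactly
  out
}

#' Apply a hazard ratio to a per-period probability
#'
#' Multiplies the underlying rate, i.e. returns `1 - (1 - p)^hr`.
#'
#' @param p Baseline probability in `[0, 1]`.
#' @param hr Hazard ratio, strictly positive.
#' @return Adjusted probability on the same period basis as `p`.
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(hr <= 0)) stop("hazard ratio must be strictly positive")
  if (any(p < 0) || any(p > 1)) stop("probability must lie in [0, 1]")
  1 - (1 - p)^hr
}

#' Age-adjust a bleeding probability
#'
#' Scales a bleeding risk for aging with a per-decade rate multiplier:
#' `1 - (1 - p_base)^(factor_per_decade^((age - base_age) / 10))`.
#' Per-cycle probabilities driven above 0.999 are clamped with a warning.
#'
#' @param p_base Bleeding probability at `base_age`, in `[0, 1)`.
#' @param age Current age in years; must be `>= base_age`.
#' @param base_age Age the baseline risk refers to (cohort start age).
#' @param factor_per_decade Rate multiplier per decade of aging.
#' @return Adjusted probability.
#' @export
age_adjust_bleeding <- function(p_base, age, base_age, factor_per_decade) {
  if (any(age < base_age)) stop("age must not be below base_age")
  if (any(p_base < 0) || any(p_base >= 1)) stop("p_base must lie in [0, 1)")
  if (any(factor_per_decade <= 0)) stop("factor_per_decade must be positive")
  e <- factor_per_decade^((age - base_age) / 10)
  out <- 1 - (1 - p_base)^e
  out[e == 1] <- rep_len(p_base, length(out))[e == 1]   # zero decades: exact

  if (any(out > 0.999)) {
    warning("age-adjusted bleeding probability exceeded 0.999; clamped")
    out <- pmin(out, 0.999)
  }
  out
}

#' Cumulative incidence curve
#'
#' A piecewise cumulative-incidence curve anchored at (0, 0), used for the
#' post-cessation recurrence risk.
#'
#' @param times Knot times in years, strictly increasing, all positive.
#' @param ci Cumulative probabilities at the knots, non-decreasing in `[0, 1]`.
#' @return An object of class `vte_ci_curve`.
#' @export
cumulative_incidence_curve <- function(times, ci) {
  if (length(times) != length(ci) || length(times) < 1)
    stop("times and ci must be non-empty and of equal length")
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("knot times must be positive and strictly increasing")
  if (any(ci < 0) || any(ci > 1)) stop("cumulative probabilities must lie in [0, 1]")
  if (any(diff(c(0, ci)) < 0)) stop("cumulative incidence must be non-decreasing")
  structure(list(times = c(0, times), ci = c(0, ci)), class = "vte_ci_curve")
}

#' Per-cycle probability from a piecewise-constant hazard
#'
#' Converts a cumulative incidence curve into the conditional per-cycle event
#' probability at time `t_start`, assuming a constant hazard within each knot
#' segment. For `t_start` in segment `(t1, t2]` the per-cycle probability is
#' `1 - ((1 - CI(t2)) / (1 - CI(t1)))^((cycle_months / 12) / (t2 - t1))`.
#' Beyond the last knot the final segment's hazard persists.
#'
#' @param curve A [cumulative_incidence_curve()].
#' @param t_start Time in years at the start of the cycle (>= 0).
#' @param cycle_months Cycle length in months.
#' @return Conditional per-cycle probability.
#' @export
piecewise_recurrence_probability <- function(curve, t_start, cycle_months = 3) {
  stopifnot(inherits(curve, "vte_ci_curve"))
  if (t_start < 0) stop("t_start must be non-negative")
  k <- length(curve$times)
  # segment whose span covers the cycle starting at t_start (cycle-start
  # convention: a knot time belongs to the segment it opens); the last
  # segment's hazard persists beyond the final knot
  i <- findInterval(t_start, curve$times)
  i <- min(max(i, 1), k - 1)
  t1 <- curve$times[i]; t2 <- curve$times[i + 1]
  s1 <- 1 - curve$ci[i]; s2 <- 1 - curve$ci[i + 1]
  if (s2 > s1 + 1e-12) stop("cumulative incidence decreases over the segment")
  if (s2 <= 0) return(1)
  hazard <- -log(s2 / s1) / (t2 - t1)          # per year
  1 - exp(-hazard * cycle_months / 12)
}

#' Relative treatment effect on the hazard scale
#'
#' Summarises two arms' interval risks as a single hazard-scale relative
#' effect: `log(1 - cumulative treated risk) / log(1 - cumulative untreated
#' risk)`. Used to scale the post-cessation recurrence hazard for patients who
#' remain anticoagulated beyond the trial window.
#'
#' @param treated Vector of per-interval risks for the treated arm.
#' @param untreated Vector of per-interval risks for the untreated arm.
#' @return Hazard ratio (dimensionless); 0 when the treated arm has no risk.
#' @export
treatment_effect_rr <- function(treated, untreated) {
  if (length(treated) != length(untreated) || length(treated) < 1)
    stop("both arms must supply the same number of interval risks")
  if (any(treated < 0) || any(treated >= 1) || any(untreated < 0) || any(untreated >= 1))
    stop("interval risks must lie in [0, 1)")
  cum_t <- 1 - prod(1 - treated)
  cum_u <- 1 - prod(1 - untreated)
  if (cum_u == 0) stop("untreated arm has zero cumulative risk")
  if (cum_t == 0) return(0)
  log(1 - cum_t) / log(1 - cum_u)
}

# internal: probability <-> rate over one period
prob_to_rate <- function(p) -log(1 - p)
rate_to_prob <- function(r) 1 - exp(-r)
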