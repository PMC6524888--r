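# Synthetic period life table (Gompertz-Makeham) and background mortality.
# Stands in for a national life table; tests and the packaged analyses use it
# so the model runs without external data.

#' Build a life table from Gompertz-Makeham parameters
#'
#' Annual death probability `q(age) = 1 - exp(-(makeham + scale * exp(shape *
#' age)))` per sex, tabulated from age 0 to `max_age` with the terminal row
#' forced to 1.
#'
#' @param male,female Named lists with elements `makeham`, `scale`, `shape`
#'   (all positive; `makeham` is the age-independent background rate).
#' @param max_age Final tabulated age (death is certain there).
#' @return A `data.frame` of class `vte_life_table` with columns `age`,
#'   `qx_male`, `qx_female`.
#' @export
make_life_table <- function(male, female, max_age = 100) {
  gm <- function(p) {
    if (any(unlist(p) < 0) || p$scale <= 0 || p$shape <= 0)
      stop("Gompertz-Makeham parameters must be positive")
    age <- 0:max_age
    q <- pmin(1 - exp(-(p$makeham + p$scale * exp(p$shape * age))), 1)
    q[length(q)] <- 1
    q
  }
  structure(data.frame(age = 0:max_age, qx_male = gm(male), qx_female = gm(female)),
            class = c("vte_life_table", "data.frame"))
}

#' Packaged synthetic life table
#'
#' Default Gompertz-Makeham fixture calibrated so that the annual death
#' probability at the cohort start age (56.9 years) is of order 0.5% and the
#' remaining general-population life expectancy there is 25-30 years, the
#' range typical of a high-income country's period table.
#'
#' @return A `vte_life_table`.
#' @export
default_life_table <- function() {
  make_life_table(
    male   = list(makeham = 2.0e-4, scale = 3.0e-5, shape = 0.095),
    female = list(makeham = 1.5e-4, scale = 1.35e-5, shape = 0.099))
}

#' Read / write a life table CSV
#'
#' Plain CSV with columns `age`, `qx_male`, `qx_female`.
#'
#' @param path File path.
#' @return `read_life_table` returns a `vte_life_table`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("age", "qx_male", "qx_female")
  if (!all(need %in% names(df)))
    stop(sprintf("life table %s must have columns %s", path, paste(need, collapse = ", ")))
  if (any(df$qx_male < 0 | df$qx_male > 1 | df$qx_female < 0 | df$qx_female > 1))
    stop("life-table death probabilities must lie in [0, 1]")
  if (df$qx_male[nrow(df)] != 1 || df$qx_female[nrow(df)] != 1)
    stop("terminal life-table row must have q = 1")
  structure(df[need], class = c("vte_life_table", "data.frame"))
}

#' @rdname read_life_table
#' @param lt A `vte_life_table`.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

# internal: sex-mixed annual q at (possibly fractional) age
annual_q <- function(lt, age, male_fraction) {
  a <- pmin(floor(age), max(lt$age))
  i <- match(a, lt$age)
  if (anyNA(i)) stop("age outside life-table span")
  male_fraction * lt$qx_male[i] + (1 - male_fraction) * lt$qx_female[i]
}

#' Per-cycle background mortality
#'
#' Mixes the male and female annual death probabilities by the cohort sex mix,
#' rescales to the cycle length and applies a mortality hazard ratio on the
#' rate scale: `1 - (1 - q)^(hr * cycle_months / 12)`. Ages at or beyond the
#' end of the table return 1.
#'
#' @param age Age in years at the cycle start.
#' @param male_fraction Fraction of the cohort that is male.
#' @param life_table A `vte_life_table`.
#' @param hr Mortality hazard ratio (default 1).
#' @param cycle_months Cycle length in months.
#' @return Per-cycle death probability.
#' @export
background_mortality <- function(age, male_fraction, life_table, hr = 1,
                                 cycle_months = 3) {
  if (any(age < 0)) stop("age must be non-negative")
  if (any(hr <= 0)) stop("hazard ratio must be positive")
  out <- numeric(length(age))
  terminal <- age >= max(life_table$age)
  out[terminal] <- 1
  if (any(!terminal)) {
    q <- annual_q(life_table, age[!terminal], male_fraction)
    out[!terminal] <- 1 - (1 - q)^(hr * cycle_months / 12)
  }
  out
}

#' Life expectancy from a life table
#'
#' Remaining life expectancy at `age`, computed either by summing the
#' survival curve on a monthly grid (`"survival_sum"`) or from the exact
#' closed-form integral of the piecewise-exponential survival
#' (`"integration"`). The two agree to well under 0.01 years and serve as
#' mutual checks.
#'
#' @param lt A `vte_life_table`.
#' @param age Starting age (integer years).
#' @param male_fraction Sex mix.
#' @param method `"survival_sum"` or `"integration"`.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age, male_fraction = 0.5,
                            method = c("survival_sum", "integration")) {
  method <- match.arg(method)
  ages <- age:max(lt$age)
  q <- annual_q(lt, ages, male_fraction)
  haz <- -log(pmax(1 - q, 1e-12))          # annual hazards, piecewise constant
  if (method == "survival_sum") {
    m <- 1 / 12
    hmon <- rep(haz * m, each = 12)
    s <- c(1, exp(-cumsum(hmon)))
    sum((s[-length(s)] + s[-1]) / 2 * m)
  } else {
    # exact: integral of S over year k is S(k) * (1 - exp(-h_k)) / h_k
    s <- c(1, exp(-cumsum(haz)))[seq_along(haz)]
    sum(s * (1 - exp(-haz)) / haz)
  }
}
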