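# Table and figure-series generation, with the display conventions used
# throughout: probabilities as whole percents, times and life expectancies
# to one decimal, harm/benefit ratios to two significant figures.

#' Round half away from zero
#'
#' Display rounding for the outcome tables (R's `round()` rounds half to
#' even, which would turn 26.5 into 26).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Outcome table over a mortality-rate grid
#'
#' One row per (mortality rate, waiting time) cell with the no-benefit /
#' harm / benefit percentages and the harm-to-benefit ratio, in the layout
#' of the published tables.
#'
#' @param mr Mortality-rate grid (deaths per 100 patient-years); default 15
#'   to 35 in steps of 5.
#' @param wait_years Waiting times in years (one or more).
#' @param hold_fraction,hold_rr Hold-status composition (see
#'   [adjust_profile()]).
#' @param preset Profile preset name (see [rr_profile_preset()]).
#' @param profile Optional explicit [rr_profile()] overriding `preset`.
#' @param raw If `TRUE`, return unrounded probabilities (0-1 scale) instead
#'   of display-rounded percentages.
#' @return A data frame with columns `mortality_rate`, `life_expectancy`,
#'   `wait_years`, `no_benefit_pct`, `harm_pct`, `benefit_pct`,
#'   `harm_benefit_ratio`.
#' @examples
#' outcome_table(wait_years = 2, preset = "extended")
#' @export
outcome_table <- function(mr = seq(15, 35, by = 5), wait_years = 2,
                          hold_fraction = 0, hold_rr = 2.2,
                          preset = "extended", profile = NULL,
                          raw = FALSE) {
  if (length(mr) < 1L || any(mr <= 0)) stop("`mr` grid must be positive")
  if (length(wait_years) < 1L || any(wait_years < 0))
    stop("`wait_years` must be non-negative")
  cells <- expand.grid(mr = mr, w = wait_years, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- decompose_outcomes(scenario(
      cells$mr[i], wait_years = cells$w[i],
      hold_fraction = hold_fraction, hold_rr = hold_rr,
      preset = preset, profile = profile))
    data.frame(mortality_rate = cells$mr[i],
               life_expectancy = life_expectancy(cells$mr[i]),
               wait_years = cells$w[i],
               no_benefit = d$p_no_benefit,
               harm = d$p_harm,
               benefit = d$p_benefit,
               harm_benefit_ratio = d$harm_benefit_ratio)
  })
  out <- do.call(rbind, rows)
  if (raw) {
    names(out)[4:6] <- c("p_no_benefit", "p_harm", "p_benefit")
    return(out)
  }
  data.frame(
    mortality_rate = out$mortality_rate,
    life_expectancy = round_half_up(out$life_expectancy, 1),
    wait_years = out$wait_years,
    no_benefit_pct = round_half_up(100 * out$no_benefit),
    harm_pct = round_half_up(100 * out$harm),
    benefit_pct = round_half_up(100 * out$benefit),
    harm_benefit_ratio = signif(out$harm_benefit_ratio, 2))
}

#' Survival curve series for both arms
#'
#' Exact closed-form evaluations of the wait-list and transplant survival
#' curves on a time grid, with the two characteristic times attached as
#' attributes (`t_equal_survival`, `t_equal_life_years`).
#'
#' @param profile An [rr_profile()].
#' @param m Annual baseline hazard.
#' @param t_grid Increasing, non-negative time grid (years).
#' @return A data frame `t`, `s_waitlist`, `s_transplant`.
#' @export
survival_curve_series <- function(profile, m,
                                  t_grid = seq(0, 10, by = 0.05)) {
  if (is.unsorted(t_grid) || any(t_grid < 0))
    stop("`t_grid` must be increasing and non-negative")
  out <- data.frame(t = t_grid,
                    s_waitlist = waitlist_survival(m, t_grid),
                    s_transplant = transplant_survival(profile, m, t_grid))
  attr(out, "t_equal_survival") <- time_to_equal_survival(profile)
  attr(out, "t_equal_life_years") <-
    tryCatch(time_to_equal_life_years(profile, m),
             txbenefit_no_catchup = function(e) NA_real_)
  out
}

#' Serialise a result to JSON
#'
#' JSON record with field names matching the result object's fields;
#' numbers are written unrounded.
#'
#' @param x An `"outcome_decomposition"`, `"calibration_result"` or
#'   `"sim_result"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  rec <- if (inherits(x, "outcome_decomposition")) as.list(x)
  else if (inherits(x, "calibration_result"))
    list(m = x$m, r1 = x$r1, r2 = x$r2, r3 = x$r3, d1 = x$d1, d2 = x$d2,
         implied = x$implied, residuals = as.list(x$residuals))
  else if (inherits(x, "sim_result"))
    list(n = x$n, seed = x$seed, counts = as.list(x$counts),
         p_hat = as.list(x$p_hat), se = as.list(x$se),
         analytic = as.list(x$analytic),
         t_equal_life_years = x$t_equal_life_years,
         mean_rly_tx = x$mean_rly_tx, mean_rly_wait = x$mean_rly_wait,
         rly_diff = x$rly_diff, rly_diff_se = x$rly_diff_se)
  else stop("unsupported object")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
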