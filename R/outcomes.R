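# The central computation: the time at which the transplant arm has lived as
# many cumulative life years as the wait-list arm (restricted-AUC equality),
# and the resulting no-benefit / harm / benefit decomposition of a
# candidate's prognosis.

#' Analysis scenario
#'
#' Bundles one analysis cell: baseline mortality, deterministic waiting time,
#' hold-status composition of the wait list, and the relative-risk preset.
#' Hold adjustment is applied to the profile downstream (in
#' [decompose_outcomes()] and friends), so the stored profile is the
#' whole-list-referenced one.
#'
#' @param mr_per_100py Baseline mortality rate (deaths per 100 patient-years)
#'   or a [mortality_rate()] object.
#' @param wait_years Years spent on the wait list before transplant, `>= 0`.
#'   All patients are assumed to wait exactly this long.
#' @param hold_fraction Proportion of the wait list on hold/inactive status,
#'   in `[0, 1)`.
#' @param hold_rr Mortality hazard ratio of hold vs active patients, `>= 1`.
#' @param preset Name of a built-in profile preset (see
#'   [rr_profile_preset()]); ignored when `profile` is supplied.
#' @param profile Optional [rr_profile()] overriding the preset.
#' @return An object of class `"tx_scenario"`.
#' @examples
#' scenario(15, wait_years = 2)
#' scenario(30, hold_fraction = 0.2, preset = "extended")
#' @export
scenario <- function(mr_per_100py, wait_years = 2, hold_fraction = 0,
                     hold_rr = 2.2, preset = "extended", profile = NULL) {
  mort <- if (inherits(mr_per_100py, "mortality_rate")) mr_per_100py
          else mortality_rate(mr_per_100py)
  if (!is.numeric(wait_years) || length(wait_years) != 1L ||
      is.na(wait_years) || wait_years < 0)
    stop("`wait_years` must be a single non-negative number")
  if (hold_fraction < 0 || hold_fraction >= 1)
    stop("`hold_fraction` must lie in [0, 1)")
  if (hold_rr < 1) stop("`hold_rr` must be >= 1")
  if (is.null(profile)) {
    preset <- match.arg(preset, c("published", "extended"))
    profile <- rr_profile_preset(preset)
  } else {
    stopifnot(inherits(profile, "rr_profile"))
    preset <- "custom"
  }
  structure(
    list(mortality = mort, wait_years = wait_years,
         hold_fraction = hold_fraction, hold_rr = hold_rr,
         profile = profile, preset_name = preset),
    class = "tx_scenario")
}

#' @export
print.tx_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: MR %g/100 py, wait %g y, hold %g%% at rr %g, preset '%s'\n",
    x$mortality$mr_per_100py, x$wait_years, 100 * x$hold_fraction,
    x$hold_rr, x$preset_name))
  invisible(x)
}

# Effective (active-comparator) profile for a scenario.
effective_profile <- function(sc) {
  adjust_profile(sc$profile, sc$hold_fraction, sc$hold_rr)
}

#' Time to equal cumulative life years
#'
#' The break-even time `t*` after transplant at which the areas under the
#' transplant and wait-list survival curves are equal. Before `t*` the
#' average transplanted patient has lived fewer life years than the average
#' wait-listed patient; after `t*`, more. Found by bracketing upward from
#' [time_to_equal_survival()] (doubling the upper bound until the restricted
#' AUC difference changes sign, capped at `200/m`) followed by bisection to
#' `|AUC difference| <= 1e-10`.
#'
#' Returns 0 when the curves never diverge unfavourably (all `rr = 1`, or no
#' excess hazard ever accumulates). Signals `"txbenefit_no_catchup"` when
#' the final-period relative risk is `>= 1` or the transplant arm's life
#' years never reach the wait-list arm's within the bracket cap.
#'
#' @param profile An [rr_profile()] (already hold-adjusted if applicable).
#' @param m Annual baseline hazard, `> 0`.
#' @return Years since transplant (scalar).
#' @examples
#' time_to_equal_life_years(rr_profile_preset("published"), 0.15)  # ~2.55
#' @export
time_to_equal_life_years <- function(profile, m) {
  stopifnot(inherits(profile, "rr_profile"))
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    stop("`m` must be a single positive annual hazard")
  n <- length(profile$rr)
  if (all(abs(profile$rr - 1) < 1e-13)) return(0)
  if (profile$rr[n] >= 1) {
    # a persistent excess can never be repaid in life years
    ts <- tryCatch(time_to_equal_survival(profile),
                   txbenefit_no_crossing = function(e) NA_real_)
    if (is.na(ts) || ts > 0) stop_no_catchup()
    return(0)
  }
  ts <- time_to_equal_survival(profile)
  auc_diff <- function(t)
    restricted_auc("waitlist", m, t) -
      restricted_auc("transplant", m, t, profile)
  if (ts == 0) return(0)               # never behind on survival => never behind on AUC
  f_lo <- auc_diff(ts)
  if (f_lo <= 0) return(ts)            # degenerate: already equal at the crossing
  lo <- ts
  hi <- 2 * ts
  cap <- 200 / m
  while (auc_diff(hi) > 0) {
    lo <- hi
    hi <- 2 * hi
    if (hi > cap) stop_no_catchup()
  }
  # bisection on the exact AUC difference
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- auc_diff(mid)
    if (abs(fm) <= 1e-13 || (hi - lo) < 1e-13) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2                        # nocov
}

#' Decompose a candidate's prognosis into no benefit, harm and benefit
#'
#' With deterministic waiting time `w` and baseline hazard `m`:
#' \deqn{P(\mathrm{no\ benefit}) = 1 - e^{-mw}} (death on the list before
#' transplant); among survivors to transplant, those dying before the time of
#' equal cumulative life years `t*` are harmed and the rest benefit:
#' \deqn{P(\mathrm{harm}) = e^{-mw}\,(1 - S_{tx}(t^*)), \quad
#'       P(\mathrm{benefit}) = e^{-mw}\,S_{tx}(t^*).}
#' The scenario's profile is hold-adjusted (via [adjust_profile()]) before
#' any computation.
#'
#' @param sc A [scenario()].
#' @return An object of class `"outcome_decomposition"`: a list with
#'   `p_no_benefit`, `p_harm`, `p_benefit`, `t_equal_survival`,
#'   `t_equal_life_years` (both years since transplant),
#'   `harm_benefit_ratio`, plus the scenario inputs.
#' @examples
#' decompose_outcomes(scenario(15, wait_years = 2, preset = "published"))
#' @export
decompose_outcomes <- function(sc) {
  stopifnot(inherits(sc, "tx_scenario"))
  prof <- effective_profile(sc)
  m <- sc$mortality$m
  w <- sc$wait_years
  t_star <- time_to_equal_life_years(prof, m)
  t_surv <- time_to_equal_survival(prof)
  s_star <- transplant_survival(prof, m, t_star)
  p_listed <- exp(-m * w)
  structure(
    list(p_no_benefit = 1 - p_listed,
         p_harm = p_listed * (1 - s_star),
         p_benefit = p_listed * s_star,
         t_equal_survival = t_surv,
         t_equal_life_years = t_star,
         benefit_share = s_star,
         harm_benefit_ratio = if (s_star > 0) (1 - s_star) / s_star
                              else NA_real_,
         scenario = sc),
    class = "outcome_decomposition")
}

#' @export
print.outcome_decomposition <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  no benefit %5.1f%%   harm %5.1f%%   benefit %5.1f%%\n",
              100 * x$p_no_benefit, 100 * x$p_harm, 100 * x$p_benefit))
  cat(sprintf("  equal survival at %.2f y, equal life years at %.2f y, harm/benefit %.2f\n",
              x$t_equal_survival, x$t_equal_life_years,
              x$harm_benefit_ratio))
  invisible(x)
}

#' @export
as.list.outcome_decomposition <- function(x, ...) {
  x[c("p_no_benefit", "p_harm", "p_benefit", "t_equal_survival",
      "t_equal_life_years", "harm_benefit_ratio")]
}

#' Harm-to-benefit ratio
#'
#' `(1 - S_tx(t*)) / S_tx(t*)`: the odds that a transplanted patient dies
#' before the time of equal cumulative life years. The waiting time cancels
#' (both harm and benefit scale by `exp(-m w)`), so the ratio is a property
#' of the mortality rate and profile alone.
#'
#' @param sc A [scenario()].
#' @return Dimensionless ratio; signals an error when benefit is zero.
#' @export
harm_benefit_ratio <- function(sc) {
  d <- decompose_outcomes(sc)
  if (d$benefit_share <= 0)
    stop_txbenefit("txbenefit_undefined_ratio",
                   "benefit probability is zero: ratio undefined")
  d$harm_benefit_ratio
}

#' Equivalence mortality rate
#'
#' The baseline mortality rate at which transplantation is as likely to harm
#' as to benefit, i.e. the transplant survival at the time of equal
#' cumulative life years equals 1/2. The waiting time does not enter (it
#' scales harm and benefit equally).
#'
#' Two modes:
#' \describe{
#'   \item{`"integer_grid"`}{scans integer mortality rates and returns the
#'     largest with `P(benefit) >= P(harm)`; the benefit share is first
#'     verified to be monotone decreasing over the grid.}
#'   \item{`"continuous"`}{solves `S_tx(t*(m); m) = 1/2` by root-finding over
#'     the bracket.}
#' }
#'
#' @param profile An [rr_profile()] (hold-adjusted if applicable).
#' @param mode `"integer_grid"` or `"continuous"`.
#' @param grid Integer mortality rates (deaths per 100 patient-years) to
#'   scan in `"integer_grid"` mode.
#' @param bracket Length-2 mortality-rate bracket for `"continuous"` mode.
#' @return Mortality rate in deaths per 100 patient-years.
#' @examples
#' prof <- adjust_profile(rr_profile_preset("extended"), 0.2, 2.2)
#' equivalence_mr(prof)  # 22
#' @export
equivalence_mr <- function(profile, mode = c("integer_grid", "continuous"),
                           grid = 15:35, bracket = c(5, 60)) {
  stopifnot(inherits(profile, "rr_profile"))
  mode <- match.arg(mode)
  if (all(abs(profile$rr - 1) < 1e-13))
    stop_no_equivalence(
      "curves coincide: benefit share is 1 at every mortality rate")
  share <- function(mr) {
    m <- mr / 100
    transplant_survival(profile, m, time_to_equal_life_years(profile, m))
  }
  if (mode == "integer_grid") {
    grid <- sort(as.integer(grid))
    s <- vapply(grid, share, numeric(1))
    if (any(diff(s) >= 0))
      stop_txbenefit("txbenefit_nonmonotone",
        "benefit share is not monotone decreasing over the grid")
    ok <- s >= 0.5
    if (!any(ok))
      stop_no_equivalence("benefit never reaches harm on the grid")
    res <- max(grid[ok])
    if (res == max(grid))
      warning("equivalence rate is at or above the top of the grid")
    return(res)
  }
  f <- function(mr) share(mr) - 0.5
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo * fhi > 0)
    stop_no_equivalence("no sign change of benefit - harm in the bracket")
  stats::uniroot(f, bracket, f.lower = flo, f.upper = fhi,
                 tol = 1e-10)$root
}
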