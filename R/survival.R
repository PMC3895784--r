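# Closed-form survival mathematics. Wait-list survival is exponential at a
# fixed annual hazard m = MR/100 (MR in deaths per 100 patient-years);
# transplant survival uses the same baseline hazard scaled by the
# piecewise-constant relative-risk profile. All areas under curves are exact
# segment algebra, never quadrature.

#' Baseline mortality rate
#'
#' Carries a candidate's mortality rate in the reporting unit (deaths per 100
#' patient-years) together with the annual hazard `m = mr / 100` used
#' internally. Under exponential survival the life expectancy is `1/m =
#' 100/mr` years.
#'
#' @param mr_per_100py Mortality rate in deaths per 100 patient-years, `> 0`.
#' @return An object of class `"mortality_rate"` with fields `mr_per_100py`
#'   and `m`.
#' @export
mortality_rate <- function(mr_per_100py) {
  if (!is.numeric(mr_per_100py) || length(mr_per_100py) != 1L ||
      is.na(mr_per_100py) || mr_per_100py <= 0)
    stop("`mr_per_100py` must be a single positive number")
  structure(list(mr_per_100py = mr_per_100py, m = mr_per_100py / 100),
            class = "mortality_rate")
}

#' @export
print.mortality_rate <- function(x, ...) {
  cat(sprintf("Mortality rate: %g deaths per 100 patient-years (hazard %g/y, life expectancy %.1f y)\n",
              x$mr_per_100py, x$m, 1 / x$m))
  invisible(x)
}

#' Wait-list survival probability
#'
#' `S(t) = exp(-m t)` for a cohort remaining on the wait list at constant
#' annual hazard `m`.
#'
#' @param m Annual hazard (per year), `> 0`.
#' @param t Time in years, `>= 0` (vectorised).
#' @return Survival probabilities in `(0, 1]`.
#' @examples
#' waitlist_survival(-log(0.51) / 4, 4)  # 0.51
#' @export
waitlist_survival <- function(m, t) {
  check_hazard_time(m, t)
  exp(-m * t)
}

check_hazard_time <- function(m, t) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    stop("`m` must be a single positive annual hazard")
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("`t` must be non-negative (years)")
  invisible(TRUE)
}

#' Transplant cumulative hazard
#'
#' `H(t) = m * sum_k rr_k * (time spent in segment k before t)`: continuous,
#' piecewise linear and nondecreasing in `t`.
#'
#' @inheritParams waitlist_survival
#' @param profile An [rr_profile()].
#' @return Cumulative hazards (dimensionless), vectorised over `t`.
#' @export
transplant_cumulative_hazard <- function(profile, m, t) {
  stopifnot(inherits(profile, "rr_profile"))
  check_hazard_time(m, t)
  m * relative_cumhaz(profile, t)
}

# H(t)/m: cumulative relative-risk exposure, shared by survival evaluation,
# crossing-time search and hazard inversion.
relative_cumhaz <- function(profile, t) {
  out <- numeric(length(t))
  for (k in seq_along(profile$rr)) {
    dt <- pmin(t - profile$start[k], profile$duration[k])
    out <- out + profile$rr[k] * pmax(dt, 0)
  }
  out
}

#' Transplant survival probability
#'
#' `exp(-H(t))` with `H` from [transplant_cumulative_hazard()].
#'
#' @inheritParams transplant_cumulative_hazard
#' @return Survival probabilities in `(0, 1]`, vectorised over `t`.
#' @examples
#' transplant_survival(rr_profile_preset("published"), -log(0.51) / 4, 4)
#' @export
transplant_survival <- function(profile, m, t) {
  exp(-transplant_cumulative_hazard(profile, m, t))
}

#' Restricted area under a survival curve
#'
#' Expected life years lived on `[0, t]` (restricted mean survival time),
#' computed exactly. For the wait list this is `(1 - exp(-m t)) / m`; for the
#' transplant arm it is summed segment by segment as
#' `S(start_k) (1 - exp(-lambda_k dt_k)) / lambda_k` with
#' `lambda_k = rr_k m`. `t = Inf` is allowed whenever the terminal hazard is
#' positive and yields the unrestricted life expectancy.
#'
#' @param arm `"waitlist"` or `"transplant"`.
#' @inheritParams waitlist_survival
#' @param profile An [rr_profile()]; required for the transplant arm.
#' @return Years of life (scalar; `t` must be a single time).
#' @examples
#' restricted_auc("waitlist", m = 0.2, t = Inf)  # life expectancy, 5 years
#' @export
restricted_auc <- function(arm = c("waitlist", "transplant"), m, t,
                           profile = NULL) {
  arm <- match.arg(arm)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("`t` must be a single non-negative time (years), possibly Inf")
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    stop("`m` must be a single positive annual hazard")
  if (arm == "waitlist") {
    if (is.infinite(t)) return(1 / m)
    return((1 - exp(-m * t)) / m)
  }
  stopifnot(inherits(profile, "rr_profile"))
  n <- length(profile$rr)
  if (is.infinite(t) && profile$rr[n] * m <= 0)
    stop_txbenefit("txbenefit_divergent",
                   "unrestricted AUC diverges: terminal hazard is zero")
  total <- 0
  for (k in seq_len(n)) {
    dt <- min(t - profile$start[k], profile$duration[k])
    if (dt <= 0) break
    lam <- profile$rr[k] * m
    s0 <- exp(-m * relative_cumhaz(profile, profile$start[k]))
    total <- total + s0 * (1 - exp(-lam * dt)) / lam
  }
  total
}

#' Life expectancy from a mortality rate
#'
#' Under exponential survival, the area under the survival curve is `1/m`,
#' i.e. `100 / MR` years for `MR` in deaths per 100 patient-years.
#'
#' @param mr_per_100py Mortality rate in deaths per 100 patient-years.
#' @return Life expectancy in years.
#' @examples
#' life_expectancy(15)  # 6.67 years
#' @export
life_expectancy <- function(mr_per_100py) {
  if (!is.numeric(mr_per_100py) || anyNA(mr_per_100py) ||
      any(mr_per_100py <= 0))
    stop("`mr_per_100py` must be positive")
  100 / mr_per_100py
}

#' Time to equal percent survival
#'
#' The first time `t > 0` at which the transplant and wait-list survival
#' curves intersect, i.e. the transplant cumulative hazard equals `m t`.
#' Because both cumulative hazards are proportional to `m`, the crossing time
#' depends only on the relative-risk profile, never on the baseline rate —
#' hence no `m` argument.
#'
#' Conventions: if the curves coincide everywhere (all `rr = 1`) or the
#' transplant arm never accumulates excess hazard, returns 0. If the
#' cumulative hazards touch without crossing, the touch point is returned.
#' If an excess persists forever (final-period `rr >= 1` with unresolved
#' excess) a `"txbenefit_no_crossing"` condition is signalled.
#'
#' @param profile An [rr_profile()].
#' @return Years since transplant (scalar).
#' @examples
#' time_to_equal_survival(rr_profile_preset("published"))  # 1.45
#' @export
time_to_equal_survival <- function(profile) {
  stopifnot(inherits(profile, "rr_profile"))
  rr <- profile$rr
  d <- profile$duration
  slope <- rr - 1                      # d/dt of g(t) = H(t)/m - t
  eps <- 1e-13
  n <- length(rr)
  # skip a leading coincident stretch (rr exactly 1): curves have not
  # diverged yet, so equality there is not a crossing
  k0 <- 1L
  while (k0 <= n && abs(slope[k0]) < eps) k0 <- k0 + 1L
  if (k0 > n) return(0)                # identical curves
  g <- 0
  for (k in k0:n) {
    s <- slope[k]
    # a crossing inside segment k needs g and s of opposite sign
    if (k > k0 && abs(g) > eps && s != 0 && sign(s) == -sign(g)) {
      t_hit <- profile$start[k] + g / (-s)
      if (t_hit <= profile$start[k] + d[k] + eps) return(t_hit)
    }
    if (k > k0 && abs(g) <= eps) return(profile$start[k])  # tangency at boundary
    if (is.infinite(d[k])) {
      if (g > eps && s >= 0) stop_no_crossing()
      if (g < -eps && s <= 0) return(0)  # transplant ahead forever: no excess
      # opposite signs handled above for k > k0; k0 == n means divergence
      # starts in the open-ended segment and never resolves
      if (k == k0) { if (s > 0) stop_no_crossing() else return(0) }
      return(0)
    }
    g <- g + s * d[k]
  }
  # finite segments exhausted without a final Inf segment: unreachable by
  # construction (constructor enforces an open-ended final segment)
  stop("invalid profile")              # nocov
}
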