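# Calibration of the relative-risk profile to published survival anchors:
# cohort survival at a horizon for each arm plus the time at which the two
# survival curves intersect. With the equivalent-risk period fixed, the
# increased- and reduced-risk ratios solve a 2x2 linear system exactly.

#' Calibration targets
#'
#' Published anchors the profile is fitted to: survival of each arm at a
#' horizon (default 4 years) and the observed time to equal percent
#' survival.
#'
#' @param s_wait Wait-list survival at the horizon, in `(0, 1)`.
#' @param s_tx Transplant survival at the horizon, in `(0, 1)`.
#' @param t_equal_survival Observed crossing time of the survival curves,
#'   in `(0, horizon)` years.
#' @param horizon Anchor horizon in years (default 4).
#' @return An object of class `"calibration_targets"`.
#' @examples
#' calibration_targets(0.51, 0.66, 1.6)
#' @export
calibration_targets <- function(s_wait, s_tx, t_equal_survival,
                                horizon = 4) {
  for (s in c(s_wait, s_tx))
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0 || s >= 1)
      stop("survival anchors must lie strictly between 0 and 1")
  if (horizon <= 0) stop("`horizon` must be positive")
  if (t_equal_survival <= 0 || t_equal_survival >= horizon)
    stop("`t_equal_survival` must lie in (0, horizon)")
  structure(list(s_wait = s_wait, s_tx = s_tx,
                 t_equal_survival = t_equal_survival, horizon = horizon),
            class = "calibration_targets")
}

#' Baseline hazard from the wait-list anchor
#'
#' Inverts `S(h) = exp(-m h)`: `m = -log(s_wait) / h`.
#'
#' @param s_wait Wait-list survival at the horizon, in `(0, 1)`.
#' @param horizon Horizon in years, `> 0`.
#' @return Annual hazard `m` (multiply by 100 for deaths per 100
#'   patient-years).
#' @examples
#' fit_baseline_mr(0.51, 4)  # ~0.1684
#' @export
fit_baseline_mr <- function(s_wait, horizon) {
  if (!is.numeric(s_wait) || length(s_wait) != 1L || is.na(s_wait) ||
      s_wait <= 0 || s_wait >= 1)
    stop("`s_wait` must lie strictly between 0 and 1")
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("`horizon` must be positive")
  -log(s_wait) / horizon
}

#' Fit increased- and reduced-risk ratios to survival anchors
#'
#' With period boundaries `d1` (increased risk) and `d2` (equivalent risk,
#' ratio fixed at `r2`) given, the two unknown ratios `r1` (early) and `r3`
#' (late) are determined exactly by two conditions: equal cumulative hazard
#' at the observed crossing time, and the transplant survival anchor at the
#' horizon:
#' \deqn{r_1 d_1 + r_2 d_2 + r_3 (t_{eq} - d_1 - d_2) = t_{eq}}
#' \deqn{r_1 d_1 + r_2 d_2 + r_3 (h - d_1 - d_2) = -\log(s_{tx}) / m}
#' The baseline hazard `m` comes from [fit_baseline_mr()]. Residuals are
#' reported by pushing the fitted profile back through the forward model
#' (they are zero up to round-off for this exact path); a warning is issued
#' when the fit is not physically meaningful (`r1 > 1 > r3 > 0` violated).
#'
#' @param targets A [calibration_targets()].
#' @param d1,d2 Durations (years) of the increased- and equivalent-risk
#'   periods; `horizon > d1 + d2` required.
#' @param r2 Relative risk during the equivalent-risk period (default 1).
#' @return An object of class `"calibration_result"`: `m`, `r1`, `r2`, `r3`,
#'   `d1`, `d2`, the fitted [rr_profile()], implied anchors and residuals
#'   (implied minus target).
#' @examples
#' fit_relative_risks(calibration_targets(0.51, 0.66, 1.6))
#' @export
fit_relative_risks <- function(targets, d1 = 0.2, d2 = 0.8, r2 = 1) {
  stopifnot(inherits(targets, "calibration_targets"))
  h <- targets$horizon
  t_eq <- targets$t_equal_survival
  if (h <= d1 + d2) stop("`horizon` must exceed d1 + d2")
  if (d1 <= 0 || d2 <= 0 || r2 <= 0) stop("d1, d2, r2 must be positive")
  m <- fit_baseline_mr(targets$s_wait, h)
  A <- rbind(c(d1, t_eq - d1 - d2),
             c(d1, h - d1 - d2))
  b <- c(t_eq - r2 * d2,
         -log(targets$s_tx) / m - r2 * d2)
  if (abs(det(A)) < 1e-12)
    stop_txbenefit("txbenefit_calibration_failure",
                   "degenerate anchor geometry: singular system")
  sol <- solve(A, b)
  r1 <- sol[1]; r3 <- sol[2]
  if (!(r1 > 1 && r3 < 1 && r3 > 0))
    warning(sprintf(
      "fit is not physically meaningful (expected r1 > 1 > r3 > 0; got r1 = %.4g, r3 = %.4g)",
      r1, r3))
  if (r1 <= 0 || r3 <= 0)
    stop_txbenefit("txbenefit_calibration_failure",
                   "fitted relative risks are non-positive")
  prof <- rr_profile(c(d1, d2, Inf), c(r1, r2, r3))
  implied <- list(
    s_wait = waitlist_survival(m, h),
    s_tx = transplant_survival(prof, m, h),
    t_equal_survival = tryCatch(time_to_equal_survival(prof),
                                txbenefit_no_crossing = function(e)
                                  NA_real_))
  residuals <- c(
    s_wait = implied$s_wait - targets$s_wait,
    s_tx = implied$s_tx - targets$s_tx,
    t_equal_survival = implied$t_equal_survival - t_eq)
  structure(
    list(m = m, r1 = r1, r2 = r2, r3 = r3, d1 = d1, d2 = d2,
         profile = prof, targets = targets, implied = implied,
         residuals = residuals),
    class = "calibration_result")
}

#' Implied anchors of a given profile
#'
#' The forward map used for calibration diagnostics: what survival anchors a
#' given profile and baseline hazard imply. Useful for quantifying how far a
#' published relative-risk triple is from a set of published anchors.
#'
#' @param profile An [rr_profile()].
#' @param m Annual baseline hazard.
#' @param horizon Anchor horizon in years.
#' @return A list with `s_wait`, `s_tx` (survival at the horizon) and
#'   `t_equal_survival`.
#' @export
implied_anchors <- function(profile, m, horizon = 4) {
  list(s_wait = waitlist_survival(m, horizon),
       s_tx = transplant_survival(profile, m, horizon),
       t_equal_survival = time_to_equal_survival(profile))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Relative-risk calibration\n")
  cat(sprintf("  baseline hazard m = %.5f /y (MR %.1f per 100 py)\n",
              x$m, 100 * x$m))
  cat(sprintf("  fitted ratios: r1 = %.4f (first %g y), r2 = %g (next %g y), r3 = %.4f (after)\n",
              x$r1, x$d1, x$r2, x$d2, x$r3))
  cat(sprintf("  implied anchors: S_wait(%g) = %.3f, S_tx(%g) = %.3f, crossing at %.3f y\n",
              x$targets$horizon, x$implied$s_wait, x$targets$horizon,
              x$implied$s_tx, x$implied$t_equal_survival))
  cat(sprintf("  residuals: %s\n",
              paste(sprintf("%s = %+.2e", names(x$residuals), x$residuals),
                    collapse = ", ")))
  invisible(x)
}
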