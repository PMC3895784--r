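# Independent brute-force oracles. These deliberately avoid the package's
# segment algebra: survival is evaluated from first principles and areas are
# trapezoid Riemann sums on a fine grid, so agreement with the closed forms
# is a genuine cross-check.

# relative cumulative hazard sum_k rr_k * overlap(t, segment k)
oracle_rel_cumhaz <- function(durations, rr, t) {
  starts <- cumsum(c(0, durations[-length(durations)]))
  vapply(t, function(tt)
    sum(rr * pmax(0, pmin(tt - starts, durations))), numeric(1))
}

oracle_surv_tx <- function(durations, rr, m, t)
  exp(-m * oracle_rel_cumhaz(durations, rr, t))

# trapezoid Riemann sum of f over [0, t]
riemann_auc <- function(f, t, step = 1e-4) {
  grid <- seq(0, t, by = step)
  if (grid[length(grid)] < t) grid <- c(grid, t)
  y <- f(grid)
  sum(diff(grid) * (y[-length(y)] + y[-1]) / 2)
}

# time of equal cumulative life years by Riemann sums + uniroot
oracle_t_star <- function(durations, rr, m, upper = 50, step = 1e-4) {
  f <- function(t)
    riemann_auc(function(u) exp(-m * u), t, step) -
      riemann_auc(function(u) oracle_surv_tx(durations, rr, m, u), t, step)
  stats::uniroot(function(t) f(t), c(0.05, upper), tol = 1e-9)$root
}

PUB_D <- c(0.2, 0.8, Inf)
EXT_D <- c(0.2, 1.0, Inf)
RR3 <- c(2.26, 1, 0.44)
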