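test_that("time to equal cumulative life years solves the AUC-equality root", {
  pub <- rr_profile_preset("published")
  ext <- rr_profile_preset("extended")
  expect_identical(time_to_equal_life_years(rr_profile(Inf, 1), 0.2), 0)

  t_pub <- time_to_equal_life_years(pub, 0.15)
  expect_equal(t_pub, oracle_t_star(PUB_D, RR3, 0.15), tolerance = 1e-5)
  expect_equal(t_pub, 2.551075, tolerance = 1e-5)
  t_ext <- time_to_equal_life_years(ext, 0.30)
  expect_equal(t_ext, oracle_t_star(EXT_D, RR3, 0.30), tolerance = 1e-5)
  expect_equal(t_ext, 3.002893, tolerance = 1e-5)

  # root condition and behaviour beyond the root
  for (cfg in list(list(p = pub, m = 0.15), list(p = ext, m = 0.30))) {
    ts <- time_to_equal_life_years(cfg$p, cfg$m)
    gap <- function(t) vapply(t, function(tt)
      restricted_auc("waitlist", cfg$m, tt) -
        restricted_auc("transplant", cfg$m, tt, cfg$p), numeric(1))
    expect_lt(abs(gap(ts)), 1e-10)
    later <- ts + c(0.5, 1, 2, 5)
    expect_true(all(gap(later) < 0))        # transplant arm ahead after t*
    expect_true(all(diff(-gap(later)) > 0)) # and pulling further ahead
    # and it comes strictly after the survival crossing
    expect_gt(ts, time_to_equal_survival(cfg$p))
  }

  # transplant arm that can never catch up
  expect_error(time_to_equal_life_years(rr_profile(c(0.5, Inf), c(2, 1)), 0.2),
               class = "txbenefit_no_catchup")
  expect_error(
    time_to_equal_life_years(rr_profile(c(0.2, Inf), c(80, 0.999)), 0.02),
    class = "txbenefit_no_catchup")
})

test_that("decomposition reproduces its closed forms and sums to one", {
  d <- decompose_outcomes(scenario(15, wait_years = 2, preset = "published"))
  expect_equal(d$p_no_benefit, 1 - exp(-0.3))
  expect_equal(round_half_up(100 * d$p_no_benefit), 26)
  expect_equal(d$p_harm + d$p_benefit, exp(-0.3))
  expect_equal(d$harm_benefit_ratio, d$p_harm / d$p_benefit)

  d0 <- decompose_outcomes(scenario(20, wait_years = 0))
  expect_identical(d0$p_no_benefit, 0)
  expect_equal(d0$p_harm + d0$p_benefit, 1)

  d30 <- decompose_outcomes(scenario(30, wait_years = 2, preset = "extended"))
  expect_equal(d30$p_harm, 0.2689841, tolerance = 1e-6)
  expect_equal(d30$p_benefit, 0.2798275, tolerance = 1e-6)

  # hold adjustment with p = 0 is an exact identity downstream
  expect_equal(as.list(decompose_outcomes(scenario(25, hold_fraction = 0))),
               as.list(decompose_outcomes(
                 scenario(25, hold_fraction = 0, hold_rr = 1.7))))
})

test_that("probabilities behave as probabilities across a parameter sweep", {
  for (preset in c("published", "extended")) {
    for (hold in c(0, 0.1, 0.2)) {
      for (mr in c(1, 5, 15, 28, 42, 60)) {
        for (w in c(0, 0.5, 2, 6, 10)) {
          d <- decompose_outcomes(scenario(
            mr, wait_years = w, hold_fraction = hold, preset = preset))
          p <- c(d$p_no_benefit, d$p_harm, d$p_benefit)
          expect_true(all(p >= 0 & p <= 1))
          expect_lt(abs(sum(p) - 1), 1e-12)
          expect_gte(d$t_equal_life_years, d$t_equal_survival)
        }
      }
    }
  }
  # monotonicity in mortality and waiting time
  nb_mr <- vapply(seq(5, 60, by = 5), function(mr)
    decompose_outcomes(scenario(mr))$p_no_benefit, numeric(1))
  expect_true(all(diff(nb_mr) > 0))
  byw <- lapply(0:6, function(w) decompose_outcomes(scenario(25, wait_years = w)))
  expect_true(all(diff(vapply(byw, `[[`, numeric(1), "p_no_benefit")) > 0))
  expect_true(all(diff(vapply(byw, `[[`, numeric(1), "p_benefit")) < 0))
})

test_that("harm-benefit ratio is invariant to waiting time", {
  for (mr in seq(15, 35, by = 5)) {
    r <- vapply(c(2, 3, 4), function(w)
      harm_benefit_ratio(scenario(mr, wait_years = w, hold_fraction = 0.2)),
      numeric(1))
    expect_lt(max(r) - min(r), 1e-12)
  }
})

test_that("equivalence mortality rate marks equal harm and benefit", {
  ext <- rr_profile_preset("extended")
  hold20 <- adjust_profile(ext, 0.2, 2.2)
  expect_identical(equivalence_mr(hold20, mode = "integer_grid",
                                  grid = 15:35), 22L)
  hold10 <- adjust_profile(ext, 0.1, 2.2)
  expect_identical(equivalence_mr(hold10, mode = "integer_grid",
                                  grid = 15:35), 26L)

  pub <- rr_profile_preset("published")
  mr_eq <- equivalence_mr(pub, mode = "continuous")
  expect_equal(mr_eq, 34.61516, tolerance = 1e-4)
  # at the continuous root, harm and benefit are exactly balanced
  d <- decompose_outcomes(scenario(mr_eq, preset = "published"))
  expect_equal(d$harm_benefit_ratio, 1, tolerance = 1e-6)
  expect_equal(d$p_harm, d$p_benefit, tolerance = 1e-6)

  expect_error(equivalence_mr(rr_profile(Inf, 1)),
               class = "txbenefit_no_equivalence")
})
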