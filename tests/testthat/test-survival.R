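test_that("wait-list survival is exponential with the stated unit convention", {
  expect_identical(waitlist_survival(0.3, 0), 1)
  expect_equal(waitlist_survival(-log(0.51) / 4, 4), 0.51)
  expect_equal(waitlist_survival(0.15, 2), exp(-0.3))
  expect_error(waitlist_survival(0, 1))
  expect_error(waitlist_survival(-0.1, 1))
  expect_error(waitlist_survival(0.1, -1))
  m <- mortality_rate(15)
  expect_equal(m$m, 0.15)
  expect_equal(1 / m$m, 100 / 15)
  expect_error(mortality_rate(0))
})

test_that("transplant cumulative hazard accumulates rr-weighted exposure", {
  pub <- rr_profile_preset("published")
  ones <- rr_profile(Inf, 1)
  t <- c(0, 0.13, 0.5, 1, 2.7, 10)
  expect_equal(transplant_cumulative_hazard(ones, 0.21, t), 0.21 * t)
  expect_equal(transplant_cumulative_hazard(pub, 0.15, 0.2), 0.0678)
  expect_equal(transplant_cumulative_hazard(pub, 0.15, 1), 0.1878)
  # oracle agreement and monotone continuity on a fine grid
  grid <- seq(0, 6, by = 0.01)
  h <- transplant_cumulative_hazard(pub, 0.15, grid)
  expect_equal(h, 0.15 * oracle_rel_cumhaz(PUB_D, RR3, grid))
  expect_true(all(diff(h) > 0))
})

test_that("transplant survival matches the forward model at the anchors", {
  m51 <- -log(0.51) / 4
  pub <- rr_profile_preset("published")
  ext <- rr_profile_preset("extended")
  expect_identical(transplant_survival(pub, 0.3, 0), 1)
  expect_equal(transplant_survival(pub, m51, 4), exp(-m51 * 2.572))
  expect_equal(transplant_survival(ext, 0.30, 3),
               exp(-0.3 * (0.452 + 1 + 0.44 * 1.8)))
  # with all rr = 1 the two arms coincide at every t
  ones <- rr_profile(Inf, 1)
  t <- seq(0, 20, by = 0.25)
  expect_equal(transplant_survival(ones, 0.15, t),
               waitlist_survival(0.15, t), tolerance = 1e-15)
})

test_that("closed-form restricted AUC agrees with Riemann sums", {
  pub <- rr_profile_preset("published")
  expect_identical(restricted_auc("waitlist", 0.3, 0), 0)
  expect_identical(restricted_auc("transplant", 0.3, 0, pub), 0)
  expect_equal(restricted_auc("waitlist", 0.2, Inf), 5)
  expect_equal(restricted_auc("transplant", 0.2, Inf, profile = pub),
               riemann_auc(function(t) oracle_surv_tx(PUB_D, RR3, 0.2, t),
                           250, step = 1e-3),
               tolerance = 1e-6)
  for (m in c(0.05, 0.15, 0.40)) {
    for (t_end in c(0.15, 1.0, 2.55, 5)) {
      expect_equal(
        restricted_auc("transplant", m, t_end, pub),
        riemann_auc(function(t) oracle_surv_tx(PUB_D, RR3, m, t), t_end),
        tolerance = 1e-8)
      expect_equal(restricted_auc("waitlist", m, t_end),
                   (1 - exp(-m * t_end)) / m)
    }
  }
})

test_that("life expectancy is 100/MR in the reporting unit", {
  expect_identical(life_expectancy(100), 1)
  expect_equal(round_half_up(life_expectancy(15), 1), 6.7)
  expect_equal(round_half_up(life_expectancy(22), 1), 4.5)
  expect_error(life_expectancy(0))
  expect_error(life_expectancy(-5))
})

test_that("time to equal percent survival solves the crossing in closed form", {
  pub <- rr_profile_preset("published")
  ext <- rr_profile_preset("extended")
  expect_identical(time_to_equal_survival(rr_profile(Inf, 1)), 0)
  expect_equal(time_to_equal_survival(pub), 0.812 / 0.56)
  expect_equal(time_to_equal_survival(ext), 0.924 / 0.56)
  # independence of m: the curves really do cross there, for any m
  for (m in c(0.05, 0.15, 0.35)) {
    t_eq <- time_to_equal_survival(pub)
    expect_equal(transplant_survival(pub, m, t_eq),
                 waitlist_survival(m, t_eq), tolerance = 1e-12)
  }
  # no excess hazard ever accumulates -> 0 by convention
  expect_identical(time_to_equal_survival(rr_profile(c(1, Inf), c(0.5, 0.8))), 0)
  # persistent excess -> distinct condition, not a numeric sentinel
  expect_error(time_to_equal_survival(rr_profile(c(0.5, Inf), c(2, 1.1))),
               class = "txbenefit_no_crossing")
  expect_error(time_to_equal_survival(rr_profile(Inf, 1.5)),
               class = "txbenefit_no_crossing")
  # tangency: cumulative hazards touch at t = 3 without crossing
  touch <- rr_profile(c(1, 2, Inf), c(2, 0.5, 1))
  expect_equal(time_to_equal_survival(touch), 3)
})
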