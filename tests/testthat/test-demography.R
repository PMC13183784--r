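test_that("observed_mortality is the per-interval death fraction", {
  expect_equal(observed_mortality(0, 500), 0)
  expect_equal(observed_mortality(25, 500), 0.05)
  expect_error(observed_mortality(5, 0), "positive")
  expect_error(observed_mortality(600, 500), "between 0")
})

test_that("simulated no-harvest deaths match the exponential-survival oracle", {
  # per 6-week interval the expected death fraction is 1 - exp(-6 mu)
  mu <- 0.01
  cfg <- inert_config(mu = mu)
  reps <- 200
  set.seed(14)
  rates <- vapply(seq_len(reps), function(i) {
    st <- make_state(runif(500, 10, 22), config = cfg)
    st <- simulate_phase(st, cfg, duration_weeks = 6, harvest = FALSE)
    observed_mortality(nrow(death_log(st)), 500)
  }, 0)
  expected <- 1 - exp(-6 * mu)
  se <- sd(rates) / sqrt(reps)
  expect_lt(abs(mean(rates) - expected), 3 * se)
})

test_that("mark-recapture estimator matches the closed form", {
  expect_equal(total_mortality_mark_recapture(
    data.frame(count = c(100, 100), p_hs = 1, dt_weeks = 6))$mu_week, 0)
  est <- total_mortality_mark_recapture(
    data.frame(count = c(200, 131), p_hs = c(0.8, 1), dt_weeks = 6))
  expect_equal(est$mu_week, log(160 / 131) / 6, tolerance = 1e-12)
  expect_equal(est$n_intervals, 1)
})

test_that("mark-recapture estimator input handling", {
  expect_error(total_mortality_mark_recapture(
    data.frame(count = 100, p_hs = 1, dt_weeks = 6)), ">= 2 cycles")
  # growing counts: negative estimate floored at 0 with a warning
  expect_warning(
    est <- total_mortality_mark_recapture(
      data.frame(count = c(100, 120, 150), p_hs = 1, dt_weeks = 6)),
    "floored")
  expect_equal(est$mu_week, 0)
  # zero counts truncate the series
  tr <- noiseless_track(0.05, 0.8, cycles = 6)
  tr$count[5:6] <- 0
  est2 <- total_mortality_mark_recapture(tr, seed = 1)
  expect_equal(est2$n_intervals, 3)
  expect_equal(est2$mu_week, 0.05, tolerance = 1e-10)
})

test_that("pooled estimate converges to simulator mu as cohort size grows", {
  set.seed(23)
  err <- vapply(c(100, 1000, 10000), function(n0) {
    mus <- vapply(1:10, function(i) {
      tr <- simulate_cohort_track(0.05, n0 = n0, cycles = 6,
                                  seed = 23000 + 17 * i + n0)
      total_mortality_mark_recapture(tr, n_boot = 50, seed = 1)$mu_week
    }, 0)
    abs(mean(mus) - 0.05)
  }, 0)
  expect_lt(err[3], 0.004)
  expect_lt(err[3], err[1] + 0.002)
})

test_that("generation_time follows the life-table formula", {
  # single reproducing class at x = 5: T = 5 cycles = 210 days
  lt1 <- life_table(x = c(0, 5), lx = c(1, 0.3), mx = c(0, 4))
  expect_equal(generation_time(lt1, cycle_weeks = 6), 210)
  # hand-computed oracle
  lt2 <- life_table(x = 0:2, lx = c(1, 0.5, 0.25), mx = c(0, 2, 2))
  expect_equal(generation_time(lt2, cycle_weeks = 6), 56)
  # invariance to rescaling m_x
  lt3 <- life_table(x = 0:2, lx = c(1, 0.5, 0.25), mx = c(0, 14, 14))
  expect_equal(generation_time(lt3, 6), generation_time(lt2, 6))
  expect_error(generation_time(
    life_table(x = 0:1, lx = c(1, 0.5), mx = c(0, 0)), 6), "zero net")
  expect_error(life_table(x = 0:1, lx = c(0.9, 0.5), mx = c(0, 1)), "l_0")
  expect_error(life_table(x = 0:1, lx = c(1, 1.5), mx = c(0, 1)),
               "non-increasing")
})

test_that("life-table generation time is recovered from simulated cohorts", {
  # stated world: schedules tuned so the analytic generation time is 267 days
  # (flat fecundity from age class 2 on; solve survival for T = 267/42 cycles)
  x <- 0:15
  target_cycles <- 267 / 42
  t_of_q <- function(q) {
    w <- q^x; w[x < 2] <- 0
    sum(x * w) / sum(w)
  }
  q <- uniroot(function(q) t_of_q(q) - target_cycles, c(0.3, 0.95),
               tol = 1e-12)$root
  mu <- -log(q) / 6
  mx <- ifelse(x >= 2, 3, 0)
  t_true <- generation_time(life_table(x, q^x, mx), 6)
  expect_equal(t_true, 267, tolerance = 1e-6)

  cfg <- inert_config(mu = mu)
  set.seed(37)
  ests <- vapply(1:3, function(i) {
    st <- make_state(runif(500, 10, 22), config = cfg)
    st <- mark_and_track_cohort(st, "g", rep(TRUE, 500))
    st <- simulate_phase(st, cfg, duration_weeks = 15 * 6, harvest = FALSE)
    tr <- cohort_tracks(st)
    lx_hat <- rep(0, length(x))
    lx_hat[seq_len(nrow(tr))] <- tr$count / tr$count[1]
    generation_time(data.frame(x = x, lx = cummin(pmin(1, lx_hat)), mx = mx), 6)
  }, 0)
  expect_lt(abs(mean(ests) - 267) / 267, 0.10)
})

test_that("elasticity follows the proportional-change definition", {
  expect_equal(elasticity(10, 10, 50, 40)$elasticity, 0)
  expect_equal(elasticity(10, 9, 50, 40)$elasticity, 0.5)
  # opposite-direction response: trait +5%, biomass -10%
  expect_equal(elasticity(20, 21, 50, 45)$elasticity, -0.5)
  e <- elasticity(10, 12, 50, 50)
  expect_true(e$undefined)
  expect_true(is.na(e$elasticity))
  expect_error(elasticity(0, 1, 50, 40), "trait_before")
})

test_that("elasticity is antisymmetric in trait change and unit-invariant", {
  e_up <- elasticity(10, 12, 50, 40)$elasticity
  e_dn <- elasticity(10, 8, 50, 40)$elasticity
  expect_equal(e_up, -e_dn)
  # rescaling trait and biomass units changes nothing
  e_scaled <- elasticity(10 * 25.4, 12 * 25.4, 50 / 1000, 40 / 1000)$elasticity
  expect_equal(e_up, e_scaled)
})

test_that("population_harvest_fraction implements the regime arithmetic", {
  expect_equal(population_harvest_fraction(0.60, "positive", 500, 500), 0.30)
  expect_equal(population_harvest_fraction(0.25, "positive", 500, 500), 0.125)
  expect_equal(population_harvest_fraction(0.25, "negative", 500, 500), 0.125)
  expect_equal(population_harvest_fraction(0.4, "random", 100, 900), 0.2)
  expect_equal(population_harvest_fraction(0.5, "positive", 0, 800), 0)
  expect_error(population_harvest_fraction(0.5, "positive", 0, 0), "empty")
})
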