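test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(harvest_proportion_P = 1.2), "harvest_proportion_P")
  expect_error(sim_config(census_fraction = 0), "census_fraction")
  expect_error(sim_config(cycle_weeks = 0), "cycle_weeks")
  expect_error(sim_config(growth_params = list(c = -1)), "growth_params")
  expect_error(sim_config(maturation_params = list(mode = "psychic")),
               "maturation_params")
})

test_that("initialize_population splits sexes as evenly as parity allows", {
  st <- initialize_population(sim_config(n_initial = 140, seed = 1))
  expect_equal(abundance(st), 140)
  expect_equal(unname(table(st$fish$sex)["female"]), 70L)
  expect_equal(unname(table(st$fish$sex)["male"]), 70L)

  st0 <- initialize_population(sim_config(n_initial = 0, seed = 1))
  expect_equal(abundance(st0), 0)

  st101 <- initialize_population(sim_config(n_initial = 101, seed = 1))
  expect_equal(abs(diff(as.integer(table(st101$fish$sex)))), 1L)

  # deterministic given seed
  a <- initialize_population(sim_config(seed = 7))
  b <- initialize_population(sim_config(seed = 7))
  expect_identical(a$fish, b$fish)
})

test_that("founding fish respect the configured allometry", {
  cfg <- sim_config(seed = 3)
  st <- initialize_population(cfg)
  gp <- cfg$growth_params
  expect_equal(st$fish$weight_g,
               length_to_weight(st$fish$length_mm, gp$a_wl, gp$b_wl),
               tolerance = 1e-10)
  expect_equal(biomass(st), sum(st$fish$weight_g))
})

test_that("step_week is a no-op when nothing can happen", {
  cfg <- inert_config(mu = 0, seed = 2)
  st <- make_state(runif(100, 10, 22), config = cfg)
  set.seed(2)
  st2 <- step_week(st, cfg)
  expect_equal(abundance(st2), 100)
  expect_equal(st2$week, 1L)
  expect_equal(st2$fish$length_mm, st$fish$length_mm)
  expect_equal(nrow(death_log(st2)), 0)
})

test_that("extreme mortality wipes out the population in one week", {
  cfg <- inert_config(mu = 10, seed = 5)
  st <- make_state(runif(1000, 10, 22), config = cfg)
  set.seed(5)
  st2 <- step_week(st, cfg)
  # expected survivors 1000 * exp(-10) ~ 0.045
  expect_lt(abundance(st2), 5)
})

test_that("weekly survival matches the binomial exponential-survival oracle", {
  # oracle: survivors ~ Binomial(N, exp(-mu)); mean over R replicates of the
  # simulator must sit within 3 SE of N * exp(-mu)
  mu <- 0.0718; n <- 1000; reps <- 2000
  cfg <- inert_config(mu = mu)
  st <- make_state(rep(15, n), config = cfg)
  set.seed(11)
  survivors <- vapply(seq_len(reps), function(i) abundance(step_week(st, cfg)),
                      0L)
  expected <- n * exp(-mu)
  se <- sd(survivors) / sqrt(reps)
  expect_lt(abs(mean(survivors) - expected), 3 * se + 1e-9)
})

test_that("apply_harvest implements the three regimes", {
  cfg <- inert_config(P = 0.5, regime = "positive")
  st <- make_state(c(seq(17, 26, length.out = 10), seq(7, 15, length.out = 10)))
  set.seed(1)
  res <- apply_harvest(st, cfg, P = 0.5, regime = "positive")
  expect_equal(nrow(res$harvested), 5)
  expect_true(all(res$harvested$length_mm > 16))
  expect_equal(abundance(res$state), 15)

  # P = 0: identity
  res0 <- apply_harvest(st, cfg, P = 0, regime = "positive")
  expect_equal(nrow(res0$harvested), 0)
  expect_identical(res0$state$fish, st$fish)

  # negative, P = 1: exhaustive below-or-equal threshold
  res1 <- apply_harvest(st, cfg, P = 1, regime = "negative")
  expect_true(all(res1$harvested$length_mm <= 16))
  expect_equal(nrow(res1$harvested), 10)
  expect_true(all(res1$state$fish$length_mm > 16))

  # random removes P/2 of everyone
  resr <- apply_harvest(st, cfg, P = 0.5, regime = "random")
  expect_equal(nrow(resr$harvested), 5)

  expect_error(apply_harvest(st, cfg, P = 1.5), "P")
})

test_that("boundary-length fish (exactly 16 mm) belong to the negative regime", {
  cfg <- inert_config()
  st <- make_state(c(16, 16, 20, 20))
  set.seed(1)
  pos <- apply_harvest(st, cfg, P = 1, regime = "positive")
  expect_setequal(pos$harvested$length_mm, 20)
  neg <- apply_harvest(st, cfg, P = 1, regime = "negative")
  expect_setequal(neg$harvested$length_mm, 16)
})

test_that("census samples the configured fraction, non-destructively", {
  cfg <- inert_config()
  st <- make_state(runif(400, 10, 22), config = cfg)
  set.seed(9)
  rec <- census(st, cfg)  # fraction 0.25
  expect_equal(nrow(rec), 100)
  expect_equal(abundance(st), 400)
  expect_true(all(rec$id %in% st$fish$id))

  st0 <- make_state(numeric(0), config = cfg)
  expect_equal(nrow(census(st0, cfg)), 0)

  st3 <- make_state(c(12, 15, 18), config = cfg)
  expect_equal(nrow(census(st3, cfg)), 1)  # round_half_up(0.75) = 1

  bad <- cfg; bad$census_fraction <- 1.5
  expect_error(census(st3, bad), "census_fraction")
})

test_that("cohort marking and tracking follow the survival model", {
  cfg <- inert_config(mu = 0)
  st <- make_state(runif(50, 10, 22), config = cfg)
  expect_error(mark_and_track_cohort(st, "a", rep(FALSE, 50)), "no live fish")
  st <- mark_and_track_cohort(st, "a", rep(TRUE, 50))
  set.seed(4)
  st <- simulate_phase(st, cfg, duration_weeks = 18, cycle_weeks = 6,
                       harvest = FALSE)
  tr <- cohort_tracks(st)
  expect_equal(tr$count, c(50, 50, 50))
  expect_equal(tr$p_hs, c(1, 1, 1))

  # exact halving: whole population marked, random harvest P = 1 removes half
  st2 <- make_state(runif(100, 10, 22), config = cfg)
  st2 <- mark_and_track_cohort(st2, "h", rep(TRUE, 100))
  set.seed(4)
  st2 <- simulate_phase(st2, cfg, duration_weeks = 18, cycle_weeks = 6,
                        harvest = TRUE, regime = "random", P = 1)
  tr2 <- cohort_tracks(st2)
  expect_equal(tr2$count, c(100, 50, 25))
  # last cycle: round_half_up(12.5) = 13 of 25 removed
  expect_equal(tr2$p_hs, c(0.5, 0.5, 0.48))
})

test_that("cohort decay matches N[t+1] = exp(-mu dt) P_hs N[t] in expectation", {
  # mark 200, harvest survival 0.8 applied at marking, mu dt = 0.2 over one
  # 6-week cycle: expected count 200 * exp(-0.2) * 0.8 = 131.0
  mu <- 0.2 / 6
  cfg <- inert_config(mu = mu)
  reps <- 2000
  set.seed(21)
  counts <- vapply(seq_len(reps), function(i) {
    st <- make_state(runif(200, 10, 22), config = cfg)
    st <- mark_and_track_cohort(st, "m", rep(TRUE, 200))
    res <- apply_harvest(st, cfg, P = 0.4, regime = "random")  # removes 40
    st <- res$state
    for (w in 1:6) st <- step_week(st, cfg)
    sum(!is.na(st$fish$cohort))
  }, 0L)
  expected <- 200 * exp(-0.2) * 0.8
  se <- sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("conservation: initial + births = alive + dead + harvested", {
  cfg <- sim_config(regime = "positive", seed = 31,
                    harvest_proportion_P = 0.5)
  st <- initialize_population(cfg)
  st <- simulate_phase(st, cfg, duration_weeks = 60, phase = "p1",
                       replicate = 1L)
  expect_equal(st$n_initial + st$births,
               abundance(st) + nrow(death_log(st)) + nrow(harvest_log(st)))
})

test_that("regime selectivity holds over full runs", {
  for (reg in c("positive", "negative")) {
    cfg <- sim_config(regime = reg, seed = 17, harvest_proportion_P = 0.6)
    st <- initialize_population(cfg)
    st <- simulate_phase(st, cfg, duration_weeks = 90)
    hv <- harvest_log(st)
    expect_gt(nrow(hv), 0)
    if (reg == "positive") {
      expect_true(all(hv$length_mm > cfg$size_threshold_mm))
    } else {
      expect_true(all(hv$length_mm <= cfg$size_threshold_mm))
    }
  }
})

test_that("event logs are bit-identical under a fixed seed", {
  run <- function() {
    cfg <- sim_config(regime = "negative", seed = 99)
    st <- initialize_population(cfg)
    st <- simulate_phase(st, cfg, duration_weeks = 48, phase = "x",
                         replicate = 1L, mark_recruit_cohorts = TRUE)
    list(census_log(st), death_log(st), harvest_log(st), cohort_tracks(st),
         st$fish)
  }
  expect_identical(run(), run())
})

test_that("positive harvest truncates the length distribution above threshold", {
  run <- function(P) {
    cfg <- sim_config(regime = "positive", seed = 55, harvest_proportion_P = P)
    st <- initialize_population(cfg)
    st <- simulate_phase(st, cfg, duration_weeks = 12 * 6, harvest = P > 0)
    mean(st$fish$length_mm[st$fish$length_mm > cfg$size_threshold_mm])
  }
  expect_lt(run(0.5), run(0))
})
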