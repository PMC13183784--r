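# Shared fixtures, all generated in code.

# A configuration with every biological process inert except the one under
# test: no growth, no maturation, no reproduction.
inert_config <- function(mu = 0, regime = "random", P = 0.4, seed = NULL,
                         ...) {
  sim_config(regime = regime, harvest_proportion_P = P, mu_nat_week = mu,
             growth_params = list(c = 0),
             maturation_params = list(lp50_mm = 1e6, slope = 5),
             fecundity_params = list(b0 = 0, b1 = 0),
             seed = seed, ...)
}

# Build a population_state directly from a vector of lengths.
make_state <- function(lengths, mature = FALSE, sex = NULL,
                       config = inert_config()) {
  n <- length(lengths)
  gp <- config$growth_params
  if (n == 0L) {
    return(harvestlab:::new_population_state(harvestlab:::fish_columns(),
                                             week = 0L))
  }
  fish <- data.frame(
    id = seq_len(n),
    sex = sex %||% rep(c("female", "male"), length.out = n),
    age_weeks = 10,
    length_mm = lengths,
    weight_g = harvestlab:::length_to_weight(lengths, gp$a_wl, gp$b_wl),
    mature = rep(mature, length.out = n),
    cohort = NA_character_,
    brood_due_weeks = NA_real_,
    stringsAsFactors = FALSE)
  harvestlab:::new_population_state(fish, week = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noiseless geometric-decay cohort track N[t+1] = exp(-mu dt) p_hs N[t].
noiseless_track <- function(mu, p_hs, dt = 6, n0 = 1000, cycles = 6) {
  counts <- numeric(cycles)
  counts[1] <- n0
  for (i in seq_len(cycles - 1)) {
    counts[i + 1] <- counts[i] * p_hs * exp(-mu * dt)
  }
  data.frame(cycle = seq_len(cycles), count = counts, p_hs = p_hs,
             dt_weeks = dt)
}

# Simulate one marked cohort through the IBM under random harvest and return
# its track (used by mortality-recovery tests).
simulate_cohort_track <- function(mu, n0 = 500, cycles = 8, P = 0.5,
                                  seed = 1) {
  cfg <- inert_config(mu = mu, regime = "random", P = P, seed = seed)
  set.seed(seed)
  st <- make_state(runif(n0, 10, 22), config = cfg)
  st <- mark_and_track_cohort(st, "k", rep(TRUE, n0))
  st <- simulate_phase(st, cfg, duration_weeks = cycles * 6, cycle_weeks = 6,
                       harvest = TRUE, regime = "random", P = P)
  cohort_tracks(st)
}
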