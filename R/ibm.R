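# Individual-based simulator: size-structured, iteroparous populations with
# overlapping generations under size-dependent harvest.
#
# A population_state holds the live fish as one data.frame plus an event log
# (censuses, deaths, harvests, cohort tracks). All stochastic events draw from
# the session RNG; seeding is done once per replicate, so a fixed seed gives a
# bit-identical event log.

fish_columns <- function() {
  data.frame(id = integer(), sex = character(), age_weeks = numeric(),
             length_mm = numeric(), weight_g = numeric(), mature = logical(),
             cohort = character(), brood_due_weeks = numeric(),
             stringsAsFactors = FALSE)
}

new_population_state <- function(fish, week = 0L, next_id = NULL) {
  structure(list(
    week = as.integer(week),
    fish = fish,
    next_id = as.integer(next_id %||% (max(c(0L, fish$id)) + 1L)),
    births = 0L,
    n_initial = nrow(fish),
    log = list(censuses = list(), deaths = list(), harvests = list(),
               cohorts = list(), popsize = list())
  ), class = "population_state")
}

#' Population abundance and biomass
#'
#' @param state a \code{population_state}.
#' @return \code{abundance()}: number of live fish; \code{biomass()}: summed
#'   live weight in g.
#' @export
abundance <- function(state) nrow(state$fish)

#' @rdname abundance
#' @export
biomass <- function(state) sum(state$fish$weight_g)

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> week %d: %d fish, %.1f g biomass, %d births logged\n",
              x$week, abundance(x), biomass(x), x$births))
  invisible(x)
}

#' Initialize a founding population
#'
#' Creates \code{n_initial} fish with sexes split as evenly as parity allows,
#' ages uniform on 0..\code{init_age_max_weeks}, and weights obtained by
#' running the juvenile growth recursion from the newborn size for each age
#' (with lognormal individual variation), so that founding lengths are
#' consistent with the configured growth model and allometry.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{population_state} at week 0.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_initial
  if (n == 0L) {
    return(new_population_state(fish_columns(), week = 0L, next_id = 1L))
  }
  gp <- config$growth_params
  sexes <- sample(rep(c("female", "male"), length.out = n))
  ages <- sample.int(config$init_age_max_weeks + 1L, n, replace = TRUE) - 1L
  w <- rep(length_to_weight(config$newborn_length_mm, gp$a_wl, gp$b_wl), n)
  for (a in seq_len(max(ages))) {
    juv <- ages >= a
    w[juv] <- w[juv] + gp$c * w[juv]^gp$alpha
  }
  w <- w * exp(stats::rnorm(n, 0, 0.1))
  len <- weight_to_length(w, gp$a_wl, gp$b_wl)
  mp <- config$maturation_params
  mature <- if (mp$mode == "deterministic") {
    len >= mp$lp50_mm
  } else {
    stats::runif(n) < stats::plogis(mp$slope * (len - mp$lp50_mm))
  }
  brood_due <- rep(NA_real_, n)
  fem_mat <- mature & sexes == "female"
  if (any(fem_mat)) {
    brood_due[fem_mat] <- sample.int(config$fecundity_params$brood_interval_weeks,
                                     sum(fem_mat), replace = TRUE)
  }
  fish <- data.frame(id = seq_len(n), sex = sexes, age_weeks = as.numeric(ages),
                     length_mm = len, weight_g = w, mature = mature,
                     cohort = NA_character_, brood_due_weeks = brood_due,
                     stringsAsFactors = FALSE)
  new_population_state(fish, week = 0L, next_id = n + 1L)
}

# Effective (possibly drifted) process parameters for one week.
effective_params <- function(config, override = NULL) {
  eff <- list(mu = config$mu_nat_week,
              c = config$growth_params$c,
              r = config$growth_params$r,
              lp50_mm = config$maturation_params$lp50_mm)
  if (!is.null(override)) eff[names(override)] <- override
  eff
}

#' Advance the population by one week
#'
#' Applies, in fixed order: natural mortality (per-capita survival
#' \code{exp(-mu)}, optionally scaled by relative biomass), the biphasic
#' growth increment (scaled by the food factor), a maturation trial for
#' immature fish, and brood release for females whose inter-brood interval has
#' elapsed. Ages and the clock advance by one week; deaths are logged.
#'
#' @param state a \code{population_state}.
#' @param config a \code{\link{sim_config}}.
#' @param override optional named list overriding \code{mu}, \code{c},
#'   \code{r} or \code{lp50_mm} for this week (used for phenomenological
#'   trait drift in \code{\link{run_experiment}}).
#' @return the advanced \code{population_state}.
#' @export
step_week <- function(state, config, override = NULL) {
  stopifnot(inherits(state, "population_state"), inherits(config, "sim_config"))
  eff <- effective_params(config, override)
  fish <- state$fish
  week_next <- state$week + 1L
  n <- nrow(fish)
  if (n > 0L) {
    # 1. natural mortality
    bm <- sum(fish$weight_g)
    mort_scale <- if (config$gamma_mort == 0) 1 else
      (bm / config$food_ration)^config$gamma_mort
    p_surv <- exp(-eff$mu * mort_scale)
    dead <- stats::runif(n) >= p_surv
    if (any(dead)) {
      d <- fish[dead, , drop = FALSE]
      state$log$deaths[[length(state$log$deaths) + 1L]] <-
        data.frame(week = week_next, id = d$id, age_weeks = d$age_weeks + 1,
                   length_mm = d$length_mm, sex = d$sex,
                   stringsAsFactors = FALSE)
      fish <- fish[!dead, , drop = FALSE]
    }
  }
  n <- nrow(fish)
  if (n > 0L) {
    gp <- config$growth_params
    # 2. growth, density-dependent through the food factor
    bm <- sum(fish$weight_g)
    f <- min(config$food_factor_max,
             (config$food_ration / bm)^config$gamma_growth)
    dw <- eff$c * fish$weight_g^gp$alpha * f
    dw[fish$mature] <- dw[fish$mature] / (1 + eff$r)
    fish$weight_g <- fish$weight_g + dw
    fish$length_mm <- weight_to_length(fish$weight_g, gp$a_wl, gp$b_wl)
    # 3. maturation trial for immature fish
    mp <- config$maturation_params
    imm <- which(!fish$mature)
    if (length(imm) > 0L) {
      newly <- if (mp$mode == "deterministic") {
        imm[fish$length_mm[imm] >= eff$lp50_mm]
      } else {
        p <- stats::plogis(mp$slope * (fish$length_mm[imm] - eff$lp50_mm))
        imm[stats::runif(length(imm)) < p]
      }
      if (length(newly) > 0L) {
        fish$mature[newly] <- TRUE
        fem <- newly[fish$sex[newly] == "female"]
        fish$brood_due_weeks[fem] <- config$fecundity_params$brood_interval_weeks
      }
    }
    # 4. brood release
    fp <- config$fecundity_params
    mothers <- which(fish$mature & fish$sex == "female")
    newborns <- 0L
    if (length(mothers) > 0L) {
      fish$brood_due_weeks[mothers] <- fish$brood_due_weeks[mothers] - 1
      due <- mothers[fish$brood_due_weeks[mothers] <= 0]
      if (length(due) > 0L) {
        len <- fish$length_mm[due]
        brood <- ifelse(len > fp$threshold_mm,
                        pmax(0L, round_half_up(fp$b0 + fp$b1 * (len - fp$threshold_mm))),
                        0L)
        fish$brood_due_weeks[due] <- fp$brood_interval_weeks
        newborns <- sum(brood)
      }
    }
    fish$age_weeks <- fish$age_weeks + 1
    if (newborns > 0L) {
      gp <- config$growth_params
      w0 <- length_to_weight(config$newborn_length_mm, gp$a_wl, gp$b_wl)
      kids <- data.frame(
        id = seq.int(state$next_id, length.out = newborns),
        sex = ifelse(stats::runif(newborns) < 0.5, "female", "male"),
        age_weeks = 0, length_mm = config$newborn_length_mm, weight_g = w0,
        mature = FALSE, cohort = NA_character_, brood_due_weeks = NA_real_,
        stringsAsFactors = FALSE)
      fish <- rbind(fish, kids)
      state$next_id <- state$next_id + newborns
      state$births <- state$births + newborns
    }
  }
  state$fish <- fish
  state$week <- week_next
  state
}

#' Apply one size-dependent harvest event
#'
#' Positive harvest removes a simple random sample of
#' \code{round(P * n_above)} fish strictly above the size threshold; negative
#' harvest removes \code{round(P * n_below)} of the fish at or below it;
#' random harvest removes \code{round((P/2) * n)} irrespective of size (so all
#' three regimes remove about P/2 of the population when abundance is balanced
#' across the threshold). Rounding is half-up. Removed fish are logged.
#'
#' @param state a \code{population_state}; call on harvest-cycle boundaries.
#' @param config a \code{\link{sim_config}}.
#' @param P per-size-class harvest intensity; defaults to the configured one.
#' @param regime harvest regime; defaults to the configured one.
#' @param phase optional phase label recorded in the harvest log.
#' @return list with elements \code{state} (fish removed, event logged) and
#'   \code{harvested} (data.frame of removed fish).
#' @export
apply_harvest <- function(state, config, P = config$harvest_proportion_P,
                          regime = config$regime, phase = NA_character_) {
  stopifnot(inherits(state, "population_state"))
  if (!is.numeric(P) || length(P) != 1L || is.na(P) || P < 0 || P > 1) {
    stop("harvest proportion P must be in [0, 1]", call. = FALSE)
  }
  fish <- state$fish
  thr <- config$size_threshold_mm
  eligible <- switch(regime,
    positive = which(fish$length_mm > thr),
    negative = which(fish$length_mm <= thr),
    random   = seq_len(nrow(fish)),
    stop("unknown regime: ", regime, call. = FALSE))
  k <- if (regime == "random") {
    round_half_up((P / 2) * nrow(fish))
  } else {
    round_half_up(P * length(eligible))
  }
  k <- min(k, length(eligible))
  take <- sample_ids(eligible, k)
  harvested <- fish[take, , drop = FALSE]
  if (k > 0L) {
    state$log$harvests[[length(state$log$harvests) + 1L]] <-
      data.frame(week = state$week, phase = phase, regime = regime, P = P,
                 id = harvested$id, length_mm = harvested$length_mm,
                 sex = harvested$sex, mature = harvested$mature,
                 stringsAsFactors = FALSE)
    state$fish <- fish[-take, , drop = FALSE]
  }
  list(state = state, harvested = harvested)
}

#' Phenotypic census
#'
#' Samples \code{round(census_fraction * abundance)} live fish without
#' replacement (half-up rounding) and records length, sex and maturity.
#' Non-destructive: sampled fish remain in the population.
#'
#' @param state a \code{population_state}.
#' @param config a \code{\link{sim_config}}.
#' @param replicate,phase labels copied into each record.
#' @return data.frame of census records (possibly empty).
#' @export
census <- function(state, config, replicate = NA_integer_,
                   phase = NA_character_) {
  if (config$census_fraction <= 0 || config$census_fraction > 1) {
    stop("census_fraction must be in (0, 1]", call. = FALSE)
  }
  fish <- state$fish
  n <- nrow(fish)
  k <- min(n, round_half_up(config$census_fraction * n))
  empty <- data.frame(replicate = integer(), regime = character(),
                      week = integer(), phase = character(), id = integer(),
                      sex = character(), length_mm = numeric(),
                      mature = logical(), stringsAsFactors = FALSE)
  if (k == 0L) return(empty)
  take <- sample_ids(seq_len(n), k)
  s <- fish[take, , drop = FALSE]
  data.frame(replicate = replicate, regime = config$regime, week = state$week,
             phase = phase, id = s$id, sex = s$sex, length_mm = s$length_mm,
             mature = s$mature, stringsAsFactors = FALSE)
}

#' Mark a cohort for mark-recapture tracking
#'
#' Tags the selected live fish with a cohort label. Thereafter, every harvest
#' cycle the simulator appends (cycle index, pre-harvest count alive, realized
#' harvest survival P_hs) to the cohort track in the event log; retrieve it
#' with \code{\link{cohort_tracks}}.
#'
#' @param state a \code{population_state}.
#' @param label cohort label (character scalar).
#' @param selection a logical vector over the live fish, a vector of fish ids,
#'   or a predicate \code{function(fish_df)} returning a logical vector.
#' @return the updated \code{population_state}.
#' @export
mark_and_track_cohort <- function(state, label, selection) {
  fish <- state$fish
  sel <- if (is.function(selection)) {
    selection(fish)
  } else if (is.logical(selection)) {
    selection
  } else {
    fish$id %in% selection
  }
  if (length(sel) != nrow(fish)) {
    stop("selection must address every live fish", call. = FALSE)
  }
  if (!any(sel)) stop("cohort selection matches no live fish", call. = FALSE)
  state$fish$cohort[sel] <- as.character(label)
  state
}

# Append one tracking row per active cohort. `p_hs` is a named vector of
# realized harvest survival per cohort for the harvest applied at this cycle
# boundary (1 when there was no harvest).
record_cohort_cycle <- function(state, cycle, dt_weeks, p_hs = NULL,
                                counts = NULL) {
  labs <- sort(unique(state$fish$cohort[!is.na(state$fish$cohort)]))
  labs <- union(labs, names(counts))
  if (length(labs) == 0L) return(state)
  cnt <- counts %||% table(factor(state$fish$cohort, levels = labs))
  rows <- data.frame(cohort = labs, cycle = cycle, week = state$week,
                     dt_weeks = dt_weeks,
                     count = as.integer(cnt[labs]),
                     p_hs = if (is.null(p_hs)) 1 else as.numeric(p_hs[labs]),
                     stringsAsFactors = FALSE)
  rows$count[is.na(rows$count)] <- 0L
  rows$p_hs[is.na(rows$p_hs)] <- 1
  state$log$cohorts[[length(state$log$cohorts) + 1L]] <- rows
  state
}

#' Extract event-log tables from a population state
#'
#' @param state a \code{population_state}.
#' @return a data.frame (zero rows if no events of that kind were logged).
#' @export
cohort_tracks <- function(state) {
  bind_log(state$log$cohorts,
           data.frame(cohort = character(), cycle = integer(), week = integer(),
                      dt_weeks = numeric(), count = integer(), p_hs = numeric(),
                      stringsAsFactors = FALSE))
}

#' @rdname cohort_tracks
#' @export
death_log <- function(state) {
  bind_log(state$log$deaths,
           data.frame(week = integer(), id = integer(), age_weeks = numeric(),
                      length_mm = numeric(), sex = character(),
                      stringsAsFactors = FALSE))
}

#' @rdname cohort_tracks
#' @export
harvest_log <- function(state) {
  bind_log(state$log$harvests,
           data.frame(week = integer(), phase = character(), regime = character(),
                      P = numeric(), id = integer(), length_mm = numeric(),
                      sex = character(), mature = logical(),
                      stringsAsFactors = FALSE))
}

#' @rdname cohort_tracks
#' @export
popsize_log <- function(state) {
  bind_log(state$log$popsize,
           data.frame(week = integer(), phase = character(),
                      abundance = integer(), biomass_g = numeric(),
                      stringsAsFactors = FALSE))
}

#' @rdname cohort_tracks
#' @export
census_log <- function(state) {
  bind_log(state$log$censuses,
           data.frame(replicate = integer(), regime = character(),
                      week = integer(), phase = character(), id = integer(),
                      sex = character(), length_mm = numeric(),
                      mature = logical(), stringsAsFactors = FALSE))
}

bind_log <- function(lst, empty) {
  if (length(lst) == 0L) empty else do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

#' Simulate one population phase
#'
#' Runs the weekly scheduler for \code{duration_weeks}, with a census, cohort
#' bookkeeping and (optionally) a harvest event every \code{cycle_weeks}.
#' Event order at a cycle boundary: census, cohort marking (optional), cohort
#' count recording (pre-harvest), harvest.
#'
#' @param state a \code{population_state} (e.g. from
#'   \code{\link{initialize_population}}).
#' @param config a \code{\link{sim_config}}.
#' @param duration_weeks phase length in weeks.
#' @param cycle_weeks event interval; defaults to the configured cycle.
#' @param harvest logical: apply harvest at cycle boundaries?
#' @param P,regime harvest settings for this phase (default from config).
#' @param phase label attached to logged events.
#' @param replicate replicate id attached to census records.
#' @param mark_recruit_cohorts if TRUE, fish younger than one cycle are marked
#'   as a new cohort at every boundary (emulating VIE-marked cohorts).
#' @param drift optional named numeric vector of per-week additive drifts for
#'   \code{mu}, \code{c}, \code{r}, \code{lp50_mm}, applied linearly over the
#'   phase on top of \code{drift_offset_weeks} of accumulated drift.
#' @param drift_offset_weeks weeks of drift already accumulated before this
#'   phase.
#' @param cycle0 starting cycle index for cohort bookkeeping.
#' @return the advanced \code{population_state}.
#' @export
simulate_phase <- function(state, config, duration_weeks,
                           cycle_weeks = config$cycle_weeks,
                           harvest = TRUE,
                           P = config$harvest_proportion_P,
                           regime = config$regime,
                           phase = NA_character_,
                           replicate = NA_integer_,
                           mark_recruit_cohorts = FALSE,
                           drift = NULL, drift_offset_weeks = 0,
                           cycle0 = 0L) {
  stopifnot(duration_weeks >= 0)
  cyc <- as.integer(cycle_weeks)
  cycle <- as.integer(cycle0)
  for (w in seq_len(duration_weeks)) {
    override <- NULL
    if (!is.null(drift) && length(drift) > 0L) {
      base <- effective_params(config)
      shift <- drift * (drift_offset_weeks + w)
      override <- as.list(unlist(base[names(drift)]) + shift)
      if (!is.null(override$mu)) override$mu <- max(0, override$mu)
      if (!is.null(override$c)) override$c <- max(0, override$c)
      if (!is.null(override$r)) override$r <- max(0, override$r)
    }
    state <- step_week(state, config, override = override)
    if (w %% cyc == 0L) {
      cycle <- cycle + 1L
      state$log$censuses[[length(state$log$censuses) + 1L]] <-
        census(state, config, replicate = replicate, phase = phase)
      state$log$popsize[[length(state$log$popsize) + 1L]] <-
        data.frame(week = state$week, phase = phase,
                   abundance = abundance(state), biomass_g = biomass(state),
                   stringsAsFactors = FALSE)
      if (mark_recruit_cohorts) {
        young <- state$fish$age_weeks < cyc & is.na(state$fish$cohort)
        if (any(young)) {
          lab <- sprintf("c%03d", cycle)
          state <- mark_and_track_cohort(state, lab, young)
        }
      }
      marked <- !is.na(state$fish$cohort)
      labs <- sort(unique(state$fish$cohort[marked]))
      before <- table(factor(state$fish$cohort, levels = labs))
      if (harvest) {
        res <- apply_harvest(state, config, P = P, regime = regime,
                             phase = phase)
        state <- res$state
      }
      if (length(labs) > 0L) {
        after <- table(factor(state$fish$cohort, levels = labs))
        p_hs <- ifelse(before > 0, as.numeric(after) / as.numeric(before), 1)
        names(p_hs) <- labs
        state <- record_cohort_cycle(state, cycle, cyc, p_hs = p_hs,
                                     counts = before)
      }
    }
  }
  state
}
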