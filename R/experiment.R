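# End-to-end orchestration of the three-regime, multi-phase selection
# experiment on synthetic populations.

#' Build an experiment plan
#'
#' The default plan mirrors the decade-long design: a 28-week establishment
#' (baseline) period without harvest, harvest phase 1 (167 weeks, 6-week
#' cycles), a recovery phase in which every population is harvested randomly
#' every 12 weeks (154 weeks) followed by a 46-week break with no harvest at
#' all, and harvest phase 2 (153 weeks, 6-week cycles, with the final six
#' events at 12-week intervals at doubled intensity). Phase durations scale
#' with \code{scale} (tests run a 10x shorter plan).
#'
#' @param replicates populations per regime.
#' @param master_seed master RNG seed; per-population seeds are derived from
#'   it by fixed offsets.
#' @param P baseline per-size-class harvest intensity.
#' @param scale multiplier applied to phase durations (cycle lengths are
#'   untouched); durations are rounded to whole cycles.
#' @param phases optional custom phase table overriding the default; a
#'   data.frame with columns \code{label}, \code{duration_weeks},
#'   \code{cycle_weeks}, \code{regime} (\code{"treatment"} applies each
#'   population's own regime), \code{P}, \code{harvest}, \code{mark_cohorts},
#'   \code{drift} (does phenomenological trait drift accrue in this phase?).
#' @return an \code{experiment_plan}.
#' @export
experiment_plan <- function(replicates = 3L, master_seed = 1L, P = 0.4,
                            scale = 1, phases = NULL) {
  if (is.null(phases)) {
    phases <- data.frame(
      label = c("baseline", "harvest1", "recovery", "break",
                "harvest2", "harvest2"),
      duration_weeks = c(28, 167, 154, 46, 81, 72),
      cycle_weeks = c(6, 6, 12, 12, 6, 12),
      regime = c("none", "treatment", "random", "none",
                 "treatment", "treatment"),
      P = c(0, P, P, 0, P, min(1, 2 * P)),
      harvest = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
      mark_cohorts = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
      drift = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  }
  req <- c("label", "duration_weeks", "cycle_weeks", "regime", "P",
           "harvest", "mark_cohorts", "drift")
  if (!all(req %in% names(phases))) {
    stop("phase table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(phases$duration_weeks < 0)) {
    stop("phase durations must be non-negative", call. = FALSE)
  }
  bad <- phases$label == "recovery" & phases$harvest &
    phases$regime != "random"
  if (any(bad)) {
    stop("the recovery phase must apply random harvest to all populations",
         call. = FALSE)
  }
  if (scale != 1) {
    scaled <- phases$cycle_weeks *
      round(phases$duration_weeks * scale / phases$cycle_weeks)
    # a phase present in the plan survives scaling with at least one cycle
    phases$duration_weeks <- ifelse(phases$duration_weeks > 0,
                                    pmax(scaled, phases$cycle_weeks), 0)
  }
  structure(list(phases = phases, replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed)),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> %d replicates per regime, master seed %d\n",
              x$replicates, x$master_seed))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Default phenomenological trait drift per regime
#'
#' Trait evolution is emulated, not mechanistically inherited: the
#' probabilistic maturation midpoint Lp50 drifts linearly (mm per week)
#' during size-dependent harvest phases, only in positively harvested
#' populations (a faster life history under harvest of the large).
#'
#' @param lp50_per_week drift of Lp50 in the positive regime, mm/week.
#' @return named list of per-regime drift vectors, suitable for
#'   \code{\link{run_experiment}}.
#' @export
default_drift <- function(lp50_per_week = -0.005) {
  list(positive = c(lp50_mm = lp50_per_week), negative = NULL, random = NULL)
}

#' Run the full multi-phase, three-regime experiment
#'
#' Simulates \code{replicates} populations for each harvest regime through
#' every phase of the plan, collecting censuses, death/harvest logs,
#' population sizes and marked-cohort tracks. Per-population seeds are
#' \code{master_seed + 1000 * population_index}, so the whole experiment is
#' reproducible bit-for-bit from the master seed.
#'
#' @param plan an \code{\link{experiment_plan}}.
#' @param config a \code{\link{sim_config}} template (its \code{regime} and
#'   \code{seed} are overridden per population).
#' @param regimes regimes to simulate.
#' @param drift per-regime drift specification, see \code{\link{default_drift}};
#'   \code{NULL} disables drift.
#' @return an \code{experiment_logs} object: combined tidy tables
#'   \code{census}, \code{deaths}, \code{harvests}, \code{cohorts},
#'   \code{popsize}, plus the plan and config echo.
#' @export
run_experiment <- function(plan, config = sim_config(),
                           regimes = c("positive", "negative", "random"),
                           drift = default_drift()) {
  stopifnot(inherits(plan, "experiment_plan"), inherits(config, "sim_config"))
  pops <- expand.grid(replicate = seq_len(plan$replicates),
                      regime = regimes, stringsAsFactors = FALSE)
  res <- vector("list", nrow(pops))
  for (i in seq_len(nrow(pops))) {
    reg <- pops$regime[i]; rep_i <- pops$replicate[i]
    cfg <- config
    cfg$regime <- reg
    cfg$seed <- plan$master_seed + 1000L * i
    state <- initialize_population(cfg)
    drift_vec <- drift[[reg]]
    drift_off <- 0
    cycle0 <- 0L
    phase_rows <- list()
    week0 <- 0L
    for (p in seq_len(nrow(plan$phases))) {
      ph <- plan$phases[p, ]
      reg_ph <- if (ph$regime == "treatment") reg else ph$regime
      use_drift <- isTRUE(ph$drift) && !is.null(drift_vec) &&
        length(drift_vec) > 0L
      state <- simulate_phase(
        state, cfg,
        duration_weeks = ph$duration_weeks,
        cycle_weeks = ph$cycle_weeks,
        harvest = isTRUE(ph$harvest),
        P = ph$P,
        regime = reg_ph,
        phase = ph$label,
        replicate = rep_i,
        mark_recruit_cohorts = isTRUE(ph$mark_cohorts),
        drift = if (use_drift) drift_vec else NULL,
        drift_offset_weeks = drift_off,
        cycle0 = cycle0)
      if (use_drift) drift_off <- drift_off + ph$duration_weeks
      cycle0 <- cycle0 + ph$duration_weeks %/% ph$cycle_weeks
      phase_rows[[p]] <- data.frame(phase = ph$label, start_week = week0,
                                    end_week = week0 + ph$duration_weeks,
                                    stringsAsFactors = FALSE)
      week0 <- week0 + ph$duration_weeks
    }
    phase_table <- do.call(rbind, phase_rows)
    annotate <- function(df) {
      if (nrow(df) == 0L) {
        return(cbind(data.frame(replicate = integer(), regime = character(),
                                stringsAsFactors = FALSE), df))
      }
      cbind(data.frame(replicate = rep_i, regime = reg,
                       stringsAsFactors = FALSE), df)
    }
    dl <- death_log(state)
    if (nrow(dl) > 0L) {
      idx <- findInterval(dl$week, phase_table$start_week, left.open = TRUE,
                          rightmost.closed = FALSE)
      idx[idx < 1L] <- 1L
      dl$phase <- phase_table$phase[pmin(idx, nrow(phase_table))]
    } else {
      dl$phase <- character(0)
    }
    res[[i]] <- list(
      census = census_log(state),
      deaths = annotate(dl),
      harvests = annotate(harvest_log(state)),
      cohorts = annotate(cohort_tracks(state)),
      popsize = annotate(popsize_log(state)),
      final_abundance = abundance(state),
      seed = cfg$seed, regime = reg, replicate = rep_i)
  }
  combine <- function(field) {
    do.call(rbind, c(lapply(res, `[[`, field), list(make.row.names = FALSE)))
  }
  structure(list(
    census = combine("census"),
    deaths = combine("deaths"),
    harvests = combine("harvests"),
    cohorts = combine("cohorts"),
    popsize = combine("popsize"),
    plan = plan, config = config,
    populations = data.frame(
      replicate = pops$replicate, regime = pops$regime,
      seed = vapply(res, `[[`, 0L, "seed"),
      final_abundance = vapply(res, `[[`, 0L, "final_abundance"),
      stringsAsFactors = FALSE)
  ), class = "experiment_logs")
}

#' @export
print.experiment_logs <- function(x, ...) {
  cat(sprintf("<experiment_logs> %d populations, %d census records, %d harvest rows\n",
              nrow(x$populations), nrow(x$census), nrow(x$harvests)))
  invisible(x)
}

# ---- summaries ------------------------------------------------------------

agg_mean_se <- function(df, value, by) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(regime = character(), phase = character(),
                      estimate = numeric(), se = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(df[[value]], df[by], drop = TRUE)
  keys <- do.call(rbind, strsplit(names(sp), "\\."))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  out$estimate <- vapply(sp, function(v) mean(v, na.rm = TRUE), 0)
  out$se <- vapply(sp, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  }, 0)
  out$n <- vapply(sp, function(v) sum(!is.na(v)), 0L)
  rownames(out) <- NULL
  out
}

normalize_to_baseline <- function(tab) {
  if (nrow(tab) == 0L) {
    tab$normalized <- numeric(0)
    return(tab)
  }
  base <- tab[tab$phase == "baseline", c("regime", "estimate")]
  names(base)[2] <- "baseline"
  out <- merge(tab, base, by = "regime", all.x = TRUE)
  out$normalized <- ifelse(is.na(out$baseline) | out$baseline == 0,
                           NA_real_, out$estimate / out$baseline)
  out$baseline <- NULL
  out
}

summ_per_replicate <- function(df, fun) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(regime = character(), phase = character(),
                      replicate = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(df, df[c("regime", "phase", "replicate")], drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(regime = d$regime[1L], phase = d$phase[1L],
               replicate = d$replicate[1L], value = fun(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarize an experiment into per-regime, per-phase report tables
#'
#' Computes, per harvest regime and experiment phase (replicate-level
#' estimates aggregated as mean and SE across the replicate populations):
#' \itemize{
#'   \item \code{biomass}: census biomass, g;
#'   \item \code{length_above_threshold}: mean length of fish above the
#'     harvest threshold, mm;
#'   \item \code{l50}: length at 50\% maturity from a per-replicate logistic
#'     ogive;
#'   \item \code{observed_mortality}: natural deaths per census interval over
#'     abundance at interval start;
#'   \item \code{total_mortality}: instantaneous natural mortality (week^-1)
#'     from marked-cohort decay (phases with cohort data only);
#'   \item \code{generation_time}: life-table generation time in days, from
#'     cohort survivorship and the configured length-fecundity schedule;
#'   \item \code{haldane_length_mature}: rate of change of mature-fish length
#'     within each harvest phase, haldanes;
#'   \item \code{elasticity}: elasticity of the phenotypic metrics to biomass
#'     across the major transitions.
#' }
#' A metric that cannot be computed for a phase (no cohort data, single
#' maturity class, ...) is reported as \code{NA} and the run continues.
#' Metrics with a baseline phase include a \code{normalized} column
#' (estimate / same-regime baseline estimate).
#'
#' @param logs an \code{experiment_logs} object (from
#'   \code{\link{run_experiment}} or \code{\link{read_experiment_csv}}).
#' @param metrics subset of metric names to compute.
#' @param threshold_mm harvest size threshold used by the length metric.
#' @param boot_seed seed for bootstrap-based estimators inside the summary.
#' @return named list of tidy data.frames, class \code{experiment_summary}.
#' @export
summarize_experiment <- function(logs,
                                 metrics = c("biomass",
                                             "length_above_threshold", "l50",
                                             "observed_mortality",
                                             "total_mortality",
                                             "generation_time",
                                             "haldane_length_mature",
                                             "elasticity"),
                                 threshold_mm = 16, boot_seed = 1L) {
  out <- list()
  cen <- logs$census
  pop <- logs$popsize

  if ("biomass" %in% metrics && nrow(pop) > 0L) {
    per <- summ_per_replicate(pop, function(d) mean(d$biomass_g))
    out$biomass <- normalize_to_baseline(
      agg_mean_se(per, "value", c("regime", "phase")))
  }
  if ("length_above_threshold" %in% metrics && nrow(cen) > 0L) {
    above <- cen[cen$length_mm > threshold_mm, , drop = FALSE]
    per <- summ_per_replicate(above, function(d) mean(d$length_mm))
    out$length_above_threshold <- normalize_to_baseline(
      agg_mean_se(per, "value", c("regime", "phase")))
  }
  if ("l50" %in% metrics && nrow(cen) > 0L) {
    per <- summ_per_replicate(cen, function(d) {
      f <- tryCatch(fit_ogive(d), error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$l50_mm
    })
    out$l50 <- normalize_to_baseline(
      agg_mean_se(per, "value", c("regime", "phase")))
  }
  if ("observed_mortality" %in% metrics && nrow(logs$deaths) > 0L &&
      nrow(pop) > 0L) {
    dl <- logs$deaths
    per <- summ_per_replicate(pop, function(d) {
      d <- d[order(d$week), ]
      if (nrow(d) < 2L) return(NA_real_)
      rates <- vapply(seq_len(nrow(d) - 1L), function(k) {
        dd <- dl[dl$regime == d$regime[1L] & dl$replicate == d$replicate[1L] &
                   dl$week > d$week[k] & dl$week <= d$week[k + 1L], ,
                 drop = FALSE]
        if (d$abundance[k] <= 0) return(NA_real_)
        min(1, nrow(dd) / d$abundance[k])
      }, 0)
      mean(rates, na.rm = TRUE)
    })
    out$observed_mortality <- normalize_to_baseline(
      agg_mean_se(per, "value", c("regime", "phase")))
  }
  if ("total_mortality" %in% metrics && nrow(logs$cohorts) > 0L) {
    co <- logs$cohorts
    sp <- split(co, co[c("regime", "replicate")], drop = TRUE)
    rows <- lapply(sp, function(d) {
      mus <- vapply(split(d, d$cohort), function(tr) {
        tr <- tr[order(tr$cycle), ]
        if (sum(tr$count > 0) < 3L) return(NA_real_)
        est <- tryCatch(
          total_mortality_mark_recapture(tr, n_boot = 50, seed = boot_seed),
          error = function(e) NULL, warning = function(w) NULL)
        if (is.null(est)) NA_real_ else est$mu_week
      }, 0)
      data.frame(regime = d$regime[1L], phase = "harvest1",
                 replicate = d$replicate[1L],
                 value = mean(mus, na.rm = TRUE), stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out$total_mortality <- agg_mean_se(per, "value", c("regime", "phase"))
  }
  if ("generation_time" %in% metrics && nrow(logs$cohorts) > 0L) {
    cfg <- logs$config
    per <- generation_time_from_cohorts(logs$cohorts, cfg)
    out$generation_time <- agg_mean_se(per, "value", c("regime", "phase"))
  }
  if ("haldane_length_mature" %in% metrics && nrow(cen) > 0L) {
    gt_days <- 267
    rows <- list()
    for (ph in intersect(c("harvest1", "harvest2"), unique(cen$phase))) {
      d <- cen[cen$phase == ph & cen$mature, , drop = FALSE]
      for (reg in unique(d$regime)) {
        dr <- d[d$regime == reg, ]
        wks <- sort(unique(dr$week))
        if (length(wks) < 2L) next
        s1 <- dr$length_mm[dr$week == wks[1L]]
        s2 <- dr$length_mm[dr$week == wks[length(wks)]]
        est <- tryCatch(
          haldane_rate(s1, s2, elapsed_weeks = diff(range(wks)),
                       generation_time_days = gt_days, n_boot = 500,
                       seed = boot_seed),
          error = function(e) NULL)
        if (is.null(est)) next
        rows[[length(rows) + 1L]] <- data.frame(
          regime = reg, phase = ph, estimate = est$h, se = est$se,
          ci_lo = est$ci[1L], ci_hi = est$ci[2L], p_value = est$p_value,
          s_p = est$s_p, stringsAsFactors = FALSE)
      }
    }
    out$haldane_length_mature <-
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if ("elasticity" %in% metrics && !is.null(out$biomass)) {
    out$elasticity <- elasticity_table(out, logs)
  }
  structure(out, class = c("experiment_summary", "list"))
}

# Life-table generation time per replicate from marked-cohort survivorship
# (raw counts, i.e. including harvest) and the configured length-fecundity
# schedule evaluated along the configured growth curve.
generation_time_from_cohorts <- function(cohorts, cfg) {
  gp <- cfg$growth_params; fp <- cfg$fecundity_params
  cyc <- cfg$cycle_weeks
  max_x <- 10L
  ages_w <- (0:max_x) * cyc
  w <- predict_biphasic(gp$c, gp$r, gp$alpha,
                        t_mature = 2L * cyc,
                        w0 = length_to_weight(cfg$newborn_length_mm,
                                              gp$a_wl, gp$b_wl),
                        ages = ages_w)
  len <- weight_to_length(w, gp$a_wl, gp$b_wl)
  mx <- ifelse(len > fp$threshold_mm,
               pmax(0, fp$b0 + fp$b1 * (len - fp$threshold_mm)), 0)
  mx[1:2] <- 0  # not yet mature in the first cycles
  sp <- split(cohorts, cohorts[c("regime", "replicate")], drop = TRUE)
  rows <- lapply(sp, function(d) {
    lx <- rep(NA_real_, max_x + 1L)
    lx[1L] <- 1
    surv <- sapply(split(d, d$cohort), function(tr) {
      tr <- tr[order(tr$cycle), ]
      n <- min(nrow(tr), max_x + 1L)
      out <- rep(NA_real_, max_x + 1L)
      out[seq_len(n)] <- tr$count[seq_len(n)] / tr$count[1L]
      out
    })
    if (is.null(dim(surv))) surv <- matrix(surv, ncol = 1L)
    lx_obs <- rowMeans(surv, na.rm = TRUE)
    lx_obs[is.nan(lx_obs)] <- NA_real_
    lx <- ifelse(is.na(lx_obs), 0, pmin(1, lx_obs))
    lx <- cummin(lx)
    gt <- tryCatch(
      generation_time(data.frame(x = 0:max_x, lx = lx, mx = mx), cyc),
      error = function(e) NA_real_)
    data.frame(regime = d$regime[1L], phase = "harvest1",
               replicate = d$replicate[1L], value = gt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Elasticity of each phenotypic metric to biomass across the major
# transitions, per regime.
elasticity_table <- function(out, logs) {
  transitions <- list(
    c("baseline", "harvest1"),
    c("recovery", "harvest2"),
    c("baseline", "harvest2"))
  traits <- intersect(c("length_above_threshold", "l50", "observed_mortality"),
                      names(out))
  bio <- out$biomass
  rows <- list()
  for (trait in traits) {
    tab <- out[[trait]]
    for (tr in transitions) {
      for (reg in unique(tab$regime)) {
        t0 <- tab$estimate[tab$regime == reg & tab$phase == tr[1L]]
        t1 <- tab$estimate[tab$regime == reg & tab$phase == tr[2L]]
        b0 <- bio$estimate[bio$regime == reg & bio$phase == tr[1L]]
        b1 <- bio$estimate[bio$regime == reg & bio$phase == tr[2L]]
        if (length(t0) != 1L || length(t1) != 1L || length(b0) != 1L ||
            length(b1) != 1L || anyNA(c(t0, t1, b0, b1)) || t0 == 0 ||
            b0 == 0) next
        e <- elasticity(t0, t1, b0, b1,
                        transition = paste(tr, collapse = " -> "))
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait, regime = reg, transition = e$transition,
          elasticity = e$elasticity,
          trait_change_rel = e$trait_change_rel,
          biomass_change_rel = e$biomass_change_rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("<experiment_summary> tables:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
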