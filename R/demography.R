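# Demography: directly observed natural mortality, total natural mortality
# from marked-cohort decay, life-table generation time, and elasticity of
# traits to biomass.

#' Directly observed natural mortality over one harvest interval
#'
#' Number of recorded natural deaths during an interval divided by abundance
#' at the start of the interval.
#'
#' @param deaths_in_interval count of natural deaths in the interval.
#' @param abundance_at_start abundance at interval start (> 0).
#' @return mortality rate per interval in [0, 1].
#' @export
observed_mortality <- function(deaths_in_interval, abundance_at_start) {
  if (abundance_at_start <= 0) {
    stop("abundance at interval start must be positive", call. = FALSE)
  }
  if (deaths_in_interval < 0 || deaths_in_interval > abundance_at_start) {
    stop("deaths must be between 0 and the starting abundance", call. = FALSE)
  }
  deaths_in_interval / abundance_at_start
}

#' Total natural mortality from a marked-cohort track
#'
#' Within a marked cohort the count obeys
#' \code{N[t+1] = exp(-mu * dt) * P_hs * N[t]}, where \code{P_hs} is the
#' realized harvest survival of the cohort in that cycle and \code{mu} the
#' instantaneous total natural mortality (week^-1). With a single interval the
#' closed form \code{mu = log(P_hs * N_t / N_t+1) / dt} is returned; with
#' several, \code{mu} is minus the least-squares slope of the
#' harvest-adjusted log counts \code{log(N_t) - cumsum(log(P_hs))} against
#' cumulative weeks (pooled regression, which weights late small-count cycles
#' less than averaging per-interval estimates would). The confidence interval
#' is a seeded nonparametric bootstrap over intervals.
#'
#' @param track data.frame with columns \code{count}, \code{p_hs} and either
#'   \code{dt_weeks} (per-interval) or a constant \code{dt_weeks}; rows are
#'   consecutive cycle boundaries, \code{count} measured before the harvest
#'   whose survival is that row's \code{p_hs}. Rows at and after the first
#'   zero count are dropped.
#' @param n_boot bootstrap resamples for the CI.
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return object of class \code{mortality_estimate}: \code{mu_week},
#'   \code{ci}, \code{se}, \code{method}, \code{n_intervals}.
#' @examples
#' tr <- data.frame(count = c(200, 131), p_hs = c(0.8, 1), dt_weeks = 6)
#' total_mortality_mark_recapture(tr)$mu_week  # log(160/131)/6
#' @export
total_mortality_mark_recapture <- function(track, n_boot = 1000, conf = 0.95,
                                           seed = NULL) {
  stopifnot(all(c("count", "p_hs") %in% names(track)))
  dt <- track$dt_weeks %||% rep(6, nrow(track))
  if (length(dt) == 1L) dt <- rep(dt, nrow(track))
  keep <- which(track$count > 0)
  first_zero <- which(track$count <= 0)[1L]
  if (!is.na(first_zero)) keep <- keep[keep < first_zero]
  track <- track[keep, , drop = FALSE]
  dt <- dt[keep]
  n <- nrow(track)
  if (n < 2L) stop("need >= 2 cycles with positive counts", call. = FALSE)
  used_phs <- track$p_hs[-n]  # the last row's harvest happens after its count
  if (any(used_phs <= 0 | used_phs > 1)) {
    stop("p_hs must be in (0, 1]", call. = FALSE)
  }
  # harvest-adjusted log counts; interval i spans rows i -> i+1 and carries
  # the harvest survival recorded at row i
  y <- log(track$count) - cumsum(c(0, log(track$p_hs[-n])))
  x <- cumsum(c(0, dt[-n]))
  slope <- function(x, y) {
    xm <- x - mean(x); sum(xm * (y - mean(y))) / sum(xm^2)
  }
  mu_hat <- -slope(x, y)
  floored <- FALSE
  if (mu_hat < 0) {
    warning("pooled mortality estimate negative; floored at 0", call. = FALSE)
    mu_hat <- 0
    floored <- TRUE
  }
  # bootstrap over intervals: resample the per-interval decrements
  dy <- diff(y); dts <- dt[-n]
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n - 1L, (n - 1L) * n_boot, replace = TRUE),
                nrow = n_boot)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- idx[b, ]
    xb <- cumsum(c(0, dts[i])); yb <- cumsum(c(0, dy[i]))
    -slope(xb, yb)
  }, 0)
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(a, 1 - a), type = 7))
  if (floored) ci[1] <- min(ci[1], 0)
  structure(list(mu_week = mu_hat, ci = ci, se = stats::sd(boot),
                 method = "mark_recapture", n_intervals = n - 1L,
                 floored = floored),
            class = "mortality_estimate")
}

#' @export
print.mortality_estimate <- function(x, ...) {
  cat(sprintf("<mortality_estimate:%s> mu = %.5f week^-1 [%.5f, %.5f], %d intervals\n",
              x$method, x$mu_week, x$ci[1], x$ci[2], x$n_intervals))
  invisible(x)
}

#' Build a life table
#'
#' @param x age classes in harvest cycles (non-negative, increasing, first 0).
#' @param lx survivorship to age x (l_0 = 1, non-increasing).
#' @param mx fecundity at age x (>= 0; any positive rescaling leaves
#'   generation time unchanged).
#' @return a \code{life_table} data.frame.
#' @export
life_table <- function(x, lx, mx) {
  stopifnot(length(x) == length(lx), length(lx) == length(mx))
  if (x[1L] != 0 || abs(lx[1L] - 1) > 1e-12) {
    stop("life table must start at age class 0 with l_0 = 1", call. = FALSE)
  }
  if (is.unsorted(x, strictly = TRUE)) stop("age classes must increase", call. = FALSE)
  if (any(diff(lx) > 1e-12)) stop("l_x must be non-increasing", call. = FALSE)
  if (any(mx < 0)) stop("m_x must be non-negative", call. = FALSE)
  structure(data.frame(x = x, lx = lx, mx = mx),
            class = c("life_table", "data.frame"))
}

#' Life-table generation time
#'
#' \code{T = sum(x * l_x * m_x) / sum(l_x * m_x)} in harvest cycles (the mean
#' age of mothers at offspring production), converted to days.
#'
#' @param table a \code{\link{life_table}} (or data.frame with columns
#'   \code{x}, \code{lx}, \code{mx}).
#' @param cycle_weeks length of one age class in weeks.
#' @return generation time in days.
#' @examples
#' lt <- life_table(x = 0:2, lx = c(1, 0.5, 0.25), mx = c(0, 2, 2))
#' generation_time(lt, cycle_weeks = 6)  # 56 days
#' @export
generation_time <- function(table, cycle_weeks) {
  stopifnot(all(c("x", "lx", "mx") %in% names(table)))
  R0 <- sum(table$lx * table$mx)
  if (R0 <= 0) stop("zero net reproduction: generation time undefined", call. = FALSE)
  t_cycles <- sum(table$x * table$lx * table$mx) / R0
  t_cycles * cycle_weeks * 7
}

#' Elasticity of a trait to biomass across a transition
#'
#' Proportional change of a trait (relative to its original value) divided by
#' the proportional change of biomass over the same transition.
#'
#' @param trait_before,trait_after trait values (before must be non-zero).
#' @param biomass_before,biomass_after biomass values.
#' @param transition optional label.
#' @return an \code{elasticity_result}: \code{elasticity} (NA when biomass did
#'   not change, with \code{undefined = TRUE}), \code{trait_change_rel},
#'   \code{biomass_change_rel}.
#' @export
elasticity <- function(trait_before, trait_after, biomass_before,
                       biomass_after, transition = NA_character_) {
  if (trait_before == 0) stop("trait_before must be non-zero", call. = FALSE)
  if (biomass_before == 0) stop("biomass_before must be non-zero", call. = FALSE)
  d_trait <- (trait_after - trait_before) / trait_before
  d_bio <- (biomass_after - biomass_before) / biomass_before
  undefined <- d_bio == 0
  structure(list(
    elasticity = if (undefined) NA_real_ else d_trait / d_bio,
    trait_change_rel = d_trait, biomass_change_rel = d_bio,
    undefined = undefined, transition = transition
  ), class = "elasticity_result")
}

#' @export
print.elasticity_result <- function(x, ...) {
  if (x$undefined) {
    cat("<elasticity_result> undefined (biomass unchanged)\n")
  } else {
    cat(sprintf("<elasticity_result> %.4g (trait %+.2f%%, biomass %+.2f%%)\n",
                x$elasticity, 100 * x$trait_change_rel,
                100 * x$biomass_change_rel))
  }
  invisible(x)
}

#' Population-level harvest fraction implied by a regime
#'
#' Expected removed fraction of the whole population when a per-size-class
#' proportion P is harvested under the given regime. With equal abundance
#' above and below the threshold, both size-dependent regimes remove P/2 of
#' the population, matching the random regime's nominal intensity.
#'
#' @param P per-size-class harvest proportion.
#' @param regime \code{"positive"}, \code{"negative"} or \code{"random"}.
#' @param n_above,n_below abundances above and at-or-below the threshold.
#' @return expected removed fraction of the whole population.
#' @examples
#' population_harvest_fraction(0.60, "positive", 500, 500)  # 0.30
#' population_harvest_fraction(0.25, "positive", 500, 500)  # 0.125
#' @export
population_harvest_fraction <- function(P, regime = c("positive", "negative",
                                                      "random"),
                                        n_above, n_below) {
  regime <- match.arg(regime)
  stopifnot(P >= 0, P <= 1, n_above >= 0, n_below >= 0)
  n <- n_above + n_below
  if (n == 0) stop("population is empty", call. = FALSE)
  removed <- switch(regime,
                    positive = P * n_above,
                    negative = P * n_below,
                    random = (P / 2) * n)
  removed / n
}
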