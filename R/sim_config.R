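#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the
#' individual-based simulator. Defaults describe the experimental system the
#' package emulates: 400-l guppy populations founded with 140 fish at an even
#' sex ratio, harvested every 6 weeks at a 16 mm standard-length threshold
#' with per-size-class intensity P (0.25--0.60, long-run mean 0.40), censused
#' at 25\% per harvest event, with food rationed so that growth is
#' density-dependent.
#'
#' @param regime harvest regime: \code{"positive"} (remove fish strictly above
#'   the threshold), \code{"negative"} (at or below), or \code{"random"}
#'   (irrespective of size, at intensity P/2).
#' @param harvest_proportion_P per-size-class harvest intensity in [0, 1].
#' @param size_threshold_mm harvest size threshold, mm standard length.
#' @param cycle_weeks weeks between harvest events.
#' @param census_fraction fraction of the population measured at each census.
#' @param n_initial founding population size.
#' @param mu_nat_week instantaneous natural mortality, week^-1. The default is
#'   the level observed in the source system's non-positively-harvested lines.
#' @param growth_params named list: \code{c} (energy-acquisition coefficient,
#'   g^(1-alpha) week^-1), \code{r} (relative reproductive investment),
#'   \code{alpha} (acquisition exponent), \code{a_wl}, \code{b_wl}
#'   (weight-length allometry, log g at 16 mm and exponent).
#' @param maturation_params named list: \code{lp50_mm} (length at 50\%
#'   probability of becoming mature in one weekly trial), \code{slope}
#'   (logistic slope per mm), \code{mode} either \code{"stochastic"} (weekly
#'   Bernoulli trial) or \code{"deterministic"} (mature at first crossing of
#'   \code{lp50_mm}; used by estimator oracles).
#' @param fecundity_params named list: \code{b0}, \code{b1} (brood size =
#'   max(0, round(b0 + b1 * (L - 13))) above the 13 mm fecundity threshold),
#'   \code{brood_interval_weeks}, \code{threshold_mm}.
#' @param newborn_length_mm length at birth, mm.
#' @param food_ration weekly ration in biomass-equivalent g; the per-capita
#'   intake factor is \code{min(food_factor_max, (food_ration / biomass) ^
#'   gamma_growth)} and scales the growth increment; mortality is scaled by
#'   \code{(biomass / food_ration) ^ gamma_mort} (default exponent 0, i.e.
#'   density-independent mortality).
#' @param gamma_growth,gamma_mort density-dependence exponents.
#' @param food_factor_max cap on the growth food factor (prevents unbounded
#'   growth at very low density).
#' @param init_age_max_weeks founding fish ages are uniform on
#'   0..init_age_max_weeks; lengths follow from the growth model.
#' @param seed RNG seed for this replicate.
#' @return object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- sim_config(regime = "positive", seed = 1)
#' cfg$harvest_proportion_P
#' @export
sim_config <- function(regime = c("positive", "negative", "random"),
                       harvest_proportion_P = 0.4,
                       size_threshold_mm = 16,
                       cycle_weeks = 6L,
                       census_fraction = 0.25,
                       n_initial = 140L,
                       mu_nat_week = 0.0424,
                       growth_params = list(),
                       maturation_params = list(),
                       fecundity_params = list(),
                       newborn_length_mm = 7,
                       food_ration = 60,
                       gamma_growth = 1,
                       gamma_mort = 0,
                       food_factor_max = 2,
                       init_age_max_weeks = 20L,
                       seed = NULL) {
  regime <- match.arg(regime)
  gp <- utils::modifyList(
    list(c = 0.03, r = 0.5, alpha = 2 / 3, a_wl = log(0.041), b_wl = 3),
    growth_params)
  mp <- utils::modifyList(
    list(lp50_mm = 16, slope = 1.5, mode = "stochastic"),
    maturation_params)
  fp <- utils::modifyList(
    list(b0 = 0.5, b1 = 0.4, brood_interval_weeks = 6L, threshold_mm = 13),
    fecundity_params)

  check_number(harvest_proportion_P, "harvest_proportion_P", 0, 1)
  check_number(size_threshold_mm, "size_threshold_mm", 0)
  check_number(cycle_weeks, "cycle_weeks", 1)
  check_number(census_fraction, "census_fraction")
  if (census_fraction <= 0 || census_fraction > 1) {
    stop_config("census_fraction", "must be in (0, 1]")
  }
  check_number(n_initial, "n_initial", 0)
  check_number(mu_nat_week, "mu_nat_week", 0)
  check_number(gp$c, "growth_params$c", 0)
  check_number(gp$r, "growth_params$r", 0)
  check_number(gp$alpha, "growth_params$alpha", 0, 1)
  check_number(gp$b_wl, "growth_params$b_wl", 0.1)
  check_number(mp$lp50_mm, "maturation_params$lp50_mm", 0)
  check_number(mp$slope, "maturation_params$slope", 0)
  if (!mp$mode %in% c("stochastic", "deterministic")) {
    stop_config("maturation_params$mode",
                "must be 'stochastic' or 'deterministic'")
  }
  check_number(fp$brood_interval_weeks, "fecundity_params$brood_interval_weeks", 1)
  check_number(newborn_length_mm, "newborn_length_mm", 0.1)
  check_number(food_ration, "food_ration", 0)
  check_number(food_factor_max, "food_factor_max", 1)
  if (!is.null(seed)) check_number(seed, "seed")

  structure(list(
    regime = regime,
    harvest_proportion_P = harvest_proportion_P,
    size_threshold_mm = size_threshold_mm,
    cycle_weeks = as.integer(cycle_weeks),
    census_fraction = census_fraction,
    n_initial = as.integer(n_initial),
    mu_nat_week = mu_nat_week,
    growth_params = gp,
    maturation_params = mp,
    fecundity_params = fp,
    newborn_length_mm = newborn_length_mm,
    food_ration = food_ration,
    gamma_growth = gamma_growth,
    gamma_mort = gamma_mort,
    food_factor_max = food_factor_max,
    init_age_max_weeks = as.integer(init_age_max_weeks),
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  regime: %s  P: %.2f  threshold: %g mm  cycle: %d wk\n",
              x$regime, x$harvest_proportion_P, x$size_threshold_mm,
              x$cycle_weeks))
  cat(sprintf("  n_initial: %d  census: %.0f%%  mu_nat: %.4f /wk\n",
              x$n_initial, 100 * x$census_fraction, x$mu_nat_week))
  cat(sprintf("  growth: c=%.3g r=%.3g alpha=%.3g; maturation: Lp50=%.1f mm (%s)\n",
              x$growth_params$c, x$growth_params$r, x$growth_params$alpha,
              x$maturation_params$lp50_mm, x$maturation_params$mode))
  invisible(x)
}
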