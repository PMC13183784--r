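# Maturity ogives and maturation reaction norms.
#
# Both the probability of being mature at a given length (ogive, midpoint
# L50) and the probability of becoming mature in an observation interval
# (reaction norm, midpoint Lp50) are fitted as maximum-likelihood logistic
# regressions on length. Quantile lengths come from the closed-form logit
# inversion L_p = (logit(p) - intercept) / slope.

new_ogive_fit <- function(intercept, slope, n_obs, vcov = NULL,
                          separated = FALSE, group_coefs = NULL,
                          model = NULL, kind = "ogive") {
  l_at <- function(p) {
    if (is.infinite(slope)) return(attr(separated, "threshold") %||% NA_real_)
    (stats::qlogis(p) - intercept) / slope
  }
  structure(list(intercept = intercept, slope = slope,
                 l25_mm = l_at(0.25), l50_mm = l_at(0.5), l75_mm = l_at(0.75),
                 n_obs = n_obs, vcov = vcov, separated = isTRUE(separated),
                 group_coefs = group_coefs, model = model, kind = kind),
            class = "ogive_fit")
}

#' @export
print.ogive_fit <- function(x, ...) {
  lab <- if (x$kind == "pmrn") "Lp50" else "L50"
  cat(sprintf("<ogive_fit:%s> n = %d%s\n", x$kind, x$n_obs,
              if (x$separated) " [complete separation]" else ""))
  cat(sprintf("  intercept = %.4g, slope = %.4g per mm\n", x$intercept, x$slope))
  cat(sprintf("  %s = %.3f mm (L25 = %.3f, L75 = %.3f)\n", lab,
              x$l50_mm, x$l25_mm, x$l75_mm))
  invisible(x)
}

# Shared logistic fitting with complete-separation handling. `y` is the
# binary response, `length_mm` the covariate, `group` an optional factor and
# `age_weeks` an optional extra covariate.
fit_logistic_length <- function(length_mm, y, group = NULL, age_weeks = NULL,
                                kind = "ogive") {
  ok <- stats::complete.cases(length_mm, y)
  length_mm <- length_mm[ok]; y <- as.logical(y[ok])
  if (!is.null(group)) group <- factor(group[ok])
  if (!is.null(age_weeks)) age_weeks <- age_weeks[ok]
  n <- length(y)
  if (n < 2L || length(unique(length_mm)) < 2L) {
    stop("need at least 2 observations at distinct lengths", call. = FALSE)
  }
  if (all(y) || !any(y)) {
    stop("both maturity classes must be present", call. = FALSE)
  }
  # complete separation in length: every immature fish shorter than every
  # mature fish. Deterministic maturation rules produce this by design, so it
  # is reported (flagged, infinite slope, threshold midpoint) rather than
  # failed.
  if (is.null(group) && max(length_mm[!y]) < min(length_mm[y])) {
    thr <- (max(length_mm[!y]) + min(length_mm[y])) / 2
    sep <- TRUE; attr(sep, "threshold") <- thr
    return(new_ogive_fit(intercept = -Inf, slope = Inf, n_obs = n,
                         separated = sep, kind = kind))
  }
  dat <- data.frame(y = y, length_mm = length_mm)
  form <- y ~ length_mm
  if (!is.null(age_weeks)) {
    dat$age_weeks <- age_weeks
    form <- stats::update(form, . ~ . + age_weeks)
  }
  if (!is.null(group)) {
    dat$group <- group
    form <- stats::update(form, . ~ . + group)
  }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat))
  cf <- stats::coef(fit)
  group_coefs <- NULL
  if (!is.null(group)) {
    idx <- grep("^group", names(cf))
    group_coefs <- list(levels = levels(group), coefs = cf[idx],
                        vcov = stats::vcov(fit))
  }
  new_ogive_fit(intercept = unname(cf["(Intercept)"]),
                slope = unname(cf["length_mm"]),
                n_obs = n, vcov = stats::vcov(fit)[1:2, 1:2],
                separated = abs(cf["length_mm"]) > 50,
                group_coefs = group_coefs, model = fit, kind = kind)
}

#' Fit a maturity ogive (L50)
#'
#' Logistic regression of maturity status on standard length. The length at
#' which the fitted probability of being mature is p is
#' \code{(logit(p) - intercept)/slope}; L50 is reported together with L25 and
#' L75.
#'
#' @param records data.frame with columns \code{length_mm} and \code{mature}
#'   (logical or 0/1), e.g. census records from the simulator.
#' @param group optional grouping factor (harvest regime, phase, ...) added as
#'   a fixed effect; enables \code{\link{odds_ratio_contrast}}.
#' @return an \code{ogive_fit}: coefficients, their covariance, quantile
#'   lengths, and a \code{separated} flag (complete separation yields an
#'   infinite-slope fit whose quantiles equal the separating threshold).
#' @examples
#' set.seed(1)
#' len <- runif(500, 10, 25)
#' rec <- data.frame(length_mm = len,
#'                   mature = runif(500) < plogis(1.5 * (len - 16)))
#' fit_ogive(rec)$l50_mm
#' @export
fit_ogive <- function(records, group = NULL) {
  stopifnot(all(c("length_mm", "mature") %in% names(records)))
  fit_logistic_length(records$length_mm, records$mature, group = group,
                      kind = "ogive")
}

#' Fit a becoming-mature schedule (Lp50, probabilistic maturation reaction norm)
#'
#' Logistic regression of first-maturation events on length, restricted to
#' fish that were immature at the start of each observation interval. Lp50 is
#' the length at which the probability of becoming mature in one interval is
#' 50\%; unlike L50 it is unaffected by growth after maturation.
#'
#' @param records data.frame with columns \code{length_mm} and
#'   \code{became_mature} (plus optionally \code{age_weeks}); one row per
#'   immature-at-start fish per interval.
#' @param include_age add age in weeks as a covariate.
#' @return an \code{ogive_fit} with \code{kind = "pmrn"}; \code{l50_mm} is
#'   Lp50 (at the mean age when \code{include_age} is TRUE).
#' @export
fit_becoming_mature <- function(records, include_age = FALSE) {
  stopifnot(all(c("length_mm", "became_mature") %in% names(records)))
  age <- if (include_age) records$age_weeks else NULL
  fit <- fit_logistic_length(records$length_mm, records$became_mature,
                             age_weeks = age, kind = "pmrn")
  if (include_age && !fit$separated) {
    # report Lp50 at the mean observed age
    cf <- stats::coef(fit$model)
    fit$l50_mm <- -(cf["(Intercept)"] + cf["age_weeks"] * mean(records$age_weeks, na.rm = TRUE)) /
      cf["length_mm"]
    fit$l50_mm <- unname(fit$l50_mm)
  }
  fit
}

#' Odds-ratio contrast between groups of a grouped ogive fit
#'
#' For a fit produced with a \code{group} factor, returns the odds ratio of
#' being (or becoming) mature in group \code{groups[1]} relative to
#' \code{groups[2]} at equal length, with a Wald confidence interval.
#'
#' @param fit an \code{ogive_fit} fitted with a group factor.
#' @param groups character vector of two group levels.
#' @param conf confidence level.
#' @return list with \code{or}, \code{ci} (length 2), \code{se_log}.
#' @export
odds_ratio_contrast <- function(fit, groups, conf = 0.95) {
  stopifnot(inherits(fit, "ogive_fit"), length(groups) == 2L)
  gc <- fit$group_coefs
  if (is.null(gc)) stop("fit has no group terms", call. = FALSE)
  if (!all(groups %in% gc$levels)) {
    stop("groups absent from fit: ",
         paste(setdiff(groups, gc$levels), collapse = ", "), call. = FALSE)
  }
  coef_of <- function(g) {
    nm <- paste0("group", g)
    if (nm %in% names(gc$coefs)) unname(gc$coefs[nm]) else 0  # reference level
  }
  var_of <- function(g1, g2) {
    nm1 <- paste0("group", g1); nm2 <- paste0("group", g2)
    v <- gc$vcov
    get <- function(a, b) if (a %in% rownames(v) && b %in% colnames(v)) v[a, b] else 0
    get(nm1, nm1) + get(nm2, nm2) - 2 * get(nm1, nm2)
  }
  delta <- coef_of(groups[1]) - coef_of(groups[2])
  se <- sqrt(var_of(groups[1], groups[2]))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = exp(delta), ci = exp(delta + c(-1, 1) * z * se), se_log = se)
}
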