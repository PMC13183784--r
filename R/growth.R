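# Biphasic growth: full energy allocation to soma before maturation, a
# fraction 1/(1+r) of the surplus after it. The canonical forward map is the
# discrete weekly recursion on weight
#
#   juvenile (t < t_mature):  w <- w + c * w^alpha
#   adult    (t >= t_mature): w <- w + c * w^alpha / (1 + r)
#
# with c the size-independent energy-acquisition coefficient
# (g^(1-alpha) week^-1) and r the relative reproductive investment. Lengths
# are mapped through the log-log weight-length allometry (reference 16 mm);
# alpha and the allometry are fixed inputs estimated separately, never
# co-estimated with (c, r).

#' Forward-simulate the biphasic growth model
#'
#' @param c energy-acquisition coefficient, g^(1-alpha) week^-1.
#' @param r relative reproductive investment (>= 0); r = 0 collapses the
#'   adult phase onto the juvenile recursion.
#' @param alpha allometric exponent of energy acquisition.
#' @param t_mature age at maturation in weeks; increments at ages
#'   \code{t >= t_mature} are discounted by \code{1/(1+r)}.
#' @param w0 weight at age 0, g.
#' @param ages sorted non-negative integer ages (weeks) at which to report.
#' @return numeric vector of weights (g) at \code{ages}.
#' @examples
#' predict_biphasic(c = 0.1, r = 1, alpha = 0, t_mature = 10, w0 = 1,
#'                  ages = c(10, 12))  # 2.0, 2.1
#' @export
predict_biphasic <- function(c, r, alpha, t_mature, w0, ages) {
  if (!is.numeric(w0) || length(w0) != 1L || is.na(w0) || w0 <= 0) {
    stop("w0 must be a positive weight", call. = FALSE)
  }
  stopifnot(c >= 0, r >= 0, alpha >= 0, all(ages >= 0), !is.unsorted(ages))
  max_age <- max(ages)
  w <- numeric(max_age + 1L)
  w[1L] <- w0
  if (max_age > 0L) {
    for (t in seq_len(max_age)) {
      inc <- c * w[t]^alpha
      if ((t - 1) >= t_mature) inc <- inc / (1 + r)
      w[t + 1L] <- w[t] + inc
    }
  }
  w[ages + 1L]
}

new_growth_fit <- function(c, r, alpha, a_wl, b_wl, rss, n_obs, convergence) {
  structure(list(c = c, r = r, alpha = alpha, a_wl = a_wl, b_wl = b_wl,
                 rss = rss, n_obs = n_obs, convergence = convergence),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> c = %.5g, r = %.5g (alpha = %.3g fixed)\n",
              x$c, x$r, x$alpha))
  cat(sprintf("  RSS = %.5g over %d observations\n", x$rss, x$n_obs))
  invisible(x)
}

#' Fit the biphasic growth model to longitudinal length-at-age data
#'
#' Nonlinear least squares over (c, r), minimising squared residuals of
#' observed versus predicted standard lengths. Each individual's trajectory is
#' anchored at its first observation (converted to weight through the fixed
#' allometry) and simulated forward with its own age at maturation. A
#' multi-start over a 5 x 5 log-spaced (c, r) grid guards against local
#' minima; the best start is polished with bounded L-BFGS-B at 1e-8 parameter
#' tolerance.
#'
#' @param trajectories data.frame with columns \code{id}, \code{age_weeks}
#'   (non-negative integers), \code{length_mm}.
#' @param alpha fixed acquisition exponent.
#' @param allometry named vector or list with \code{a_wl}, \code{b_wl}.
#' @param t_mature named vector: age at maturation (weeks) per individual id;
#'   taken from observed maturation records, not estimated.
#' @param c_grid,r_grid multi-start grids (log-spaced defaults).
#' @return a \code{growth_fit} with elements \code{c}, \code{r}, \code{rss},
#'   \code{n_obs}.
#' @export
fit_biphasic <- function(trajectories, alpha, allometry, t_mature,
                         c_grid = exp(seq(log(0.005), log(0.3), length.out = 5)),
                         r_grid = exp(seq(log(0.05), log(5), length.out = 5))) {
  stopifnot(all(c("id", "age_weeks", "length_mm") %in% names(trajectories)))
  a_wl <- allometry[["a_wl"]]; b_wl <- allometry[["b_wl"]]
  ids <- unique(trajectories$id)
  if (length(ids) < 2L || nrow(trajectories) < 4L) {
    stop("need >= 2 individuals and >= 4 observations", call. = FALSE)
  }
  if (!all(as.character(ids) %in% names(t_mature))) {
    stop("t_mature must be named with every individual id", call. = FALSE)
  }
  # per-individual prepared data: anchor weight, relative ages, observed lengths
  per_id <- lapply(ids, function(i) {
    tr <- trajectories[trajectories$id == i, , drop = FALSE]
    tr <- tr[order(tr$age_weeks), , drop = FALSE]
    a0 <- tr$age_weeks[1L]
    list(w0 = length_to_weight(tr$length_mm[1L], a_wl, b_wl),
         rel_ages = tr$age_weeks - a0,
         t_mat_rel = t_mature[[as.character(i)]] - a0,
         obs = tr$length_mm)
  })
  n_adult <- sum(vapply(per_id, function(d) sum(d$rel_ages >= d$t_mat_rel), 0))
  if (n_adult == 0L) {
    stop(paste("no adult-phase observations: r is unidentifiable;",
               "fit c alone on juvenile data"), call. = FALSE)
  }
  objective <- function(par) {
    cc <- par[1L]; rr <- par[2L]
    if (cc < 0 || rr < 0) return(1e12)
    rss <- 0
    for (d in per_id) {
      w <- predict_biphasic(cc, rr, alpha, d$t_mat_rel, d$w0, d$rel_ages)
      rss <- rss + sum((weight_to_length(w, a_wl, b_wl) - d$obs)^2)
    }
    rss
  }
  starts <- expand.grid(c = c_grid, r = r_grid)
  vals <- apply(starts, 1L, objective)
  best <- NULL
  for (i in order(vals)[seq_len(min(3L, nrow(starts)))] ) {
    o <- stats::optim(as.numeric(starts[i, ]), objective, method = "L-BFGS-B",
                      lower = c(1e-8, 0), upper = c(10, 100),
                      control = list(factr = 1, pgtol = 1e-14, maxit = 1000,
                                     ndeps = c(1e-7, 1e-7)))
    if (is.null(best) || o$value < best$value) best <- o
  }
  new_growth_fit(c = best$par[1L], r = best$par[2L], alpha = alpha,
                 a_wl = a_wl, b_wl = b_wl, rss = best$value,
                 n_obs = nrow(trajectories), convergence = best$convergence)
}

#' Fit the weight-length allometry
#'
#' Ordinary least squares of \code{log(weight)} on \code{log(length/16)}:
#' the intercept \code{a_wl} is the log weight of a 16 mm fish and
#' \code{b_wl} the allometric exponent.
#'
#' @param pairs data.frame with columns \code{length_mm}, \code{weight_g},
#'   all positive.
#' @return list with \code{a_wl}, \code{b_wl}, \code{vcov} (2 x 2),
#'   \code{sigma} (residual SD of log weight), \code{n_obs}.
#' @export
fit_weight_length <- function(pairs) {
  stopifnot(all(c("length_mm", "weight_g") %in% names(pairs)))
  if (nrow(pairs) < 3L) stop("need >= 3 length-weight pairs", call. = FALSE)
  if (any(pairs$length_mm <= 0) || any(pairs$weight_g <= 0)) {
    stop("lengths and weights must be positive", call. = FALSE)
  }
  x <- log(pairs$length_mm / 16)
  if (length(unique(x)) < 2L) {
    stop("all lengths equal: allometric exponent unidentifiable", call. = FALSE)
  }
  fit <- stats::lm(log(pairs$weight_g) ~ x)
  cf <- stats::coef(fit)
  # summary.lm warns on numerically perfect fits (legitimate here: exact
  # power-law data); the coefficients and vcov are still what we want
  sm <- suppressWarnings(summary(fit))
  vc <- sm$sigma^2 * sm$cov.unscaled
  list(a_wl = unname(cf[1L]), b_wl = unname(cf[2L]),
       vcov = vc, sigma = sm$sigma, n_obs = nrow(pairs))
}
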