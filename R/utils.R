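# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used for all integer event counts (harvest takes,
#' census sample sizes, brood sizes). Base \code{round()} rounds half to even,
#' which makes expected counts depend on parity; half-up is the convention
#' adopted throughout this package.
#'
#' @param x numeric vector.
#' @return integer vector, \code{floor(x + 0.5)} for non-negative \code{x}.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_config(field, "must be supplied")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop_config(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(NULL)
}

#' Convert weight to standard length through the log-log allometry
#'
#' The allometry is parameterised as
#' \code{log(w) = a_wl + b_wl * log(L / 16)}, i.e. the intercept is the log
#' weight of a fish at the 16 mm reference length.
#'
#' @param w weight in g.
#' @param a_wl log-scale intercept (log g at 16 mm).
#' @param b_wl allometric exponent.
#' @return standard length in mm.
#' @export
weight_to_length <- function(w, a_wl, b_wl) {
  16 * (w / exp(a_wl))^(1 / b_wl)
}

#' @rdname weight_to_length
#' @param l standard length in mm.
#' @export
length_to_weight <- function(l, a_wl, b_wl) {
  exp(a_wl) * (l / 16)^b_wl
}

# Sample k elements without replacement; stable for length-1 x (unlike
# base sample()'s scalar surprise).
sample_ids <- function(x, k) {
  if (k <= 0L) return(x[0])
  x[sample.int(length(x), k)]
}
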