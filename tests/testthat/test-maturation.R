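# Logistic simulator for ogive data: maturity ~ Bernoulli(plogis(b0 + b1 L)).
sim_ogive_data <- function(n, l50, slope, lmin = 10, lmax = 25) {
  len <- runif(n, lmin, lmax)
  data.frame(length_mm = len,
             mature = runif(n) < plogis(slope * (len - l50)))
}

# delta-method SE of l50 = -intercept/slope from an ogive_fit
l50_se <- function(fit) {
  g <- c(-1 / fit$slope, fit$intercept / fit$slope^2)
  sqrt(drop(t(g) %*% fit$vcov %*% g))
}

test_that("fit_ogive recovers generating parameters and quantile geometry", {
  set.seed(101)
  rec <- sim_ogive_data(5000, l50 = 18, slope = 1.5)
  fit <- fit_ogive(rec)
  expect_s3_class(fit, "ogive_fit")
  expect_false(fit$separated)
  expect_lt(abs(fit$l50_mm - 18), 3 * l50_se(fit))
  # quantile ordering and the defining identity p(l50) = 0.5
  expect_lt(fit$l25_mm, fit$l50_mm)
  expect_lt(fit$l50_mm, fit$l75_mm)
  expect_equal(plogis(fit$intercept + fit$slope * fit$l50_mm), 0.5,
               tolerance = 1e-12)
  # closed-form inversion: l25/l75 sit ln(3)/slope either side of l50
  expect_equal(fit$l50_mm - fit$l25_mm, log(3) / fit$slope, tolerance = 1e-12)
  expect_equal(fit$l75_mm - fit$l50_mm, log(3) / fit$slope, tolerance = 1e-12)
})

test_that("degenerate ogive inputs error", {
  expect_error(fit_ogive(data.frame(length_mm = c(10, 20),
                                    mature = c(TRUE, TRUE))),
               "both maturity classes")
  expect_error(fit_ogive(data.frame(length_mm = c(10, 10),
                                    mature = c(TRUE, FALSE))),
               "distinct lengths")
  expect_error(fit_ogive(data.frame(length_mm = 15, mature = TRUE)),
               "at least 2")
})

test_that("complete separation is flagged, with the threshold as quantile", {
  rec <- data.frame(length_mm = c(seq(10, 17.8, 0.2), seq(18.2, 25, 0.2)),
                    mature = c(seq(10, 17.8, 0.2) > 18,
                               seq(18.2, 25, 0.2) > 18))
  fit <- fit_ogive(rec)
  expect_true(fit$separated)
  expect_true(is.infinite(fit$slope))
  expect_equal(fit$l50_mm, 18)
  expect_equal(fit$l25_mm, fit$l75_mm)
})

test_that("L50 is invariant to recentring the length covariate", {
  set.seed(55)
  rec <- sim_ogive_data(2000, l50 = 17, slope = 1.2)
  f1 <- fit_ogive(rec)
  rec2 <- rec
  rec2$length_mm <- rec$length_mm - 16
  f2 <- fit_ogive(rec2)
  expect_equal(f1$l50_mm, f2$l50_mm + 16, tolerance = 1e-8)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-8)
})

test_that("l50 estimator error shrinks as n grows", {
  set.seed(77)
  rmse <- vapply(c(200, 2000, 20000), function(n) {
    err <- vapply(1:20, function(i) {
      fit_ogive(sim_ogive_data(n, l50 = 18, slope = 1.5))$l50_mm - 18
    }, 0)
    sqrt(mean(err^2))
  }, 0)
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[3], rmse[2])
  expect_lt(rmse[3], 0.1)
})

test_that("fit_becoming_mature estimates Lp50 from first-maturation events", {
  # stochastic becoming-mature trials around a true Lp50 of 18, slope 2
  set.seed(31)
  len <- runif(5000, 12, 24)
  rec <- data.frame(length_mm = len, age_weeks = round(len),
                    became_mature = runif(5000) < plogis(2 * (len - 18)))
  fit <- fit_becoming_mature(rec)
  expect_identical(fit$kind, "pmrn")
  expect_lt(abs(fit$l50_mm - 18), 3 * l50_se(fit))

  # deterministic simulator rule: separation by design
  det <- data.frame(length_mm = len, became_mature = len >= 18)
  fdet <- fit_becoming_mature(det)
  expect_true(fdet$separated)
  expect_equal(fdet$l50_mm, 18, tolerance = 0.01)

  expect_error(
    fit_becoming_mature(data.frame(length_mm = len,
                                   became_mature = rep(FALSE, 5000))),
    "both maturity classes")
})

test_that("age covariate is accepted for the reaction norm", {
  set.seed(32)
  len <- runif(4000, 12, 24)
  age <- round(runif(4000, 8, 40))
  p <- plogis(2 * (len - 18) + 0.02 * (age - 24))
  rec <- data.frame(length_mm = len, age_weeks = age,
                    became_mature = runif(4000) < p)
  fit <- fit_becoming_mature(rec, include_age = TRUE)
  expect_lt(abs(fit$l50_mm - 18), 0.5)
})

test_that("odds_ratio_contrast computes Wald odds ratios between groups", {
  set.seed(43)
  len <- runif(4000, 10, 25)
  grp <- rep(c("pos", "neg"), each = 2000)
  eta <- 1.2 * (len - 17) + ifelse(grp == "pos", log(3), 0)
  rec <- data.frame(length_mm = len, mature = runif(4000) < plogis(eta))
  fit <- fit_ogive(rec, group = grp)
  same <- odds_ratio_contrast(fit, c("pos", "pos"))
  expect_equal(same$or, 1.0)
  out <- odds_ratio_contrast(fit, c("pos", "neg"))
  expect_gt(out$ci[2], out$ci[1])
  expect_true(out$ci[1] < 3 && 3 < out$ci[2])
  expect_error(odds_ratio_contrast(fit, c("pos", "zebra")), "absent")
  expect_error(odds_ratio_contrast(fit_ogive(rec), c("a", "b")),
               "no group terms")
})

test_that("odds-ratio CI coverage is near nominal (true OR 5, n = 4000)", {
  set.seed(61)
  cover <- vapply(1:300, function(i) {
    len <- runif(4000, 10, 25)
    grp <- rep(c("a", "b"), each = 2000)
    eta <- 1.2 * (len - 17) + ifelse(grp == "a", log(5), 0)
    rec <- data.frame(length_mm = len, mature = runif(4000) < plogis(eta))
    ci <- odds_ratio_contrast(fit_ogive(rec, group = grp), c("a", "b"))$ci
    ci[1] <= 5 && 5 <= ci[2]
  }, NA)
  expect_gte(mean(cover), 0.93)
})
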