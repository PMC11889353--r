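test_that("Wald ratios follow the first-order formula", {
  r <- wald_ratio(0.5, 0.25, 0.1)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$se, 0.2)
  r2 <- wald_ratio(-0.5, 0.25, 0.1)
  expect_equal(r2$ratio, -0.5)
  expect_equal(r2$se, 0.2)
  r3 <- wald_ratio(1.0, 0.0, 0.1)
  expect_equal(r3$ratio, 0)
  expect_equal(r3$se, 0.1)
  expect_error(wald_ratio(0, 0.1, 0.1), "undefined")
})

test_that("IVW matches hand arithmetic and reduces to the Wald ratio", {
  fit <- mr_ivw(c(1, 2), c(0.3, 0.6), c(1, 1))
  expect_equal(fit$theta_hat, 0.3)
  expect_equal(fit$se, 1 / sqrt(5))
  expect_equal(unname(coef(fit)), 0.3)
  expect_equal(fit$pvalue, 2 * pnorm(-abs(0.3 * sqrt(5))))

  w <- wald_ratio(0.4, 0.1, 0.05)
  f1 <- mr_ivw(0.4, 0.1, 0.05)
  expect_equal(f1$theta_hat, w$ratio)
  expect_equal(f1$se, w$se)
  expect_equal(f1$n_iv, 1L)
})

test_that("IVW equals the weighted-regression-through-origin oracle", {
  set.seed(301)
  for (i in 1:200) {
    k <- sample(2:8, 1)  # k = 1 has no residual df for the lm oracle;
                         # the single-IV case is checked against wald_ratio
    bx <- runif(k, 0.5, 2) * sample(c(-1, 1), k, replace = TRUE)
    by <- 0.3 * bx + rnorm(k, 0, 0.2)
    sy <- runif(k, 0.05, 0.5)
    fit <- mr_ivw(bx, by, sy)
    o <- wls_origin_oracle(bx, by, sy)
    expect_equal(fit$theta_hat, o$theta, tolerance = 1e-10)
    expect_equal(fit$se, o$se, tolerance = 1e-10)
  }
})

test_that("IVW is scale-equivariant and meta-analytically consistent", {
  set.seed(302)
  bx <- runif(5, 0.5, 2); by <- rnorm(5); sy <- runif(5, 0.1, 0.4)
  fit <- mr_ivw(bx, by, sy)
  c_ <- 3.7
  fy <- mr_ivw(bx, c_ * by, c_ * sy)
  expect_equal(fy$theta_hat, c_ * fit$theta_hat, tolerance = 1e-12)
  expect_equal(fy$se, c_ * fit$se, tolerance = 1e-12)
  fx <- mr_ivw(c_ * bx, by, sy)
  expect_equal(fx$theta_hat, fit$theta_hat / c_, tolerance = 1e-12)

  # duplicating every instrument = halving each variance once
  fdup <- mr_ivw(rep(bx, 2), rep(by, 2), rep(sy, 2))
  fhalf <- mr_ivw(bx, by, sy / sqrt(2))
  expect_equal(fdup$theta_hat, fhalf$theta_hat, tolerance = 1e-12)
  expect_equal(fdup$se, fhalf$se, tolerance = 1e-12)
})

test_that("degenerate IVW inputs are handled explicitly", {
  f0 <- mr_ivw(numeric(), numeric(), numeric())
  expect_true(f0$no_instruments)
  expect_equal(f0$n_iv, 0L)
  expect_true(is.na(f0$pvalue))
  expect_false(mr_decide(f0))
  expect_error(mr_ivw(c(1, 0), c(0.1, 0.2), c(0.1, 0.1)), "zero exposure")
  expect_error(mr_ivw(1, 0.1, 0), "positive")
  # configurable instrument floor
  f2 <- mr_ivw(1, 0.1, 0.1, min_iv = 3)
  expect_true(f2$no_instruments)
})

test_that("mr_ivw methods behave like a fitted model object", {
  fit <- mr_ivw(c(1, 2, 1.5), c(0.29, 0.61, 0.44), c(0.1, 0.1, 0.12))
  expect_output(print(fit), "theta_hat")
  expect_output(print(summary(fit)), "CI")
  ci <- confint(fit)
  expect_lt(ci[1], fit$theta_hat)
  expect_gt(ci[2], fit$theta_hat)
  expect_equal(unname(vcov(fit)[1, 1]), fit$se^2)
})

test_that("BH adjustment matches hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(303)
  p <- runif(100)^2
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
})

test_that("decision rules flag discoveries as specified", {
  expect_true(mr_decide(0.049))
  expect_false(mr_decide(0.051))
  expect_false(mr_decide(NA_real_))
  set.seed(304)
  p <- c(runif(1000), rep(1e-8, 1000))
  flags <- mr_decide(p, mode = "bh-family")
  expect_equal(flags, bh_oracle(p) < 0.05)
  # half the family at 1e-8, half at 0.5: exactly the strong half is flagged
  p2 <- c(rep(1e-8, 100), rep(0.5, 100))
  expect_equal(mean(mr_decide(p2, mode = "bh-family")), 0.5)
})

test_that("random-effects IVW widens but never shrinks the standard error", {
  set.seed(305)
  bx <- runif(6, 0.8, 1.6)
  sy <- rep(0.1, 6)
  # strongly over-dispersed ratios
  by_od <- 0.3 * bx + rnorm(6, 0, 0.5)
  f_fix <- mr_ivw(bx, by_od, sy, model = "fixed")
  f_ran <- mr_ivw(bx, by_od, sy, model = "random")
  expect_equal(f_ran$theta_hat, f_fix$theta_hat)  # point estimate unchanged
  w <- 1 / sy^2
  sigma <- sqrt(sum(w * (by_od - f_fix$theta_hat * bx)^2) / 5)
  expect_equal(f_ran$se, f_fix$se * max(1, sigma), tolerance = 1e-12)
  expect_gt(f_ran$se, f_fix$se)

  # under-dispersed ratios: the multiplier floors at 1
  by_ud <- 0.3 * bx + rnorm(6, 0, 1e-4)
  expect_equal(mr_ivw(bx, by_ud, sy, model = "random")$se,
               mr_ivw(bx, by_ud, sy, model = "fixed")$se)

  # "auto" follows the >= 4 instruments convention
  expect_equal(mr_ivw(bx, by_od, sy, model = "auto")$model, "random")
  expect_equal(mr_ivw(bx[1:3], by_od[1:3], sy[1:3], model = "auto")$model,
               "fixed")
})
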