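test_that("effect draws respect the instrument / invalid structure", {
  set.seed(11)
  cfg <- scenario_config(invalid_frac = 0)
  eff <- draw_effects(cfg)
  expect_equal(sum(eff$iv_flags != "null"), 30)
  expect_true(all(eff$alpha == 0))
  expect_true(all(eff$phi == 0))
  expect_true(all(eff$gamma[eff$iv_flags == "null"] == 0))
  expect_true(all(eff$gamma[eff$iv_flags != "null"] >= 0.08 &
                    eff$gamma[eff$iv_flags != "null"] <= 0.10))

  cfg2 <- scenario_config(invalid_frac = 0.5)
  eff2 <- draw_effects(cfg2)
  expect_equal(sum(eff2$iv_flags == "invalid"), 15)
  expect_true(all(eff2$alpha[eff2$iv_flags != "invalid"] == 0))
  expect_true(all(eff2$alpha[eff2$iv_flags == "invalid"] != 0))
})

test_that("gamma draws match the uniform distribution's moments", {
  set.seed(12)
  cfg <- scenario_config(n_snps = 100000L, n_ivs = 100000L)
  eff <- draw_effects(cfg)
  mc_se <- (0.02 / sqrt(12)) / sqrt(1e5)
  expect_lt(abs(mean(eff$gamma) - 0.09), 3 * mc_se)
  expect_true(all(eff$gamma >= 0.08 & eff$gamma <= 0.10))
})

test_that("truncated-normal draws stay inside the truncation bounds", {
  set.seed(13)
  d <- dist_truncnorm(0.09, 0.01, 0.08, 0.10)
  x <- phosmr:::draw_dist(d, 5000)
  expect_true(all(x >= 0.08 & x <= 0.10))
  # mean of the symmetric-bound truncated normal equals its centre
  expect_lt(abs(mean(x) - 0.09), 4 * 0.01 / sqrt(5000))
})

test_that("simulated cohorts follow the structural equations' moments", {
  set.seed(21)
  n <- 1e5
  cfg <- scenario_config(theta = 0)
  eff <- draw_effects(cfg)
  cohort <- simulate_cohort(cfg, eff, n)

  # Binomial(2, 0.3) genotype moments
  cmeans <- colMeans(cohort$genotypes)
  mc_se <- sqrt(0.42 / n)
  expect_true(all(abs(cmeans - 0.6) < 4 * mc_se))
  cvars <- apply(cohort$genotypes[, 1:10], 2, var)
  expect_true(all(abs(cvars - 0.42) < 0.01))

  # Var(Y) = theta_uy^2 + 1 when theta = 0 and alpha = phi = 0
  cfg0 <- scenario_config(theta = 0, invalid_frac = 0)
  eff0 <- draw_effects(cfg0)
  eff0$gamma[] <- 0
  cohort0 <- simulate_cohort(cfg0, eff0, n)
  expect_lt(abs(var(cohort0$Y) - 1.5625), 4 * 1.5625 * sqrt(2 / n))

  # fully decoupled model: X and Y independent N(0, 1)
  cfgd <- scenario_config(theta = 0, theta_ux = 0, theta_uy = 0)
  effd <- draw_effects(cfgd)
  effd$gamma[] <- 0
  cd <- simulate_cohort(cfgd, effd, n)
  expect_lt(abs(cor(cd$X, cd$Y)), 3 / sqrt(n))
  expect_lt(abs(var(cd$X) - 1), 0.05)
})

test_that("regression on a single instrument recovers its gamma", {
  set.seed(22)
  cfg <- scenario_config(theta = 0.6)
  eff <- draw_effects(cfg)
  cohort <- simulate_cohort(cfg, eff, 1e5)
  j <- which(eff$iv_flags == "valid")[1]
  r <- marginal_regression(cohort$genotypes[, j], cohort$X)
  expect_lt(abs(r$beta - eff$gamma[j]), 3 * r$se)
})

test_that("population corr(X, Y) under the null matches the closed form", {
  set.seed(23)
  cfg <- scenario_config(theta = 0, invalid_frac = 0)
  eff <- draw_effects(cfg)
  n <- 1e5
  cohort <- simulate_cohort(cfg, eff, n)
  var_x <- 0.42 * sum(eff$gamma^2) + 0.75^2 + 1
  var_y <- 0.75^2 + 1
  rho <- 0.75 * 0.75 / sqrt(var_x * var_y)
  expect_lt(abs(cor(cohort$X, cohort$Y) - rho), 4 / sqrt(n))
})

test_that("paired datasets realize the three heterogeneity modes", {
  cfg <- scenario_config(n_gwas = 500L, n_small = 50L,
                         heterogeneity = "homogeneous", theta = 0.6)
  set.seed(31)
  pair <- make_paired_datasets(cfg)
  rows <- attr(pair$small, "rows")
  expect_length(rows, 50)
  expect_equal(pair$small$genotypes, pair$gwas$genotypes[rows, , drop = FALSE])
  expect_equal(pair$small$X, pair$gwas$X[rows])
  # Y is regenerated, not copied
  expect_false(any(pair$small$Y == pair$gwas$Y[rows]))

  cfg_low <- scenario_config(n_gwas = 500L, n_small = 50L, heterogeneity = "low")
  set.seed(32)
  pl <- make_paired_datasets(cfg_low)
  expect_identical(pl$small$true_params$gamma, pl$gwas$true_params$gamma)

  cfg_high <- scenario_config(n_gwas = 500L, n_small = 50L, heterogeneity = "high")
  set.seed(33)
  ph <- make_paired_datasets(cfg_high)
  iv <- ph$gwas$iv_flags != "null"
  expect_false(any(ph$small$true_params$gamma[iv] ==
                     ph$gwas$true_params$gamma[iv]))
  expect_true(all(ph$small$true_params$gamma[iv] >= 0.08 &
                    ph$small$true_params$gamma[iv] <= 0.10))
  expect_true(all(ph$small$true_params$gamma[!iv] == 0))
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- scenario_config(n_gwas = 200L, n_small = 20L)
  set.seed(99); a <- make_paired_datasets(cfg)
  set.seed(99); b <- make_paired_datasets(cfg)
  expect_identical(a, b)
})

test_that("compiled and reference generators agree", {
  cfg <- scenario_config(theta = 0.4, invalid_frac = 0.3, n_small = 50L)
  set.seed(41)
  eff <- draw_effects(cfg)
  n <- 2000L
  out <- phosmr:::.sim_cohort_stats_cpp(
    n, cfg$maf, eff$gamma, eff$alpha, eff$phi, cfg$theta,
    cfg$theta_ux, cfg$theta_uy, cfg$noise_sd, seq_len(n))

  # summary stats must equal the closed-form R path on the same matrix
  sx <- batch_summary(out$G_keep, out$X_keep)
  sy <- batch_summary(out$G_keep, out$Y_keep)
  expect_equal(out$beta_x, sx$beta, tolerance = 1e-10)
  expect_equal(out$se_x, sx$se, tolerance = 1e-10)
  expect_equal(out$beta_y, sy$beta, tolerance = 1e-10)
  expect_equal(out$se_y, sy$se, tolerance = 1e-10)

  # and the generated data must follow the same law as the R generator
  expect_true(all(out$G_keep %in% 0:2))
  expect_lt(abs(mean(out$G_keep) - 0.6), 4 * sqrt(0.42 / (n * 50)))
  j <- which(eff$iv_flags == "valid")[1]
  r <- marginal_regression(out$G_keep[, j], out$X_keep)
  expect_lt(abs(r$beta - eff$gamma[j]), 4 * r$se)
})

test_that("scenario configurations round-trip through YAML", {
  cfg <- scenario_config(theta = 0.12, invalid_frac = 0.3, n_small = 200L,
                         gamma_dist = dist_uniform(1.0, 1.5),
                         heterogeneity = "high", seed = 7L)
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_scenario(cfg, path)
  expect_equal(read_scenario(path), cfg)
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(n_ivs = 60), "n_ivs")
  expect_error(scenario_config(n_small = 500, n_gwas = 400), "homogeneous")
  expect_error(scenario_config(gamma_dist = list(kind = "uniform")),
               "distribution")
  expect_error(simulate_cohort(scenario_config(),
                               draw_effects(scenario_config()), 0), "positive")
})
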