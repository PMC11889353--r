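test_that("marginal regression matches closed-form hand computations", {
  r <- marginal_regression(c(0, 1, 2), c(0, 1, 1))
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, sqrt(1 / 12))
  expect_equal(r$pvalue, 1 / 3, tolerance = 1e-12)
  expect_equal(r$n_used, 3)

  # constant response: exact zero slope, flagged
  r0 <- marginal_regression(c(0, 1, 2, 0, 1, 2), rep(5, 6))
  expect_equal(r0$beta, 0)
  expect_equal(r0$pvalue, 1)
  expect_true(r0$degenerate)

  # constant genotype: undefined slope, p = 1 by convention
  rc <- marginal_regression(rep(1, 5), rnorm(5))
  expect_true(is.na(rc$beta))
  expect_equal(rc$pvalue, 1)
  expect_true(rc$degenerate)

  expect_error(marginal_regression(c(0, 1), c(1, 2)), "3 complete cases")
})

test_that("marginal regression agrees with the lm oracle", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    g <- rbinom(n, 2, 0.3)
    if (var(g) == 0) next
    y <- 0.3 * g + rnorm(n)
    r <- marginal_regression(g, y)
    o <- lm_oracle(y, g)
    expect_equal(r$beta, o$beta, tolerance = 1e-10)
    expect_equal(r$se, o$se, tolerance = 1e-10)
    expect_equal(r$pvalue, o$pvalue, tolerance = 1e-10)
    # closed form: cov/var on complete cases
    expect_equal(r$beta, cov(g, y) / var(g), tolerance = 1e-10)
  }
})

test_that("missing values are handled complete-case", {
  set.seed(102)
  g <- rbinom(40, 2, 0.4); y <- rnorm(40)
  g[c(3, 9)] <- NA; y[15] <- NA
  ok <- !is.na(g) & !is.na(y)
  r <- marginal_regression(g, y)
  o <- lm_oracle(y[ok], g[ok])
  expect_equal(r$n_used, sum(ok))
  expect_equal(r$beta, o$beta, tolerance = 1e-10)
})

test_that("p-values are invariant to affine rescaling of the trait", {
  set.seed(103)
  g <- rbinom(50, 2, 0.3); y <- 0.2 * g + rnorm(50)
  p1 <- marginal_regression(g, y)$pvalue
  p2 <- marginal_regression(g, 100 + 7 * y)$pvalue
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("adjusted regression matches the lm oracle and reduces correctly", {
  set.seed(111)
  n <- 80
  g <- rbinom(n, 2, 0.3)
  C <- cbind(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5),
             smoking = rbinom(n, 1, 0.4))
  y <- 0.4 * g + 0.02 * C[, 1] + 0.3 * C[, 2] + rnorm(n)
  r <- adjusted_regression(g, y, C)
  o <- lm_oracle(y, g, C)
  expect_equal(r$beta, o$beta, tolerance = 1e-10)
  expect_equal(r$se, o$se, tolerance = 1e-10)
  expect_equal(r$pvalue, o$pvalue, tolerance = 1e-10)

  # zero covariate columns: identical to the marginal fit
  r2 <- adjusted_regression(g, y, matrix(numeric(0), n, 0))
  rm_ <- marginal_regression(g, y)
  expect_equal(r2$beta, rm_$beta)
  expect_equal(r2$se, rm_$se)

  # covariates orthogonal to genotype and trait leave the slope untouched
  set.seed(112)
  Z <- matrix(rnorm(n * 2), n, 2)
  Z <- Z - cbind(1, g, y) %*% solve(crossprod(cbind(1, g, y)),
                                    crossprod(cbind(1, g, y), Z))
  r3 <- adjusted_regression(g, y, Z)
  expect_equal(r3$beta, rm_$beta, tolerance = 1e-8)

  # collinearity is reported by column
  expect_error(adjusted_regression(g, y, cbind(dup = g)), "dup")
})

test_that("adjusted regression is calibrated under permutation of the trait", {
  set.seed(113)
  n <- 40
  g <- rbinom(n, 2, 0.3)
  C <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  y <- rnorm(n)
  p <- replicate(1000, adjusted_regression(g, sample(y), C)$pvalue)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("type-I error of the marginal test is controlled", {
  set.seed(114)
  n <- 30
  p <- replicate(1e4, {
    g <- rbinom(n, 2, 0.3)
    while (var(g) == 0) g <- rbinom(n, 2, 0.3)
    marginal_regression(g, rnorm(n))$pvalue
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("batch summaries equal per-column calls", {
  set.seed(121)
  n <- 50
  G <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(n)
  st <- batch_summary(G, y)
  for (j in 1:3) {
    r <- marginal_regression(G[, j], y)
    expect_equal(st$beta[j], r$beta, tolerance = 1e-12)
    expect_equal(st$se[j], r$se, tolerance = 1e-12)
    expect_equal(st$pvalue[j], r$pvalue, tolerance = 1e-12)
  }
  expect_equal(st$snp_id, c("a", "b", "c"))

  # with missing values and covariates the loop path must agree too
  G[1, 1] <- NA
  C <- cbind(rnorm(n))
  st2 <- batch_summary(G, y, covariates = C)
  r2 <- adjusted_regression(G[, 1], y, C)
  expect_equal(st2$beta[1], r2$beta)
  expect_equal(st2$n_used[1], n - 1)

  # vacuous input
  st0 <- batch_summary(G[, 0, drop = FALSE], y)
  expect_s3_class(st0, "summary_stats")
  expect_equal(nrow(st0), 0)
})

test_that("vectorized batch path matches the loop oracle on a wide matrix", {
  set.seed(122)
  n <- 2000; J <- 50
  G <- matrix(rbinom(n * J, 2, 0.3), n, J)
  y <- drop(G[, 1] * 0.1) + rnorm(n)
  st <- batch_summary(G, y)
  for (j in sample(J, 5)) {
    o <- lm_oracle(y, G[, j])
    expect_equal(st$beta[j], o$beta, tolerance = 1e-10)
    expect_equal(st$se[j], o$se, tolerance = 1e-10)
  }
})

test_that("summary statistics round-trip through TSV", {
  set.seed(123)
  G <- matrix(rbinom(90, 2, 0.4), 30, 3,
              dimnames = list(NULL, paste0("rs", 1:3)))
  st <- batch_summary(G, rnorm(30))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_summary_stats(st, path)
  back <- read_summary_stats(path)
  expect_equal(back$beta, st$beta, tolerance = 1e-12)
  expect_equal(back$snp_id, st$snp_id)
})

test_that("correlation tests match their definitions", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  expect_equal(pearson_test(x, x)$estimate, 1)
  expect_equal(spearman_test(x, x)$estimate, 1)
  expect_equal(pearson_test(x, -x)$estimate, -1)

  # rank formula against direct computation
  x2 <- c(1, 2, 3, 4, 5); y2 <- c(2, 1, 4, 3, 5)
  sp <- spearman_test(x2, y2)
  expect_equal(sp$estimate, cor(rank(x2), rank(y2)))
  ct <- suppressWarnings(cor.test(x2, y2, method = "spearman", exact = FALSE))
  expect_equal(sp$estimate, unname(ct$estimate))

  # pairwise-complete handling
  set.seed(131)
  xa <- rnorm(30); ya <- xa + rnorm(30)
  xa[4] <- NA; ya[9] <- NA
  ok <- !is.na(xa) & !is.na(ya)
  expect_equal(pearson_test(xa, ya)$estimate, cor(xa[ok], ya[ok]))
  expect_equal(pearson_test(xa, ya)$n_used, sum(ok))

  expect_error(pearson_test(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_test(rnorm(3), rnorm(3)), "4 complete pairs")
})
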