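# Independent reference implementations used to cross-check the package's
# closed-form paths.  These deliberately use different machinery (lm/qr,
# explicit loops) from the implementations they test.

# generic least-squares oracle: slope, SE and p of `term` in y ~ X
lm_oracle <- function(y, g, covariates = NULL) {
  df <- data.frame(y = y, g = g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- paste0("c", seq_along(covariates))
    df <- cbind(df, covariates)
  }
  fit <- stats::lm(y ~ ., data = df)
  s <- summary(fit)$coefficients
  list(beta = s["g", 1], se = s["g", 2], pvalue = s["g", 4])
}

# weighted regression through the origin: the IVW equivalence oracle
wls_origin_oracle <- function(beta_x, beta_y, se_y) {
  fit <- stats::lm(beta_y ~ beta_x + 0, weights = 1 / se_y^2)
  s <- summary(fit)$coefficients
  # fixed-effects IVW standard error: the weighted-LS one divided by the
  # residual standard error (sigma is forced to 1 in the meta-analysis model)
  list(theta = s[1, 1], se = s[1, 2] / summary(fit)$sigma)
}

# literal step-by-step greedy LD pruning, column by column
ld_prune_oracle <- function(G, p, r2_max) {
  idx <- order(p, seq_along(p))
  kept <- c()
  for (j in idx) {
    ok <- TRUE
    for (k in kept) {
      r2 <- suppressWarnings(cor(G[, j], G[, k]))^2
      if (!is.na(r2) && r2 > r2_max) ok <- FALSE
    }
    if (ok) kept <- c(kept, j)
  }
  sort(kept)
}

# hand step-up BH: p * m / rank with monotone enforcement from the largest p
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# quick scenario used across tests: strong instruments, small GWAS so the
# full pipeline stays fast
quick_config <- function(...) {
  scenario_config(n_gwas = 2000L, gamma_dist = dist_uniform(1.0, 1.5), ...)
}
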