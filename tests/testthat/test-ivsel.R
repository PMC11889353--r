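mk_stats <- function(p, ids = paste0("snp", seq_along(p))) {
  phosmr:::new_summary_stats(
    data.frame(snp_id = ids, beta = rep(0.5, length(p)),
               se = rep(0.1, length(p)), pvalue = p,
               n_used = 100L, degenerate = FALSE, stringsAsFactors = FALSE),
    "exposure")
}

test_that("dual-evidence selection is the conjunction of its criteria", {
  st <- mk_stats(c(0.01, 0.2, 0.04))
  ext <- external_evidence(st$snp_id, prior_member = c(TRUE, TRUE, FALSE))
  expect_equal(select_iv_dual(st, ext)$snp_ids, "snp1")

  # all internal p = 1: empty set is a valid outcome
  ext2 <- external_evidence(paste0("snp", 1:3),
                            prior_member = rep(TRUE, 3))
  expect_length(select_iv_dual(mk_stats(rep(1, 3)), ext2), 0)

  # GWAS channel: Bonferroni on raw p
  set.seed(201)
  p_int <- runif(50); p_gwas <- runif(50)^3
  st50 <- mk_stats(p_int)
  ext50 <- external_evidence(st50$snp_id, gwas_pvalue = p_gwas, n_tests = 50)
  got <- select_iv_dual(st50, ext50)$snp_ids
  want <- st50$snp_id[p_int < 0.05 & p_gwas < 0.05 / 50]
  expect_equal(got, want)

  # both channels together: AND over all present evidence
  prior <- rep(c(TRUE, FALSE), 25)
  ext_both <- external_evidence(st50$snp_id, gwas_pvalue = p_gwas,
                                prior_member = prior, n_tests = 50)
  expect_equal(select_iv_dual(st50, ext_both)$snp_ids,
               st50$snp_id[p_int < 0.05 & p_gwas < 0.001 & prior])

  # misaligned identifiers must fail loudly
  ext_bad <- external_evidence(rev(st50$snp_id), gwas_pvalue = p_gwas)
  expect_error(select_iv_dual(st50, ext_bad), "misaligned")
})

test_that("FDR / min-p / GWAS selections follow their rules", {
  st <- mk_stats(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(select_iv_fdr(st)$snp_ids, paste0("snp", 1:4))
  expect_equal(select_iv_fdr(mk_stats(0.04))$snp_ids, "snp1")
  expect_length(select_iv_fdr(mk_stats(0.06)), 0)

  # BH null property: expected selected fraction under uniform p stays <= q
  set.seed(202)
  frac <- mean(replicate(200, length(select_iv_fdr(mk_stats(runif(50)))) / 50))
  expect_lte(frac, 0.05)

  expect_equal(select_iv_min(mk_stats(c(0.001, 0.01, 0.6)))$snp_ids, "snp1")
  expect_length(select_iv_min(mk_stats(c(0.3, 0.4, 0.9))), 0)
  # ties broken deterministically by input order
  expect_equal(select_iv_min(mk_stats(c(0.01, 0.01, 0.02)))$snp_ids, "snp1")

  ext <- external_evidence(paste0("snp", 1:50),
                           gwas_pvalue = c(0.0009, 0.0011, rep(1, 48)),
                           n_tests = 50)
  expect_equal(select_iv_gwas(ext)$snp_ids, "snp1")
  ext_all1 <- external_evidence(paste0("snp", 1:50),
                                gwas_pvalue = rep(1, 50), n_tests = 50)
  expect_length(select_iv_gwas(ext_all1), 0)
})

test_that("selection subset invariants hold on random instances", {
  set.seed(203)
  for (i in 1:20) {
    p_int <- runif(50)^2; p_gwas <- runif(50)^4
    st <- mk_stats(p_int)
    ext <- external_evidence(st$snp_id, gwas_pvalue = p_gwas, n_tests = 50)
    dual <- select_iv_dual(st, ext)$snp_ids
    gw <- select_iv_gwas(ext)$snp_ids
    fdr <- select_iv_fdr(st)$snp_ids
    mn <- select_iv_min(st)$snp_ids
    expect_true(all(dual %in% gw))
    expect_true(all(mn %in% fdr))
    expect_lte(length(mn), 1)
  }
})

test_that("LD pruning keeps the most significant SNP of each linked group", {
  set.seed(211)
  g <- rbinom(100, 2, 0.4)
  G <- cbind(a = g, b = g)  # identical columns, r^2 = 1
  expect_equal(as.character(ld_prune(G, c(0.01, 0.001))), "b")

  # independent columns all survive
  G2 <- sapply(1:5, function(i) rbinom(200, 2, 0.3))
  colnames(G2) <- paste0("s", 1:5)
  if (max(cor(G2)[upper.tri(diag(5))]^2) <= 0.2)
    expect_equal(as.character(ld_prune(G2, runif(5))), paste0("s", 1:5))

  # constant columns are kept but flagged (no linkage information)
  G3 <- cbind(x = g, const = rep(1L, 100))
  out <- ld_prune(G3, c(0.5, 0.2))
  expect_setequal(as.character(out), c("x", "const"))
  expect_equal(attr(out, "flagged_constant"), "const")
})

test_that("LD pruning matches the brute-force oracle on random instances", {
  set.seed(212)
  for (i in 1:25) {
    n <- 60; J <- 8
    base <- matrix(rbinom(n * J, 2, 0.3), n, J)
    # induce linkage by copying columns with noise
    for (j in sample(J, 3)) {
      k <- sample(J, 1)
      flip <- rbinom(n, 1, 0.15) == 1
      base[, j] <- ifelse(flip, rbinom(n, 2, 0.3), base[, k])
    }
    colnames(base) <- paste0("v", 1:J)
    p <- round(runif(J), 3)  # rounded to exercise ties
    got <- ld_prune(base, p, r2_max = 0.2)
    want <- colnames(base)[ld_prune_oracle(base, p, 0.2)]
    expect_equal(as.character(got), want)
  }
})

test_that("LD pruning is invariant to column permutation up to tie-breaks", {
  set.seed(213)
  G <- matrix(rbinom(400, 2, 0.3), 50, 8)
  G[, 2] <- G[, 1]; G[, 5] <- G[, 4]
  colnames(G) <- paste0("w", 1:8)
  p <- c(0.5, 0.01, 0.3, 0.02, 0.9, 0.1, 0.2, 0.4)  # distinct p: no ties
  perm <- sample(8)
  a <- sort(as.character(ld_prune(G, p)))
  b <- sort(as.character(ld_prune(G[, perm], p[perm])))
  expect_equal(a, b)
})

test_that("cis windows are inclusive and chromosome-aware", {
  region <- list(chrom = "chr1", start = 5e6, end = 5.01e6)
  expect_true(cis_filter("chr1", 4e6, region))
  expect_false(cis_filter("chr1", 3999999, region))
  expect_true(cis_filter("chr1", 6.01e6, region))
  expect_false(cis_filter("chr1", 6010001, region))
  expect_false(cis_filter("chr2", 5005000, region))
  # window clipped at position 1
  expect_true(cis_filter("chr1", 1, list(chrom = "chr1", start = 5, end = 10)))
})

test_that("SNP and feature filters apply the stated thresholds", {
  set.seed(221)
  n <- 79
  g_low <- c(rep(1L, 7), rep(0L, n - 7))          # variation 8.9% -> drop
  g_zero <- rep(0L, n)                             # monomorphic -> drop
  g_ok <- rbinom(n, 2, 0.3)
  g_rare <- c(rep(1L, 8), rep(0L, n - 8))          # 8/79 = 10.1% varied,
  G <- cbind(low = g_low, zero = g_zero, ok = g_ok, rare = g_rare)
  kept <- filter_snps(G)
  expect_false("low" %in% kept)
  expect_false("zero" %in% kept)
  expect_true("ok" %in% kept)
  expect_true("rare" %in% kept)  # maf 8/158 = 5.1% > 1%

  # oracle recomputation on random matrices + idempotence
  for (i in 1:10) {
    Gr <- matrix(rbinom(n * 6, 2, runif(1, 0.02, 0.4)), n, 6,
                 dimnames = list(NULL, paste0("r", 1:6)))
    kept_r <- filter_snps(Gr)
    want <- colnames(Gr)[apply(Gr, 2, function(g) {
      mean(g > 0) >= 0.10 && min(mean(g) / 2, 1 - mean(g) / 2) > 0.01
    })]
    expect_equal(kept_r, want)
    expect_equal(filter_snps(Gr[, kept_r, drop = FALSE]), kept_r)
  }

  M <- matrix(rnorm(79 * 3), 3, 79,
              dimnames = list(c("f_bad", "f_ok", "f_full"), NULL))
  M["f_bad", 1:72] <- NA   # 72/79 = 91.1% missing -> removed
  M["f_ok", 1:71] <- NA    # 89.9% -> kept
  kept_f <- filter_features(M)
  expect_equal(kept_f, c("f_ok", "f_full"))
  expect_equal(filter_features(M[kept_f, , drop = FALSE]), kept_f)
})
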