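#' Marginal (univariate) SNP-trait regression
#'
#' Ordinary least squares of a trait on a single SNP dosage with an intercept:
#' the per-SNP model used to derive summary statistics in both the simulation
#' study and the cohort screen.  Rows with a missing genotype or trait value
#' are dropped (complete-case).  The slope standard error uses the residual
#' variance on `n - 2` degrees of freedom and the p-value is the two-sided t
#' test of the slope.
#'
#' A constant genotype leaves the slope undefined; such calls return a
#' flagged degenerate result (`beta = NA`, `pvalue = 1`) rather than an error,
#' so that batch screens over many SNPs can record and move on.
#'
#' @param g numeric vector of genotype dosages (0/1/2; `NA` allowed).
#' @param y numeric trait vector of the same length.
#' @return A list with `beta`, `se`, `pvalue`, `n_used` and `degenerate`.
#' @export
#' @examples
#' marginal_regression(c(0, 1, 2), c(0, 1, 1)) # beta 0.5, p 1/3
marginal_regression <- function(g, y) {
  stopifnot(length(g) == length(y))
  ok <- !is.na(g) & !is.na(y)
  g <- as.numeric(g[ok]); y <- as.numeric(y[ok])
  n <- length(g)
  if (n < 3) stop("need at least 3 complete cases", call. = FALSE)
  sg <- sum(g); sgg <- sum(g * g)
  sxx <- sgg - sg * sg / n
  if (sxx <= 0) {
    return(list(beta = NA_real_, se = NA_real_, pvalue = 1, n_used = n,
                degenerate = TRUE))
  }
  sy <- sum(y)
  sxy <- sum(g * y) - sg * sy / n
  syy <- sum(y * y) - sy * sy / n
  beta <- sxy / sxx
  rss <- max(syy - beta * sxy, 0)
  se2 <- rss / ((n - 2) * sxx)
  se <- sqrt(se2)
  if (se == 0) {
    # exact fit (or constant response): no sampling variability to test against
    p <- if (beta == 0) 1 else 0
    return(list(beta = beta, se = 0, pvalue = p, n_used = n,
                degenerate = TRUE))
  }
  tval <- beta / se
  list(beta = beta, se = se,
       pvalue = 2 * stats::pt(-abs(tval), df = n - 2),
       n_used = n, degenerate = FALSE)
}

#' Covariate-adjusted SNP-trait regression
#'
#' Least squares of a trait on a SNP dosage plus covariates (with intercept):
#' `trait ~ genotype + covariates`, the adjusted model used for cohort
#' screening (age, sex, smoking status).  Reported effect, SE and two-sided t
#' p-value refer to the genotype coefficient, on `n - rank` residual degrees
#' of freedom; rows with any missing value are dropped.  With zero covariate
#' columns this reduces exactly to [marginal_regression()].
#'
#' @param g numeric genotype vector.
#' @param y numeric trait vector.
#' @param covariates numeric matrix or data frame of covariates (may have zero
#'   columns), rows aligned with `g`.
#' @return A list with `beta`, `se`, `pvalue`, `n_used` and `degenerate`.
#' @export
adjusted_regression <- function(g, y, covariates = NULL) {
  if (is.null(covariates)) return(marginal_regression(g, y))
  covariates <- as.matrix(covariates)
  if (ncol(covariates) == 0) return(marginal_regression(g, y))
  stopifnot(length(g) == length(y), nrow(covariates) == length(g))
  storage.mode(covariates) <- "double"
  ok <- !is.na(g) & !is.na(y) & stats::complete.cases(covariates)
  g <- g[ok]; y <- y[ok]
  C <- covariates[ok, , drop = FALSE]
  n <- length(g)
  p <- 2L + ncol(C)
  if (n < p + 1L) stop("too few complete cases for the adjusted model",
                       call. = FALSE)
  if (stats::var(g) == 0) {
    return(list(beta = NA_real_, se = NA_real_, pvalue = 1, n_used = n,
                degenerate = TRUE))
  }
  X <- cbind(`(Intercept)` = 1, genotype = g, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qx, y)
  res <- y - drop(X %*% coefs)
  df <- n - qx$rank
  sigma2 <- sum(res * res) / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  # undo the pivoting applied by qr()
  unpiv <- order(qx$pivot)
  xtx_inv <- xtx_inv[unpiv, unpiv, drop = FALSE]
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  beta <- unname(coefs["genotype"])
  if (se == 0) {
    return(list(beta = beta, se = 0, pvalue = if (beta == 0) 1 else 0,
                n_used = n, degenerate = TRUE))
  }
  tval <- beta / se
  list(beta = beta, se = unname(se),
       pvalue = 2 * stats::pt(-abs(tval), df = df),
       n_used = n, degenerate = FALSE)
}

#' Per-SNP summary statistics for one trait
#'
#' Columnwise application of [marginal_regression()] (or
#' [adjusted_regression()] when covariates are supplied) across a genotype
#' matrix, producing the summary statistics (beta, SE, p) consumed by
#' instrument selection and IVW estimation.  The fully observed, unadjusted
#' case is vectorized; results are identical to per-column calls.
#'
#' @param genotypes numeric matrix, samples x SNPs.
#' @param trait numeric vector, one value per sample.
#' @param covariates optional covariate matrix/data frame.
#' @param snp_ids SNP identifiers; defaults to `colnames(genotypes)`.
#' @param trait_id identifier of the regressed trait (stored as an attribute).
#' @return A data frame of class `"summary_stats"` with columns `snp_id`,
#'   `beta`, `se`, `pvalue`, `n_used`, `degenerate`.
#' @export
batch_summary <- function(genotypes, trait, covariates = NULL,
                          snp_ids = colnames(genotypes), trait_id = "trait") {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != length(trait))
    stop("genotype rows and trait length differ", call. = FALSE)
  J <- ncol(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(J))
  if (J == 0L) {
    return(new_summary_stats(data.frame(
      snp_id = character(), beta = numeric(), se = numeric(),
      pvalue = numeric(), n_used = integer(), degenerate = logical()
    ), trait_id))
  }
  if (is.null(covariates) && !anyNA(genotypes) && !anyNA(trait)) {
    n <- nrow(genotypes)
    if (n < 3) stop("need at least 3 complete cases", call. = FALSE)
    sg <- colSums(genotypes)
    sgg <- colSums(genotypes * genotypes)
    sy <- sum(trait); syy <- sum(trait * trait) - sy * sy / n
    sxy <- drop(crossprod(genotypes, trait)) - sg * sy / n
    sxx <- sgg - sg * sg / n
    const <- sxx <= 0
    beta <- ifelse(const, NA_real_, sxy / ifelse(const, 1, sxx))
    rss <- pmax(syy - beta * sxy, 0)
    se <- sqrt(rss / ((n - 2) * ifelse(const, 1, sxx)))
    tval <- beta / se
    pv <- 2 * stats::pt(-abs(tval), df = n - 2)
    exactfit <- !const & se == 0
    pv[exactfit] <- ifelse(beta[exactfit] == 0, 1, 0)
    pv[const] <- 1
    se[const] <- NA_real_
    out <- data.frame(
      snp_id = snp_ids, beta = unname(beta), se = unname(se),
      pvalue = unname(pv), n_used = n,
      degenerate = unname(const | exactfit),
      stringsAsFactors = FALSE
    )
    return(new_summary_stats(out, trait_id))
  }
  rows <- lapply(seq_len(J), function(j) {
    r <- adjusted_regression(genotypes[, j], trait, covariates)
    data.frame(snp_id = snp_ids[j], beta = r$beta, se = r$se,
               pvalue = r$pvalue, n_used = r$n_used, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  new_summary_stats(do.call(rbind, rows), trait_id)
}

new_summary_stats <- function(df, trait_id) {
  rownames(df) <- NULL
  attr(df, "trait_id") <- trait_id
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Write / read per-SNP summary statistics
#'
#' TSV round-trip with columns `snp_id`, `beta`, `se`, `pvalue`, `n`.
#'
#' @param stats a `"summary_stats"` data frame.
#' @param path file path.
#' @return `path` (writer) or a `"summary_stats"` data frame (reader).
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.frame(snp_id = stats$snp_id, beta = stats$beta, se = stats$se,
                    pvalue = stats$pvalue, n = stats$n_used)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_summary_stats(
    data.frame(snp_id = as.character(df$snp_id), beta = df$beta, se = df$se,
               pvalue = df$pvalue, n_used = df$n,
               degenerate = is.na(df$beta), stringsAsFactors = FALSE),
    trait_id = "trait")
}

#' Pearson correlation test
#'
#' Product-moment correlation with the two-sided t test, on pairwise-complete
#' observations.  This is the conventional baseline against which the MR
#' screen is compared, and also the exposure-outcome prefilter of the cohort
#' pipeline.
#'
#' @param x,y numeric vectors.
#' @return A list with `estimate` (r), `pvalue` and `n_used`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), pvalue = ct$p.value, n_used = n)
}

#' Spearman rank correlation test
#'
#' Rank correlation using average ranks for ties, with the two-sided t
#' approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on `n - 2` degrees of
#' freedom; pairwise-complete observations.
#'
#' @param x,y numeric vectors.
#' @return A list with `estimate` (rho), `pvalue` and `n_used`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    return(list(estimate = rho, pvalue = 0, n_used = n))
  }
  tval <- rho * sqrt((n - 2) / (1 - rho * rho))
  list(estimate = rho, pvalue = 2 * stats::pt(-abs(tval), df = n - 2),
       n_used = n)
}
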