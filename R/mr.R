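#' Wald ratio for a single instrument
#'
#' The per-variant causal effect estimate \eqn{\beta_Y / \beta_X} with the
#' first-order standard error \eqn{se_Y / |\beta_X|} (exposure uncertainty
#' ignored, as in the fixed-effects IVW framework these ratios feed into).
#'
#' @param beta_x SNP-exposure effect (must be nonzero).
#' @param beta_y SNP-outcome effect.
#' @param se_y standard error of `beta_y` (positive).
#' @return A list with `ratio` and `se`.
#' @export
#' @examples
#' wald_ratio(0.5, 0.25, 0.1) # ratio 0.5, se 0.2
wald_ratio <- function(beta_x, beta_y, se_y) {
  if (beta_x == 0) stop("beta_x is zero: Wald ratio undefined", call. = FALSE)
  if (se_y <= 0) stop("se_y must be positive", call. = FALSE)
  list(ratio = beta_y / beta_x, se = se_y / abs(beta_x))
}

#' Fixed-effects inverse-variance weighted (IVW) causal estimate
#'
#' The central estimator of the package: per-variant Wald ratios combined in
#' a fixed-effects meta-analysis,
#' \deqn{\hat\theta = \frac{\sum_j \beta_{Xj}\beta_{Yj}/se_{Yj}^2}
#'                         {\sum_j \beta_{Xj}^2/se_{Yj}^2},\qquad
#'       se(\hat\theta) = \Big(\sum_j \beta_{Xj}^2/se_{Yj}^2\Big)^{-1/2},}
#' equivalent to weighted least squares of the outcome effects on the
#' exposure effects through the origin with weights \eqn{1/se_{Yj}^2}.
#' Inference uses the normal reference distribution
#' (\eqn{p = 2(1-\Phi(|\hat\theta/se|))}).  With a single instrument the
#' estimate reduces exactly to the Wald ratio.
#'
#' An empty instrument set yields a distinguished "no instruments" fit
#' (`n_iv = 0`, `NA` estimate) that downstream decision rules count as a
#' non-discovery; a zero exposure effect is an error, since selection should
#' have excluded such variants.
#'
#' The point estimate is identical under every `model`; the variants differ
#' in the standard error.  `"fixed"` uses the meta-analysis SE above.
#' `"random"` multiplies it by `max(1, \hat\sigma)`, where \eqn{\hat\sigma}
#' is the weighted residual standard error of the through-origin regression
#' — the multiplicative random-effects correction that widens intervals when
#' the per-variant ratios are over-dispersed (it needs at least 2
#' instruments and never shrinks the SE).  `"auto"` mirrors the convention
#' of the standard MR software: random-effects with 4 or more instruments,
#' fixed-effects otherwise.
#'
#' @param beta_x,beta_y per-variant exposure and outcome effects.
#' @param se_y per-variant outcome standard errors (positive).
#' @param iv_ids optional instrument identifiers.
#' @param min_iv minimum number of instruments required for an estimate
#'   (default 1); below the floor the no-instruments fit is returned.
#' @param model `"fixed"` (default), `"random"`, or `"auto"` (see Details).
#' @return An object of class `"mr_ivw"` with components `theta_hat`, `se`,
#'   `z`, `pvalue`, `n_iv`, `iv_ids`, `method`, `model`, supporting
#'   [print()], [summary()], [coef()], [vcov()], [confint()] and [plot()].
#' @export
#' @examples
#' fit <- mr_ivw(c(1, 2), c(0.3, 0.6), c(1, 1))
#' coef(fit)      # 0.3
#' confint(fit)
mr_ivw <- function(beta_x, beta_y, se_y, iv_ids = NULL, min_iv = 1L,
                   model = c("fixed", "random", "auto")) {
  model <- match.arg(model)
  k <- length(beta_x)
  stopifnot(length(beta_y) == k, length(se_y) == k)
  if (is.null(iv_ids)) iv_ids <- if (k) paste0("iv", seq_len(k)) else character()
  if (k < max(1L, min_iv)) {
    return(structure(
      list(theta_hat = NA_real_, se = NA_real_, z = NA_real_,
           pvalue = NA_real_, n_iv = 0L, iv_ids = character(),
           method = "ivw", no_instruments = TRUE,
           beta_x = numeric(), beta_y = numeric(), se_y = numeric()),
      class = "mr_ivw"))
  }
  if (any(se_y <= 0)) stop("all se_y must be positive", call. = FALSE)
  if (any(beta_x == 0))
    stop("zero exposure effect among instruments: ratio undefined",
         call. = FALSE)
  if (model == "auto") model <- if (k >= 4L) "random" else "fixed"
  w <- 1 / (se_y * se_y)
  denom <- sum(beta_x * beta_x * w)
  theta <- sum(beta_x * beta_y * w) / denom
  se <- 1 / sqrt(denom)
  if (model == "random" && k >= 2L) {
    resid <- beta_y - theta * beta_x
    sigma <- sqrt(sum(w * resid * resid) / (k - 1L))
    se <- se * max(1, sigma)
  }
  z <- theta / se
  structure(
    list(theta_hat = theta, se = se, z = z,
         pvalue = 2 * stats::pnorm(-abs(z)),
         n_iv = as.integer(k), iv_ids = as.character(iv_ids),
         method = "ivw", model = model, no_instruments = FALSE,
         beta_x = beta_x, beta_y = beta_y, se_y = se_y),
    class = "mr_ivw")
}

#' @export
print.mr_ivw <- function(x, digits = 4, ...) {
  cat("Fixed-effects IVW Mendelian randomization\n")
  if (x$no_instruments) {
    cat("  no instruments: no estimate (recorded as non-discovery)\n")
    return(invisible(x))
  }
  cat(sprintf("  instruments: %d\n", x$n_iv))
  cat(sprintf("  theta_hat = %s  (se %s, z %s, p %s)\n",
              format(x$theta_hat, digits = digits),
              format(x$se, digits = digits),
              format(x$z, digits = digits),
              format.pval(x$pvalue, digits = digits)))
  invisible(x)
}

#' @export
summary.mr_ivw <- function(object, ...) {
  structure(list(fit = object, ci = confint(object)), class = "summary.mr_ivw")
}

#' @export
print.summary.mr_ivw <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!x$fit$no_instruments) {
    cat(sprintf("  95%% CI: [%s, %s]\n",
                format(x$ci[1], digits = digits),
                format(x$ci[2], digits = digits)))
    cat("  instruments:", paste(x$fit$iv_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mr_ivw <- function(object, ...) c(theta = object$theta_hat)

#' @export
vcov.mr_ivw <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("theta", "theta"))
}

#' @export
confint.mr_ivw <- function(object, parm = "theta", level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(object$theta_hat - zq * object$se, object$theta_hat + zq * object$se)
  names(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  ci
}

#' @export
plot.mr_ivw <- function(x, ...) {
  if (x$no_instruments || !length(x$beta_x)) {
    stop("nothing to plot: no instruments", call. = FALSE)
  }
  graphics::plot(x$beta_x, x$beta_y,
                 xlab = "SNP-exposure effect", ylab = "SNP-outcome effect",
                 pch = 19, ...)
  graphics::arrows(x$beta_x, x$beta_y - 1.96 * x$se_y,
                   x$beta_x, x$beta_y + 1.96 * x$se_y,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  graphics::abline(0, x$theta_hat, col = "firebrick")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH adjustment (monotone-enforced, capped at 1), input
#' order preserved; a thin wrapper over [stats::p.adjust()] so every module
#' shares one spelling of the procedure.
#'
#' @param pvalues numeric vector of raw p-values (`NA` passed through).
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Discovery decision rule
#'
#' Converts p-values (or a fitted [mr_ivw()] object) into discovery flags.
#' In `"raw"` mode a result is a discovery when `p < alpha`; in `"bh-family"`
#' mode BH adjustment is applied across the supplied family of p-values
#' first.  Missing p-values (the no-instruments case) are never discoveries.
#'
#' @param x an `"mr_ivw"` fit or a numeric vector of p-values.
#' @param alpha significance level (default 0.05).
#' @param mode `"raw"` or `"bh-family"`.
#' @return Logical vector of discovery flags.
#' @export
mr_decide <- function(x, alpha = 0.05, mode = c("raw", "bh-family")) {
  mode <- match.arg(mode)
  p <- if (inherits(x, "mr_ivw")) x$pvalue else as.numeric(x)
  if (mode == "bh-family") p <- bh_adjust(p)
  !is.na(p) & p < alpha
}
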