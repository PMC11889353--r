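#' Scenario configuration for the generative simulation model
#'
#' Bundles every parameter of the three-equation structural model used in the
#' simulation studies.  For individual \eqn{i} and SNP \eqn{j}:
#' \deqn{U_i = \sum_j \Phi_j G_{ij} + \epsilon_{iU}}
#' \deqn{X_i = \sum_j \gamma_j G_{ij} + \theta_{Ux} U_i + \epsilon_{iX}}
#' \deqn{Y_i = \sum_j \alpha_j G_{ij} + \theta X_i + \theta_{Uy} U_i + \epsilon_{iY}}
#' with \eqn{G_{ij} \sim Binomial(2, maf)} independently and independent
#' \eqn{N(0, noise\_sd^2)} noise terms.  \eqn{X} is the exposure (a
#' phosphosite), \eqn{Y} the outcome (a protein), \eqn{U} an unmeasured
#' confounder, and \eqn{\theta} the causal effect of interest.
#'
#' Of the `n_snps` SNPs, `n_ivs` are designated instruments and receive
#' \eqn{\gamma_j} drawn from `gamma_dist`; the remaining SNPs are null
#' (\eqn{\gamma_j = \alpha_j = \Phi_j = 0}).  A fraction `invalid_frac` of the
#' instruments is invalid: those SNPs get a direct outcome effect
#' \eqn{\alpha_j \sim N(0, alpha\_sd^2)}, violating the exclusion restriction.
#'
#' @param n_snps total number of SNPs \eqn{J}.
#' @param n_ivs number of SNPs designated as instruments.
#' @param invalid_frac fraction of instruments made invalid (0, 0.3, 0.5 in the
#'   benchmark grid); `round(invalid_frac * n_ivs)` SNPs are drawn uniformly at
#'   random among the instruments.
#' @param maf minor allele frequency of the simulated genotypes.
#' @param gamma_dist distribution of SNP-exposure effects for instrument SNPs:
#'   either `dist_uniform(min, max)` or
#'   `dist_truncnorm(mean, sd, lower, upper)`.
#' @param gamma_dist_high distribution used to redraw \eqn{\gamma} for the
#'   small cohort under high heterogeneity.  By default derived from
#'   `gamma_dist`: a normal centred at the uniform's midpoint with sd equal
#'   to half its range, truncated to the same bounds (for the default
#'   U(0.08, 0.10) this is the truncated normal with mean 0.09, sd 0.01 on
#'   [0.08, 0.10]), so heterogeneity perturbs effect strengths within the
#'   same regime rather than switching regimes.
#' @param alpha_sd standard deviation of the direct SNP-outcome effects of
#'   invalid instruments.
#' @param theta true causal effect of the exposure on the outcome.
#' @param theta_ux,theta_uy confounder loadings on exposure and outcome.
#' @param phi SNP-confounder effects; scalar recycled to `n_snps` (0 throughout
#'   the benchmark settings).
#' @param noise_sd standard deviation of the three noise terms.
#' @param n_gwas sample size of the simulated external GWAS cohort.
#' @param n_small sample size of the small multiomics cohort.
#' @param heterogeneity relation between GWAS and small cohort:
#'   `"homogeneous"` (small cohort subsampled from the GWAS individuals),
#'   `"low"` (regenerated from the same realized effects), or `"high"`
#'   (\eqn{\gamma} redrawn from `gamma_dist_high` before regeneration).
#' @param n_reps default number of replicates for benchmarking.
#' @param seed root seed used by [run_benchmark()] to derive per-replicate
#'   streams.
#'
#' @return An object of class `"scenario_config"` (a validated list).
#' @seealso [draw_effects()], [simulate_cohort()], [make_paired_datasets()],
#'   [run_benchmark()]
#' @export
#' @examples
#' cfg <- scenario_config(theta = 0.6, n_small = 100, seed = 1)
#' cfg
scenario_config <- function(n_snps = 50L,
                            n_ivs = 30L,
                            invalid_frac = 0,
                            maf = 0.3,
                            gamma_dist = dist_uniform(0.08, 0.10),
                            gamma_dist_high = NULL,
                            alpha_sd = 0.15,
                            theta = 0,
                            theta_ux = 0.75,
                            theta_uy = 0.75,
                            phi = 0,
                            noise_sd = 1,
                            n_gwas = 100000L,
                            n_small = 100L,
                            heterogeneity = c("homogeneous", "low", "high"),
                            n_reps = 2000L,
                            seed = NULL) {
  heterogeneity <- match.arg(heterogeneity)
  cfg <- list(
    n_snps = as.integer(n_snps), n_ivs = as.integer(n_ivs),
    invalid_frac = invalid_frac, maf = maf,
    gamma_dist = validate_dist(gamma_dist),
    gamma_dist_high = if (is.null(gamma_dist_high))
      derive_high_dist(validate_dist(gamma_dist))
    else validate_dist(gamma_dist_high),
    alpha_sd = alpha_sd, theta = theta,
    theta_ux = theta_ux, theta_uy = theta_uy,
    phi = rep_len(phi, n_snps), noise_sd = noise_sd,
    n_gwas = as.integer(n_gwas), n_small = as.integer(n_small),
    heterogeneity = heterogeneity,
    n_reps = as.integer(n_reps),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(
    cfg$n_snps >= 1L, cfg$n_ivs >= 0L,
    cfg$invalid_frac >= 0, cfg$invalid_frac <= 1,
    cfg$maf > 0, cfg$maf < 1,
    cfg$alpha_sd >= 0, cfg$noise_sd >= 0,
    cfg$n_gwas >= 1L, cfg$n_small >= 1L, cfg$n_reps >= 1L
  )
  if (cfg$n_ivs > cfg$n_snps)
    stop("n_ivs must not exceed n_snps", call. = FALSE)
  if (cfg$heterogeneity == "homogeneous" && cfg$n_small > cfg$n_gwas)
    stop("n_small must not exceed n_gwas in homogeneous mode", call. = FALSE)
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Simulation scenario\n")
  cat(sprintf("  SNPs: %d (%d instruments, %.0f%% invalid)\n",
              x$n_snps, x$n_ivs, 100 * x$invalid_frac))
  cat(sprintf("  gamma ~ %s; alpha sd %.3g; maf %.2f\n",
              format_dist(x$gamma_dist), x$alpha_sd, x$maf))
  cat(sprintf("  theta = %.3g; confounder loadings (%.2f, %.2f)\n",
              x$theta, x$theta_ux, x$theta_uy))
  cat(sprintf("  cohorts: GWAS n = %d, small n = %d (%s heterogeneity)\n",
              x$n_gwas, x$n_small, x$heterogeneity))
  invisible(x)
}

#' Effect-size distribution specifications
#'
#' Small constructors for the distributions from which SNP-exposure effects
#' are drawn.
#'
#' @param min,max bounds of the uniform distribution.
#' @param mean,sd,lower,upper parameters of the truncated normal (`sd` is the
#'   standard deviation of the parent normal).
#' @return A list with class `"dist_spec"`.
#' @export
dist_uniform <- function(min, max) {
  structure(list(kind = "uniform", min = min, max = max), class = "dist_spec")
}

#' @rdname dist_uniform
#' @export
dist_truncnorm <- function(mean, sd, lower, upper) {
  structure(list(kind = "truncnorm", mean = mean, sd = sd,
                 lower = lower, upper = upper), class = "dist_spec")
}

# default high-heterogeneity redraw: perturb effect strengths within the
# same bounds (truncated normal at the uniform's midpoint, sd = half-range)
derive_high_dist <- function(d) {
  if (d$kind == "uniform")
    dist_truncnorm((d$min + d$max) / 2, (d$max - d$min) / 2, d$min, d$max)
  else d
}

validate_dist <- function(d) {
  if (!inherits(d, "dist_spec") || !d$kind %in% c("uniform", "truncnorm"))
    stop("invalid distribution spec; use dist_uniform() or dist_truncnorm()",
         call. = FALSE)
  if (d$kind == "uniform" && d$min > d$max)
    stop("uniform distribution requires min <= max", call. = FALSE)
  if (d$kind == "truncnorm" && (d$sd < 0 || d$lower > d$upper))
    stop("truncated normal requires sd >= 0 and lower <= upper", call. = FALSE)
  d
}

format_dist <- function(d) {
  if (d$kind == "uniform") sprintf("U(%.3g, %.3g)", d$min, d$max)
  else sprintf("TN(%.3g, %.3g; [%.3g, %.3g])", d$mean, d$sd, d$lower, d$upper)
}

draw_dist <- function(d, n) {
  switch(d$kind,
    uniform = stats::runif(n, d$min, d$max),
    truncnorm = {
      # inverse-CDF sampling of the truncated normal
      plo <- stats::pnorm(d$lower, d$mean, d$sd)
      phi <- stats::pnorm(d$upper, d$mean, d$sd)
      stats::qnorm(stats::runif(n, plo, phi), d$mean, d$sd)
    }
  )
}

#' Draw realized effect vectors for one replicate
#'
#' Samples the per-SNP effects of the structural model under the scenario
#' configuration: \eqn{\gamma_j} from `gamma_dist` for instrument SNPs (0 for
#' null SNPs), \eqn{\alpha_j \sim N(0, alpha\_sd^2)} for invalid instruments
#' (0 elsewhere), and \eqn{\Phi_j} as configured (0 throughout the benchmark
#' settings).  Instrument positions and the invalid subset are drawn uniformly
#' at random.  Uses the current RNG state.
#'
#' @param config a [scenario_config()].
#' @return A list of class `"effect_set"` with components `gamma`, `alpha`,
#'   `phi` (numeric vectors of length `n_snps`) and `iv_flags` (factor with
#'   levels `"null"`, `"valid"`, `"invalid"`).
#' @export
draw_effects <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  J <- config$n_snps
  gamma <- alpha <- numeric(J)
  flags <- rep("null", J)
  iv_idx <- sample.int(J, config$n_ivs)
  flags[iv_idx] <- "valid"
  gamma[iv_idx] <- draw_dist(config$gamma_dist, config$n_ivs)
  n_invalid <- round(config$invalid_frac * config$n_ivs)
  if (n_invalid > 0) {
    invalid_idx <- sample(iv_idx, n_invalid)
    flags[invalid_idx] <- "invalid"
    alpha[invalid_idx] <- stats::rnorm(n_invalid, 0, config$alpha_sd)
  }
  structure(
    list(gamma = gamma, alpha = alpha, phi = config$phi,
         iv_flags = factor(flags, levels = c("null", "valid", "invalid"))),
    class = "effect_set"
  )
}

#' Simulate one cohort from the structural model
#'
#' Generates genotypes and the confounder/exposure/outcome triplet for `n`
#' individuals from realized effects.  Uses the current RNG state.
#'
#' @param config a [scenario_config()].
#' @param effects an `"effect_set"` from [draw_effects()], or one with a
#'   modified `gamma` (high-heterogeneity regeneration).
#' @param n number of individuals.
#' @param theta causal effect used for the outcome equation; defaults to
#'   `config$theta`.
#' @return An object of class `"sim_cohort"`: list with `genotypes`
#'   (`n x n_snps` integer matrix of 0/1/2 dosages, columns `snp1..snpJ`),
#'   `U`, `X`, `Y` (numeric vectors), `true_params` and `iv_flags`.
#' @export
#' @examples
#' cfg <- scenario_config(n_small = 20)
#' set.seed(1)
#' eff <- draw_effects(cfg)
#' cohort <- simulate_cohort(cfg, eff, 20)
#' str(cohort$genotypes)
simulate_cohort <- function(config, effects, n, theta = config$theta) {
  stopifnot(inherits(config, "scenario_config"), inherits(effects, "effect_set"))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  J <- config$n_snps
  if (length(effects$gamma) != J)
    stop("effects are dimensioned for a different n_snps", call. = FALSE)
  G <- matrix(stats::rbinom(n * J, 2L, config$maf), nrow = n, ncol = J,
              dimnames = list(NULL, paste0("snp", seq_len(J))))
  U <- drop(G %*% effects$phi) + stats::rnorm(n, 0, config$noise_sd)
  X <- drop(G %*% effects$gamma) + config$theta_ux * U +
    stats::rnorm(n, 0, config$noise_sd)
  Y <- drop(G %*% effects$alpha) + theta * X + config$theta_uy * U +
    stats::rnorm(n, 0, config$noise_sd)
  new_sim_cohort(G, U, X, Y, effects, theta)
}

new_sim_cohort <- function(G, U, X, Y, effects, theta) {
  structure(
    list(genotypes = G, U = U, X = X, Y = Y,
         true_params = list(gamma = effects$gamma, alpha = effects$alpha,
                            phi = effects$phi, theta = theta),
         iv_flags = effects$iv_flags),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d individuals x %d SNPs (%d instruments, %d invalid)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$iv_flags != "null"), sum(x$iv_flags == "invalid")))
  invisible(x)
}

#' Generate a paired GWAS / small-cohort dataset
#'
#' Produces the two linked datasets of one benchmark replicate: a large
#' external GWAS cohort and a small multiomics cohort, coupled according to
#' the configured heterogeneity mode:
#' \describe{
#'   \item{homogeneous}{the small cohort is a uniform subsample (without
#'     replacement) of the GWAS individuals' genotypes, confounder and
#'     exposure; its outcome is regenerated from those rows and the scenario
#'     \eqn{\theta} with fresh noise.}
#'   \item{low}{the small cohort is regenerated from the same realized
#'     effect vectors.}
#'   \item{high}{\eqn{\gamma} is redrawn from `gamma_dist_high` for instrument
#'     SNPs before the small cohort is regenerated.}
#' }
#' Uses the current RNG state.
#'
#' @param config a [scenario_config()].
#' @param effects optional pre-drawn `"effect_set"`; drawn here if `NULL`.
#' @return A list with components `gwas` and `small`, both `"sim_cohort"`
#'   objects.  In homogeneous mode the subsample row indices are attached to
#'   `small` as attribute `"rows"`.
#' @export
make_paired_datasets <- function(config, effects = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(effects)) effects <- draw_effects(config)
  gwas <- simulate_cohort(config, effects, config$n_gwas)
  small <- switch(config$heterogeneity,
    homogeneous = {
      rows <- sample.int(config$n_gwas, config$n_small)
      G <- gwas$genotypes[rows, , drop = FALSE]
      U <- gwas$U[rows]
      X <- gwas$X[rows]
      Y <- drop(G %*% effects$alpha) + config$theta * X +
        config$theta_uy * U + stats::rnorm(config$n_small, 0, config$noise_sd)
      out <- new_sim_cohort(G, U, X, Y, effects, config$theta)
      attr(out, "rows") <- rows
      out
    },
    low = simulate_cohort(config, effects, config$n_small),
    high = {
      eff2 <- effects
      iv <- effects$iv_flags != "null"
      eff2$gamma[iv] <- draw_dist(config$gamma_dist_high, sum(iv))
      simulate_cohort(config, eff2, config$n_small)
    }
  )
  list(gwas = gwas, small = small)
}

#' Permute SNP identities of a cohort
#'
#' Randomly reassigns SNP identifiers to genotype columns, breaking the
#' SNP-feature linkage that instrument selection relies on while leaving all
#' marginal genotype distributions intact.  Used for the specificity
#' (robustness) check: after randomization, discoveries should collapse to
#' near zero.
#'
#' @param x a `"sim_cohort"` or `"cohort_data"` object.
#' @return A perturbed copy of `x` with attribute `"snp_permutation"`, the
#'   permutation `perm` such that output column `j` holds the genotypes that
#'   previously carried the identifier of column `perm[j]`.
#' @export
randomize_snp_identities <- function(x) {
  UseMethod("randomize_snp_identities")
}

#' @export
randomize_snp_identities.sim_cohort <- function(x) {
  J <- ncol(x$genotypes)
  perm <- sample.int(J)
  out <- x
  # keep identifiers (and downstream per-SNP labelling) fixed, shuffle columns
  cn <- colnames(out$genotypes)
  out$genotypes <- out$genotypes[, perm, drop = FALSE]
  colnames(out$genotypes) <- cn
  attr(out, "snp_permutation") <- perm
  out
}

#' @export
randomize_snp_identities.cohort_data <- function(x) {
  J <- ncol(x$genotypes)
  perm <- sample.int(J)
  out <- x
  cn <- colnames(out$genotypes)
  out$genotypes <- out$genotypes[, perm, drop = FALSE]
  colnames(out$genotypes) <- cn
  attr(out, "snp_permutation") <- perm
  out
}

#' Serialize a scenario configuration to YAML
#'
#' @param config a [scenario_config()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$gamma_dist <- unclass(x$gamma_dist)
  x$gamma_dist_high <- unclass(x$gamma_dist_high)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path file written by [write_scenario()] (or hand-authored with the
#'   same fields; missing fields fall back to the defaults of
#'   [scenario_config()]).
#' @return A `"scenario_config"`.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  as_dist <- function(d) {
    if (is.null(d)) return(NULL)
    if (d$kind == "uniform") dist_uniform(d$min, d$max)
    else dist_truncnorm(d$mean, d$sd, d$lower, d$upper)
  }
  args <- x[setdiff(names(x), c("gamma_dist", "gamma_dist_high"))]
  if (!is.null(x$gamma_dist)) args$gamma_dist <- as_dist(x$gamma_dist)
  if (!is.null(x$gamma_dist_high)) args$gamma_dist_high <- as_dist(x$gamma_dist_high)
  do.call(scenario_config, args)
}

#' Export a simulated cohort to TSV files
#'
#' Writes `genotypes.tsv` (samples x SNPs dosages) and `traits.tsv`
#' (`U`, `X`, `Y`) into `dir`; mainly a debugging aid.
#'
#' @param cohort a `"sim_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- data.frame(sample = seq_len(nrow(cohort$genotypes)), cohort$genotypes,
                  check.names = FALSE)
  utils::write.table(g, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- data.frame(sample = g$sample, U = cohort$U, X = cohort$X, Y = cohort$Y)
  utils::write.table(tr, file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
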