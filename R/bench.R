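BENCH_METHODS <- c("dual", "fdr_mr", "min_mr", "gwas_mr", "pearson", "spearman")
MR_METHODS <- c("dual", "fdr_mr", "min_mr", "gwas_mr")

# Deterministic per-replicate seed stream: one root seed yields a reproducible
# vector of child seeds, so any single replicate can be re-run in isolation
# and results do not depend on how replicates are batched across workers.
replicate_seeds <- function(root_seed, n) {
  set.seed(root_seed)
  sample.int(2147483646L, n)
}

#' Run a single benchmark replicate
#'
#' Executes one end-to-end replicate of the simulation study: draw effects,
#' generate the paired GWAS / small-cohort data, derive per-SNP summary
#' statistics (SNP-exposure in both cohorts, SNP-outcome in the small
#' cohort), select instruments under each requested strategy, fit the IVW
#' estimator, and run the Pearson/Spearman baselines on the small cohort's
#' exposure-outcome pair.  Deterministic given `(seed, rep_index)`.
#'
#' @param config a [scenario_config()].
#' @param rep_index replicate number (1-based).
#' @param seed root seed; defaults to `config$seed`.
#' @param methods subset of
#'   `c("dual", "fdr_mr", "min_mr", "gwas_mr", "pearson", "spearman")`.
#' @param alpha_internal,alpha_external,q selection thresholds (see the
#'   `select_iv_*` functions).
#' @param engine `"cpp"` (one-pass compiled generator for the GWAS stage,
#'   the default) or `"r"` (reference implementation via
#'   [make_paired_datasets()] and [batch_summary()]); the two agree
#'   distributionally but consume the RNG differently.
#' @param randomize_small if `TRUE`, SNP identities of the small cohort are
#'   permuted before summary statistics are computed (the robustness check:
#'   selection evidence no longer points at the right genotype columns).
#' @param ivw_model variance model passed to [mr_ivw()]; the benchmark
#'   default `"auto"` mirrors the standard MR software (random-effects SE
#'   with 4+ instruments, fixed-effects otherwise).
#' @return A data frame with one row per method: `rep`, `method`, `estimate`,
#'   `pvalue`, `n_iv`.
#' @export
run_replicate <- function(config, rep_index, seed = config$seed,
                          methods = BENCH_METHODS,
                          alpha_internal = 0.05, alpha_external = 0.05,
                          q = 0.05, engine = c("cpp", "r"),
                          randomize_small = FALSE,
                          ivw_model = c("auto", "fixed", "random")) {
  engine <- match.arg(engine)
  ivw_model <- match.arg(ivw_model)
  if (is.null(seed)) stop("a root seed is required", call. = FALSE)
  rs <- replicate_seeds(seed, rep_index)
  set.seed(rs[rep_index])
  out <- replicate_core(config, methods, alpha_internal, alpha_external, q,
                        engine, randomize_small, ivw_model)
  out$rep <- rep_index
  out[, c("rep", "method", "estimate", "pvalue", "n_iv")]
}

replicate_core <- function(config, methods, alpha_internal, alpha_external,
                           q, engine, randomize_small = FALSE,
                           ivw_model = "auto") {
  methods <- match.arg(methods, BENCH_METHODS, several.ok = TRUE)
  effects <- draw_effects(config)
  J <- config$n_snps
  need_mr <- any(methods %in% MR_METHODS)

  if (engine == "cpp") {
    keep <- if (config$heterogeneity == "homogeneous")
      sample.int(config$n_gwas, config$n_small) else integer()
    gw <- .sim_cohort_stats_cpp(
      config$n_gwas, config$maf, effects$gamma, effects$alpha, effects$phi,
      config$theta, config$theta_ux, config$theta_uy, config$noise_sd, keep)
    gwas_p <- two_sided_t_p(gw$beta_x / gw$se_x, config$n_gwas - 2L)
    small <- if (config$heterogeneity == "homogeneous") {
      G <- gw$G_keep
      colnames(G) <- paste0("snp", seq_len(J))
      U <- gw$U_keep
      X <- gw$X_keep
      Y <- drop(G %*% effects$alpha) + config$theta * X +
        config$theta_uy * U + stats::rnorm(config$n_small, 0, config$noise_sd)
      new_sim_cohort(G, U, X, Y, effects, config$theta)
    } else if (config$heterogeneity == "low") {
      simulate_cohort(config, effects, config$n_small)
    } else {
      eff2 <- effects
      iv <- effects$iv_flags != "null"
      eff2$gamma[iv] <- draw_dist(config$gamma_dist_high, sum(iv))
      simulate_cohort(config, eff2, config$n_small)
    }
  } else {
    pair <- make_paired_datasets(config, effects)
    gstats <- batch_summary(pair$gwas$genotypes, pair$gwas$X,
                            trait_id = "exposure")
    gwas_p <- gstats$pvalue
    small <- pair$small
  }

  if (randomize_small) small <- randomize_snp_identities(small)

  stats_x <- batch_summary(small$genotypes, small$X, trait_id = "exposure")
  stats_y <- batch_summary(small$genotypes, small$Y, trait_id = "outcome")
  ext <- external_evidence(stats_x$snp_id, gwas_pvalue = gwas_p, n_tests = J)

  rows <- list()
  for (m in intersect(methods, MR_METHODS)) {
    ivs <- switch(m,
      dual = select_iv_dual(stats_x, ext, alpha_internal, alpha_external),
      fdr_mr = select_iv_fdr(stats_x, q),
      min_mr = select_iv_min(stats_x, q),
      gwas_mr = select_iv_gwas(ext, alpha_external))
    idx <- match(ivs$snp_ids, stats_x$snp_id)
    # degenerate columns carry no usable exposure effect
    idx <- idx[!is.na(stats_x$beta[idx]) & stats_x$beta[idx] != 0]
    fit <- mr_ivw(stats_x$beta[idx], stats_y$beta[idx], stats_y$se[idx],
                  iv_ids = stats_x$snp_id[idx], model = ivw_model)
    rows[[m]] <- data.frame(method = m, estimate = fit$theta_hat,
                            pvalue = fit$pvalue, n_iv = fit$n_iv)
  }
  if ("pearson" %in% methods) {
    pr <- pearson_test(small$X, small$Y)
    rows$pearson <- data.frame(method = "pearson", estimate = pr$estimate,
                               pvalue = pr$pvalue, n_iv = NA_integer_)
  }
  if ("spearman" %in% methods) {
    sp <- spearman_test(small$X, small$Y)
    rows$spearman <- data.frame(method = "spearman", estimate = sp$estimate,
                                pvalue = sp$pvalue, n_iv = NA_integer_)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

two_sided_t_p <- function(tval, df) 2 * stats::pt(-abs(tval), df = df)

#' Run a full benchmark (many replicates of one scenario)
#'
#' Replicates [run_replicate()] `n_reps` times under per-replicate child
#' seeds derived from one root seed, so results are independent of worker
#' count and any replicate can be reproduced in isolation.
#'
#' @inheritParams run_replicate
#' @param n_reps number of replicates (default `config$n_reps`).
#' @param workers number of parallel workers (forked via the parallel
#'   package when available; default 1).
#' @return A data frame of class `"benchmark_result"` (rows =
#'   replicates x methods) with the scenario attached as attribute
#'   `"config"`.
#' @export
#' @examples
#' cfg <- scenario_config(theta = 0.6, n_small = 100, n_gwas = 2000,
#'                        gamma_dist = dist_uniform(1, 1.5), seed = 7)
#' res <- run_benchmark(cfg, n_reps = 5, methods = c("dual", "pearson"))
#' evaluate(res)
run_benchmark <- function(config, n_reps = config$n_reps,
                          seed = config$seed,
                          methods = BENCH_METHODS,
                          alpha_internal = 0.05, alpha_external = 0.05,
                          q = 0.05, engine = c("cpp", "r"),
                          randomize_small = FALSE, workers = 1L,
                          ivw_model = c("auto", "fixed", "random")) {
  engine <- match.arg(engine)
  ivw_model <- match.arg(ivw_model)
  if (is.null(seed)) stop("a root seed is required", call. = FALSE)
  rs <- replicate_seeds(seed, n_reps)
  one <- function(i) {
    set.seed(rs[i])
    out <- replicate_core(config, methods, alpha_internal, alpha_external, q,
                          engine, randomize_small, ivw_model)
    out$rep <- i
    out
  }
  res <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE) &&
               .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n_reps), one, mc.cores = workers)
  } else {
    lapply(seq_len(n_reps), one)
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out <- out[, c("rep", "method", "estimate", "pvalue", "n_iv")]
  attr(out, "config") <- config
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Evaluate a benchmark run: power / FDR and estimate summaries
#'
#' Converts per-replicate p-values into the scenario-level operating
#' characteristics.  When the true effect is nonzero the flagged fraction is
#' reported as `power`; under the null it is reported as `fdr` (the fraction
#' of replicates falsely declared significant).  Two decision modes:
#' \describe{
#'   \item{raw}{a replicate is a discovery when `p < alpha`;}
#'   \item{bh}{BH adjustment is first applied across all replicates of a
#'     method as one family (the reading of the published null-FDR tables
#'     consistent with their magnitudes and the stated BH usage).}
#' }
#' Replicates with no instruments (missing p) are never discoveries but stay
#' in the denominator.
#'
#' @param results a `"benchmark_result"` from [run_benchmark()], or any data
#'   frame with `method`, `pvalue`, `estimate`, `n_iv`.
#' @param theta_true true causal effect; defaults to the attached scenario's
#'   `theta`.
#' @param alpha decision threshold (default 0.05).
#' @param mode `"raw"` or `"bh"`.
#' @return A data frame of class `"evaluation_result"`: one row per method
#'   with `metric` (power/fdr), `value`, `mean_estimate`, `sd_estimate`,
#'   `n_reps`, `n_reps_effective` (replicates with at least one instrument)
#'   and `decision_mode`.
#' @export
evaluate <- function(results, theta_true = NULL, alpha = 0.05,
                     mode = c("raw", "bh")) {
  mode <- match.arg(mode)
  if (is.null(theta_true)) {
    cfg <- attr(results, "config")
    if (is.null(cfg)) stop("theta_true is required when results carry no config",
                           call. = FALSE)
    theta_true <- cfg$theta
  }
  metric <- if (theta_true != 0) "power" else "fdr"
  rows <- lapply(split(seq_len(nrow(results)), results$method), function(ii) {
    p <- results$pvalue[ii]
    est <- results$estimate[ii]
    niv <- results$n_iv[ii]
    flag <- if (mode == "bh") mr_decide(p, alpha, "bh-family")
            else mr_decide(p, alpha, "raw")
    data.frame(
      method = results$method[ii][1],
      metric = metric,
      value = mean(flag),
      mean_estimate = mean(est, na.rm = TRUE),
      sd_estimate = stats::sd(est, na.rm = TRUE),
      n_reps = length(ii),
      n_reps_effective = if (all(is.na(niv))) length(ii) else sum(niv > 0, na.rm = TRUE),
      decision_mode = mode,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(match(out$method, BENCH_METHODS)), ]
  rownames(out) <- NULL
  class(out) <- c("evaluation_result", "data.frame")
  out
}

#' Build a grid of scenario configurations
#'
#' Cartesian product of sample sizes, invalid-instrument fractions,
#' heterogeneity modes and causal effects, holding all other parameters
#' fixed.
#'
#' @param n_small,invalid_frac,heterogeneity,theta vectors of levels.
#' @param ... further arguments passed to [scenario_config()] (e.g.
#'   `gamma_dist`, `n_gwas`, `seed`).
#' @return A list of `"scenario_config"` objects.
#' @export
benchmark_grid <- function(n_small = c(50L, 100L, 200L, 300L),
                           invalid_frac = c(0, 0.3, 0.5),
                           heterogeneity = "homogeneous",
                           theta = c(0, 0.6), ...) {
  grid <- expand.grid(n_small = n_small, invalid_frac = invalid_frac,
                      heterogeneity = heterogeneity, theta = theta,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    scenario_config(n_small = grid$n_small[i],
                    invalid_frac = grid$invalid_frac[i],
                    heterogeneity = grid$heterogeneity[i],
                    theta = grid$theta[i], ...)
  })
}

#' Run and evaluate a list of scenarios
#'
#' @param configs list of [scenario_config()] objects (see
#'   [benchmark_grid()]).
#' @param n_reps replicates per scenario (default: each config's own).
#' @param mode decision mode passed to [evaluate()].
#' @param workers parallel workers, applied within each scenario; results are
#'   worker-count independent by the per-replicate seeding contract.
#' @inheritParams run_benchmark
#' @return A data frame: one row per scenario x method, with scenario
#'   descriptors (`n_small`, `invalid_frac`, `heterogeneity`, `theta`)
#'   prepended to the [evaluate()] columns.
#' @export
run_grid <- function(configs, n_reps = NULL, seed = NULL,
                     methods = BENCH_METHODS, mode = c("raw", "bh"),
                     alpha_internal = 0.05, alpha_external = 0.05, q = 0.05,
                     engine = c("cpp", "r"), workers = 1L,
                     ivw_model = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  ivw_model <- match.arg(ivw_model)
  rows <- lapply(configs, function(cfg) {
    nr <- if (is.null(n_reps)) cfg$n_reps else n_reps
    sd_ <- if (is.null(seed)) cfg$seed else seed
    res <- run_benchmark(cfg, n_reps = nr, seed = sd_, methods = methods,
                         alpha_internal = alpha_internal,
                         alpha_external = alpha_external, q = q,
                         engine = engine, workers = workers,
                         ivw_model = ivw_model)
    ev <- evaluate(res, theta_true = cfg$theta, mode = mode)
    cbind(data.frame(n_small = cfg$n_small, invalid_frac = cfg$invalid_frac,
                     heterogeneity = cfg$heterogeneity, theta = cfg$theta),
          ev)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Write an evaluation/grid table to TSV
#'
#' @param x a data frame from [evaluate()] or [run_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Density plot of per-replicate effect estimates by method
#'
#' Visual comparison of estimator variability across methods (IVW causal
#' estimates vs correlation coefficients), one density per method.
#'
#' @param x a `"benchmark_result"` from [run_benchmark()].
#' @param methods methods to draw (default: all present).
#' @param ... passed to [graphics::plot()].
#' @export
plot.benchmark_result <- function(x, methods = unique(x$method), ...) {
  keep <- x$method %in% methods & !is.na(x$estimate)
  dens <- lapply(split(x$estimate[keep], droplevels(factor(x$method[keep]))),
                 stats::density)
  if (!length(dens)) stop("no estimates to plot", call. = FALSE)
  xr <- range(unlist(lapply(dens, `[[`, "x")))
  yr <- c(0, max(unlist(lapply(dens, `[[`, "y"))))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "effect estimate",
                 ylab = "density", ...)
  for (i in seq_along(dens)) graphics::lines(dens[[i]], col = i, lwd = 2)
  graphics::legend("topright", legend = names(dens), col = seq_along(dens),
                   lwd = 2, bty = "n")
  invisible(x)
}
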