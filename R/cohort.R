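#' Assemble a multiomics cohort for causal screening
#'
#' Validated container for everything the screening pipeline consumes:
#' genotypes with genomic annotation, phosphosite and protein abundance
#' matrices (log-scale, features x samples, missing values allowed), sample
#' covariates, gene regions and the prior SNP list.  All matrices must share
#' one ordered set of sample identifiers; use [load_cohort()] to build one
#' from files with automatic sample reconciliation.
#'
#' @param genotypes samples x SNPs integer matrix (0/1/2 dosages, `NA`
#'   allowed), with SNP identifiers as column names and sample identifiers as
#'   row names.
#' @param snp_info data frame with columns `id`, `chrom`, `pos` (1-based),
#'   aligned with the genotype columns.
#' @param phospho phosphosites x samples numeric matrix (row names = site
#'   identifiers, column names = sample identifiers).
#' @param phospho_genes named character vector mapping each phosphosite to
#'   its host gene.
#' @param protein proteins x samples numeric matrix.
#' @param protein_genes named character vector mapping each protein to its
#'   gene.
#' @param covariates samples x k data frame / matrix (e.g. age, sex, smoking
#'   status), row names = sample identifiers.
#' @param gene_regions data frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param prior_snps character vector of SNP identifiers with prior evidence
#'   of affecting phosphorylation.
#' @return An object of class `"cohort_data"`.
#' @export
cohort_data <- function(genotypes, snp_info, phospho, phospho_genes,
                        protein, protein_genes, covariates, gene_regions,
                        prior_snps) {
  genotypes <- as.matrix(genotypes)
  phospho <- as.matrix(phospho)
  protein <- as.matrix(protein)
  samples <- rownames(genotypes)
  if (is.null(samples)) stop("genotypes need sample row names", call. = FALSE)
  if (!identical(colnames(phospho), samples) ||
      !identical(colnames(protein), samples) ||
      !identical(rownames(as.data.frame(covariates)), samples))
    stop("sample identifiers are not aligned across matrices; use load_cohort()",
         call. = FALSE)
  if (!identical(as.character(snp_info$id), colnames(genotypes)))
    stop("snp_info rows must align with genotype columns", call. = FALSE)
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype dosages must be 0, 1 or 2", call. = FALSE)
  missing_genes <- setdiff(unname(phospho_genes[rownames(phospho)]),
                           gene_regions$gene)
  if (length(missing_genes))
    stop("phosphosite host gene(s) missing from gene_regions: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  structure(
    list(genotypes = genotypes, snp_info = snp_info,
         phospho = phospho, phospho_genes = phospho_genes,
         protein = protein, protein_genes = protein_genes,
         covariates = as.data.frame(covariates),
         gene_regions = gene_regions,
         prior_snps = as.character(prior_snps)),
    class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("Multiomics cohort\n")
  cat(sprintf("  samples: %d\n", nrow(x$genotypes)))
  cat(sprintf("  SNPs: %d (%d with prior evidence)\n",
              ncol(x$genotypes), length(intersect(colnames(x$genotypes),
                                                  x$prior_snps))))
  cat(sprintf("  phosphosites: %d; proteins: %d\n",
              nrow(x$phospho), nrow(x$protein)))
  cat(sprintf("  covariates: %s\n", paste(colnames(x$covariates),
                                          collapse = ", ")))
  invisible(x)
}

#' Screen a cohort for phosphosite-to-protein causal links
#'
#' The end-to-end one-sample MR pipeline over a [cohort_data()] object:
#' \enumerate{
#'   \item drop phosphosites/proteins with missingness above `max_missing`;
#'   \item drop SNPs with variation rate below `variation_min` or MAF at or
#'     below `maf_min`;
#'   \item form candidate pairs: phosphosite (exposure) x protein (outcome)
#'     with Pearson prefilter p below `alpha_prefilter`;
#'   \item per phosphosite, select instruments among SNPs in the host gene's
#'     cis window that appear in the prior list, requiring a
#'     covariate-adjusted SNP-phosphosite p below `alpha_internal`, then
#'     greedily LD-prune at `r2_max`;
#'   \item per surviving pair, compute covariate-adjusted SNP-protein
#'     statistics and fit the fixed-effects IVW estimator;
#'   \item BH-adjust across all fitted pairs; links with adjusted p below
#'     `q_links` are flagged significant.
#' }
#' All regressions/correlations are complete-case with a floor of
#' `min_samples` observations.  Pairs mapping to the same gene are allowed
#' but flagged (`same_gene`).  Stage-by-stage counts are recorded in
#' `stage_log`.
#'
#' @param cohort a [cohort_data()] object.
#' @param alpha_internal SNP-exposure selection threshold (default 0.05).
#' @param alpha_prefilter exposure-outcome Pearson prefilter threshold
#'   (default 0.05).
#' @param q_links BH threshold on links (default 0.05).
#' @param r2_max LD pruning threshold (default 0.2).
#' @param cis_window cis window in bp (default 1 Mb).
#' @param maf_min,variation_min,max_missing quality filters (see
#'   [filter_snps()], [filter_features()]).
#' @param min_samples minimum complete cases per test (default 10).
#' @param min_iv minimum instruments required to fit a pair (default 1).
#' @param ivw_model variance model passed to [mr_ivw()].
#' @param pairs optional two-column data frame (`phosphosite`, `protein`)
#'   restricting which pairs may be tested (e.g. a pathway-derived
#'   restriction); default all pairs.
#' @return An object of class `"screen_result"`: `links` (a data frame with
#'   one row per fitted pair: `phosphosite`, `protein`, `theta_hat`, `se`,
#'   `z`, `pvalue`, `p_adj`, `n_iv`, `iv_ids`, `prefilter_r`, `prefilter_p`,
#'   `same_gene`, `significant`), `stage_log`, and the parameters used.
#' @export
screen_cohort <- function(cohort,
                          alpha_internal = 0.05,
                          alpha_prefilter = 0.05,
                          q_links = 0.05,
                          r2_max = 0.2,
                          cis_window = 1e6,
                          maf_min = 0.01,
                          variation_min = 0.10,
                          max_missing = 0.90,
                          min_samples = 10L,
                          min_iv = 1L,
                          ivw_model = c("auto", "fixed", "random"),
                          pairs = NULL) {
  ivw_model <- match.arg(ivw_model)
  stopifnot(inherits(cohort, "cohort_data"))
  params <- list(alpha_internal = alpha_internal,
                 alpha_prefilter = alpha_prefilter, q_links = q_links,
                 r2_max = r2_max, cis_window = cis_window, maf_min = maf_min,
                 variation_min = variation_min, max_missing = max_missing,
                 min_samples = min_samples, min_iv = min_iv,
                 ivw_model = ivw_model)
  log <- list()

  # (1) feature missingness filters
  sites <- filter_features(cohort$phospho, max_missing)
  prots <- filter_features(cohort$protein, max_missing)
  log$phosphosites <- c(before = nrow(cohort$phospho), after = length(sites))
  log$proteins <- c(before = nrow(cohort$protein), after = length(prots))

  # (2) SNP quality filters
  snps <- filter_snps(cohort$genotypes, maf_min, variation_min)
  log$snps <- c(before = ncol(cohort$genotypes), after = length(snps))
  snp_info <- cohort$snp_info[match(snps, cohort$snp_info$id), , drop = FALSE]

  # (3) Pearson prefilter over candidate pairs
  cand <- list()
  for (s in sites) {
    xs <- cohort$phospho[s, ]
    for (p in prots) {
      if (!is.null(pairs) &&
          !any(pairs$phosphosite == s & pairs$protein == p)) next
      yp <- cohort$protein[p, ]
      ok <- sum(!is.na(xs) & !is.na(yp))
      if (ok < max(4L, min_samples)) next
      pr <- tryCatch(pearson_test(xs, yp), error = function(e) NULL)
      if (is.null(pr) || pr$pvalue >= alpha_prefilter) next
      cand[[length(cand) + 1L]] <- data.frame(
        phosphosite = s, protein = p,
        prefilter_r = pr$estimate, prefilter_p = pr$pvalue)
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(phosphosite = character(), protein = character(),
               prefilter_r = numeric(), prefilter_p = numeric())
  log$pairs_prefilter <- c(candidates = length(sites) * length(prots),
                           passing = nrow(cand))

  # (4) per-phosphosite instrument selection (cis, prior, association, LD)
  covars <- covariate_matrix(cohort$covariates)
  iv_sets <- list()
  iv_stats <- list()
  for (s in unique(cand$phosphosite)) {
    gene <- unname(cohort$phospho_genes[s])
    region <- cohort$gene_regions[cohort$gene_regions$gene == gene, ][1, ]
    in_cis <- cis_filter(snp_info$chrom, snp_info$pos, region, cis_window)
    cand_snps <- snp_info$id[in_cis & snp_info$id %in% cohort$prior_snps]
    if (!length(cand_snps)) { iv_sets[[s]] <- character(); next }
    st <- batch_summary(cohort$genotypes[, cand_snps, drop = FALSE],
                        cohort$phospho[s, ], covariates = covars,
                        snp_ids = cand_snps, trait_id = s)
    sig <- !is.na(st$pvalue) & st$pvalue < alpha_internal & !st$degenerate &
      st$n_used >= min_samples
    if (!any(sig)) { iv_sets[[s]] <- character(); next }
    kept <- ld_prune(cohort$genotypes[, st$snp_id[sig], drop = FALSE],
                     st$pvalue[sig], r2_max, snp_ids = st$snp_id[sig])
    iv_sets[[s]] <- as.character(kept)
    iv_stats[[s]] <- st
  }
  log$sites_with_ivs <- c(candidates = length(unique(cand$phosphosite)),
                          with_ivs = sum(lengths(iv_sets) >= max(1L, min_iv)))
  log$iv_candidates_total <- sum(lengths(iv_sets))

  # (5) IVW per surviving pair (outcome stats cached per protein x SNP)
  outcome_cache <- new.env(parent = emptyenv())
  outcome_stat <- function(prot, snp) {
    key <- paste0(prot, "\r", snp)
    if (!is.null(v <- outcome_cache[[key]])) return(v)
    r <- adjusted_regression(cohort$genotypes[, snp], cohort$protein[prot, ],
                             covars)
    outcome_cache[[key]] <- r
    r
  }
  links <- list()
  for (i in seq_len(nrow(cand))) {
    s <- cand$phosphosite[i]; p <- cand$protein[i]
    ivs <- iv_sets[[s]]
    if (length(ivs) < max(1L, min_iv)) next
    st <- iv_stats[[s]]
    bx <- st$beta[match(ivs, st$snp_id)]
    out <- lapply(ivs, outcome_stat, prot = p)
    by <- vapply(out, `[[`, numeric(1), "beta")
    sy <- vapply(out, `[[`, numeric(1), "se")
    ny <- vapply(out, `[[`, numeric(1), "n_used")
    usable <- !is.na(by) & !is.na(sy) & sy > 0 & bx != 0 & ny >= min_samples
    if (sum(usable) < max(1L, min_iv)) next
    fit <- mr_ivw(bx[usable], by[usable], sy[usable], iv_ids = ivs[usable],
                  model = ivw_model)
    links[[length(links) + 1L]] <- data.frame(
      phosphosite = s, protein = p,
      theta_hat = fit$theta_hat, se = fit$se, z = fit$z, pvalue = fit$pvalue,
      n_iv = fit$n_iv, iv_ids = paste(fit$iv_ids, collapse = ","),
      prefilter_r = cand$prefilter_r[i], prefilter_p = cand$prefilter_p[i],
      same_gene = identical(unname(cohort$phospho_genes[s]),
                            unname(cohort$protein_genes[p])),
      stringsAsFactors = FALSE)
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(phosphosite = character(), protein = character(),
               theta_hat = numeric(), se = numeric(), z = numeric(),
               pvalue = numeric(), n_iv = integer(), iv_ids = character(),
               prefilter_r = numeric(), prefilter_p = numeric(),
               same_gene = logical(), stringsAsFactors = FALSE)

  # (6) BH across every fitted pair
  links$p_adj <- bh_adjust(links$pvalue)
  links$significant <- !is.na(links$p_adj) & links$p_adj < q_links
  links <- links[order(links$p_adj, links$pvalue), , drop = FALSE]
  rownames(links) <- NULL
  log$links <- c(tested = nrow(links), significant = sum(links$significant))

  structure(list(links = links, stage_log = log, params = params),
            class = "screen_result")
}

covariate_matrix <- function(cov) {
  if (is.null(cov) || !ncol(as.data.frame(cov))) return(NULL)
  # keep NA rows in place so covariates stay aligned with the sample axis
  mf <- stats::model.frame(~ ., data = as.data.frame(cov),
                           na.action = stats::na.pass)
  m <- stats::model.matrix(~ ., mf)
  m[, -1, drop = FALSE]  # drop the intercept; regressions add their own
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Phosphosite-protein causal screen\n")
  lg <- x$stage_log
  cat(sprintf("  features kept: %d/%d phosphosites, %d/%d proteins\n",
              lg$phosphosites["after"], lg$phosphosites["before"],
              lg$proteins["after"], lg$proteins["before"]))
  cat(sprintf("  SNPs kept: %d/%d\n", lg$snps["after"], lg$snps["before"]))
  cat(sprintf("  pairs passing prefilter: %d\n", lg$pairs_prefilter["passing"]))
  cat(sprintf("  pairs fitted: %d; significant links (BH < %.2g): %d\n",
              lg$links["tested"], x$params$q_links, lg$links["significant"]))
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  print(object)
  sig <- object$links[object$links$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("\nTop links:\n")
    print(utils::head(sig[, c("phosphosite", "protein", "theta_hat", "se",
                              "n_iv", "p_adj")], 10), row.names = FALSE)
  }
  invisible(object)
}

#' Export the significant links as a network edge list
#'
#' @param x a `"screen_result"` (or its `links` data frame).
#' @param path optional TSV path; when given, `<path>` receives the edge list
#'   and `<path>.nodes.tsv` the node degree table.
#' @return Invisibly, a list with `edges` (source = phosphosite, target =
#'   protein, weight = causal estimate, p_adj) and `nodes` (id, role,
#'   degree).
#' @export
export_network <- function(x, path = NULL) {
  links <- if (inherits(x, "screen_result"))
    x$links[x$links$significant, , drop = FALSE] else as.data.frame(x)
  edges <- data.frame(source = links$phosphosite, target = links$protein,
                      weight = links$theta_hat, p_adj = links$p_adj,
                      stringsAsFactors = FALSE)
  deg <- function(ids, role) {
    if (!length(ids)) return(data.frame(id = character(), role = character(),
                                        degree = integer()))
    tb <- table(ids)
    data.frame(id = names(tb), role = role, degree = as.integer(tb),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(deg(edges$source, "phosphosite"), deg(edges$target, "protein"))
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(edges = edges, nodes = nodes))
}

#' Write / read a causal-link table
#'
#' TSV round-trip of the `links` component of a screen result.
#'
#' @param links data frame of links.
#' @param path file path.
#' @export
write_links <- function(links, path) {
  utils::write.table(links, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_links
#' @export
read_links <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
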