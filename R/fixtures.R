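#' Specification of a synthetic screening cohort
#'
#' Parameters of the synthetic-cohort generator used to exercise the full
#' screening pipeline: genes laid out on synthetic chromosomes with
#' non-overlapping cis windows, LD-blocked cis SNPs, phosphosites driven by a
#' subset of their gene's cis SNPs, proteins generated from planted
#' phosphosite-to-protein causal links plus confounding, a prior SNP list
#' covering the causal SNPs, covariates with mild effects, and
#' missing-completely-at-random omics values.
#'
#' @param n_samples cohort size.
#' @param n_genes number of genes (one phosphosite and one protein each).
#' @param snps_per_gene cis SNPs per gene (one LD block).
#' @param causal_snps_per_site how many of a gene's cis SNPs drive its
#'   phosphosite.
#' @param ld_block_r pairwise genotype correlation within an LD block
#'   (exact under the ancestral-allele-copy construction).
#' @param n_causal_links number of planted phosphosite-to-protein links.
#' @param theta_causal causal effect of each planted link.
#' @param gamma_dist distribution of SNP-phosphosite effects
#'   ([dist_uniform()] / [dist_truncnorm()]).
#' @param theta_ux,theta_uy loadings of the shared confounder on
#'   phosphosites and proteins.
#' @param prior_coverage fraction of causal SNPs present in the prior list.
#' @param prior_decoy_frac fraction of non-causal SNPs added to the prior
#'   list as decoys.
#' @param missing_rate_omics MCAR missingness rate applied to both omics
#'   matrices.
#' @param maf_range each LD block's shared minor allele frequency is drawn
#'   uniformly from this range.
#' @param covariate_effects effects of (age, sex, smoking) added to every
#'   omics feature; age is centered before scaling.
#' @param seed optional seed applied by [make_fixture_cohort()].
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_samples = 200L,
                         n_genes = 12L,
                         snps_per_gene = 5L,
                         causal_snps_per_site = 3L,
                         ld_block_r = 0.5,
                         n_causal_links = 4L,
                         theta_causal = 0.6,
                         gamma_dist = dist_uniform(1.0, 1.5),
                         theta_ux = 0.75,
                         theta_uy = 0.75,
                         prior_coverage = 1.0,
                         prior_decoy_frac = 0.10,
                         missing_rate_omics = 0.05,
                         maf_range = c(0.1, 0.5),
                         covariate_effects = c(age = 0.02, sex = 0.3,
                                               smoking = 0.3),
                         seed = NULL) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               snps_per_gene = as.integer(snps_per_gene),
               causal_snps_per_site = as.integer(causal_snps_per_site),
               ld_block_r = ld_block_r,
               n_causal_links = as.integer(n_causal_links),
               theta_causal = theta_causal,
               gamma_dist = validate_dist(gamma_dist),
               theta_ux = theta_ux, theta_uy = theta_uy,
               prior_coverage = prior_coverage,
               prior_decoy_frac = prior_decoy_frac,
               missing_rate_omics = missing_rate_omics,
               maf_range = maf_range,
               covariate_effects = covariate_effects,
               seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(spec$n_samples >= 10L, spec$n_genes >= 2L,
            spec$causal_snps_per_site <= spec$snps_per_gene,
            spec$ld_block_r >= 0, spec$ld_block_r < 1,
            spec$prior_coverage >= 0, spec$prior_coverage <= 1,
            spec$prior_decoy_frac >= 0, spec$prior_decoy_frac <= 1,
            spec$missing_rate_omics >= 0, spec$missing_rate_omics < 1,
            is.finite(spec$theta_causal),
            2L * spec$n_causal_links <= spec$n_genes)
  class(spec) <- "fixture_spec"
  spec
}

GENES_PER_CHROM <- 4L
GENE_SPACING <- 2.5e6   # keeps the 1 Mb cis windows of neighbours disjoint
GENE_LENGTH <- 1e4
CHROM_OFFSET <- 2e6

# correlated Binomial(2, maf) genotypes for one LD block via ancestral-allele
# copying: per chromatid, each SNP copies a shared block allele with
# probability sqrt(r) and draws a fresh Bernoulli(maf) allele otherwise.
# Marginals stay Binomial(2, maf) and every SNP pair in the block has
# genotype correlation exactly r (blocks share one allele frequency).
ld_block_genotypes <- function(n, n_snps, r, maf) {
  stopifnot(length(maf) == 1L)
  cpy <- sqrt(r)
  draw_alleles <- function() {
    anc <- stats::rbinom(n, 1L, maf)
    fresh <- matrix(stats::rbinom(n * n_snps, 1L, maf), n, n_snps)
    use_anc <- matrix(stats::runif(n * n_snps) < cpy, n, n_snps)
    ifelse(use_anc, anc, fresh)
  }
  a <- draw_alleles() + draw_alleles()
  storage.mode(a) <- "integer"
  a
}

#' Generate a synthetic screening cohort with planted causal links
#'
#' Builds a [cohort_data()] object realizing the structure assumed by
#' [screen_cohort()], together with the ground-truth table of planted links.
#' Each phosphosite follows the structural exposure equation (cis-SNP
#' effects plus a shared standard-normal confounder and unit noise); each
#' planted link generates its target protein from the phosphosite with
#' effect `theta_causal`; all proteins receive the confounder, unit noise
#' and the covariate effects.
#'
#' @param spec a [fixture_spec()].
#' @return A list with `cohort` (a `"cohort_data"`) and `truth` (data frame
#'   `phosphosite`, `protein`, `theta`, `causal_snps`).
#' @export
#' @examples
#' fx <- make_fixture_cohort(fixture_spec(n_samples = 60, n_genes = 4,
#'                                        n_causal_links = 1, seed = 1))
#' fx$truth
make_fixture_cohort <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_samples
  G_genes <- spec$n_genes
  samples <- sprintf("S%03d", seq_len(n))

  # genomic layout: GENES_PER_CHROM genes per chromosome, spaced so that
  # neighbouring 1 Mb cis windows cannot overlap
  gene_ids <- sprintf("GENE%02d", seq_len(G_genes))
  chrom <- paste0("chr", (seq_len(G_genes) - 1L) %/% GENES_PER_CHROM + 1L)
  slot <- (seq_len(G_genes) - 1L) %% GENES_PER_CHROM
  start <- CHROM_OFFSET + slot * GENE_SPACING
  gene_regions <- data.frame(gene = gene_ids, chrom = chrom,
                             start = start, end = start + GENE_LENGTH,
                             stringsAsFactors = FALSE)

  # cis SNPs: one LD block per gene, placed within +-0.5 Mb of the gene
  snp_rows <- list()
  geno_blocks <- list()
  for (g in seq_len(G_genes)) {
    k <- spec$snps_per_gene
    maf <- stats::runif(1, spec$maf_range[1], spec$maf_range[2])
    pos <- sort(sample(seq(max(1, start[g] - 5e5), start[g] + GENE_LENGTH + 5e5),
                       k))
    ids <- sprintf("%s_rs%d", gene_ids[g], seq_len(k))
    snp_rows[[g]] <- data.frame(id = ids, chrom = chrom[g], pos = pos,
                                gene = gene_ids[g], maf = maf,
                                stringsAsFactors = FALSE)
    geno_blocks[[g]] <- ld_block_genotypes(n, k, spec$ld_block_r, maf)
  }
  snp_info <- do.call(rbind, snp_rows)
  genotypes <- do.call(cbind, geno_blocks)
  dimnames(genotypes) <- list(samples, snp_info$id)

  # covariates with mild effects on every omics feature
  covariates <- data.frame(age = sample(40:75, n, replace = TRUE),
                           sex = stats::rbinom(n, 1, 0.5),
                           smoking = stats::rbinom(n, 1, 0.4),
                           row.names = samples)
  ce <- spec$covariate_effects
  cov_term <- ce[["age"]] * (covariates$age - mean(covariates$age)) +
    ce[["sex"]] * covariates$sex + ce[["smoking"]] * covariates$smoking

  U <- stats::rnorm(n)  # shared confounder

  # phosphosites: one per gene, driven by a subset of its cis SNPs
  site_ids <- sprintf("%s_S%d", gene_ids, sample(10:999, G_genes))
  phospho <- matrix(NA_real_, G_genes, n, dimnames = list(site_ids, samples))
  causal_snps <- vector("list", G_genes)
  for (g in seq_len(G_genes)) {
    k <- spec$causal_snps_per_site
    snps_g <- snp_rows[[g]]$id
    csnp <- sample(snps_g, k)
    gamma <- draw_dist(spec$gamma_dist, k)
    causal_snps[[g]] <- csnp
    phospho[g, ] <- drop(genotypes[, csnp, drop = FALSE] %*% gamma) +
      spec$theta_ux * U + cov_term + stats::rnorm(n)
  }

  # proteins: planted links get theta_causal * phosphosite, others are
  # confounder + noise; every protein carries the covariate term
  prot_ids <- paste0("P_", gene_ids)
  protein <- matrix(NA_real_, G_genes, n, dimnames = list(prot_ids, samples))
  link_sites <- sample.int(G_genes, spec$n_causal_links)
  # target proteins on other genes, one target per protein
  pool <- setdiff(seq_len(G_genes), link_sites)
  link_prots <- pool[sample.int(length(pool), spec$n_causal_links)]
  target_of <- rep(NA_integer_, G_genes)
  target_of[link_prots] <- link_sites
  for (g in seq_len(G_genes)) {
    base <- spec$theta_uy * U + cov_term + stats::rnorm(n)
    if (!is.na(target_of[g]))
      base <- base + spec$theta_causal * phospho[target_of[g], ]
    protein[g, ] <- base
  }
  truth <- data.frame(
    phosphosite = site_ids[link_sites], protein = prot_ids[link_prots],
    theta = rep(spec$theta_causal, length(link_sites)),
    causal_snps = vapply(causal_snps[link_sites], paste, "", collapse = ","),
    stringsAsFactors = FALSE)

  # prior list: causal SNPs at the configured coverage, plus decoys
  causal_all <- unique(unlist(causal_snps))
  prior <- causal_all[stats::runif(length(causal_all)) < spec$prior_coverage]
  others <- setdiff(snp_info$id, causal_all)
  prior <- c(prior, others[stats::runif(length(others)) < spec$prior_decoy_frac])
  prior <- sort(prior)

  # MCAR missingness on both omics matrices
  if (spec$missing_rate_omics > 0) {
    phospho[stats::runif(length(phospho)) < spec$missing_rate_omics] <- NA
    protein[stats::runif(length(protein)) < spec$missing_rate_omics] <- NA
  }

  phospho_genes <- stats::setNames(gene_ids, site_ids)
  protein_genes <- stats::setNames(gene_ids, prot_ids)
  cohort <- cohort_data(genotypes, snp_info[, c("id", "chrom", "pos")],
                        phospho, phospho_genes, protein, protein_genes,
                        covariates, gene_regions, prior)
  list(cohort = cohort, truth = truth)
}

#' Write a fixture cohort to disk
#'
#' Emits every file the pipeline's readers consume: `genotypes.vcf` (VCF
#' 4.2 with GT fields), `phospho.tsv` and `protein.tsv` (feature, gene, one
#' column per sample), `covariates.tsv`, `regions.tsv` (1-based inclusive),
#' `prior_snps.tsv`, and `truth.tsv`.  Re-reading with [load_cohort()]
#' reproduces the in-memory object.
#'
#' @param cohort a `"cohort_data"`.
#' @param truth the planted-link table (may be `NULL`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, truth, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vcf(cohort$genotypes, cohort$snp_info, file.path(dir, "genotypes.vcf"))
  write_omics <- function(mat, genes, path) {
    df <- data.frame(feature = rownames(mat),
                     gene = unname(genes[rownames(mat)]),
                     mat, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_omics(cohort$phospho, cohort$phospho_genes,
              file.path(dir, "phospho.tsv"))
  write_omics(cohort$protein, cohort$protein_genes,
              file.path(dir, "protein.tsv"))
  cov <- data.frame(sample = rownames(cohort$covariates), cohort$covariates,
                    check.names = FALSE)
  utils::write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$gene_regions, file.path(dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("snp_id", cohort$prior_snps), file.path(dir, "prior_snps.tsv"))
  if (!is.null(truth))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# minimal VCF 4.2 writer (records sorted by chromosome then position)
write_vcf <- function(genotypes, snp_info, path) {
  ord <- order(snp_info$chrom, snp_info$pos)
  info <- snp_info[ord, , drop = FALSE]
  G <- genotypes[, ord, drop = FALSE]
  gt <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=phosmr",
    paste0("##contig=<ID=", unique(info$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(seq_len(nrow(info)), function(i) {
    calls <- ifelse(is.na(G[, i]), "./.", gt[G[, i] + 1L])
    paste(c(info$chrom[i], info$pos[i], info$id[i], "A", "G", ".", "PASS",
            ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
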