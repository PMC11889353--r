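#' External evidence for instrument eligibility
#'
#' Container for the external channel of instrument selection.  In simulation
#' mode the evidence is per-SNP p-values from the large external GWAS
#' (screened at a Bonferroni-adjusted threshold); in cohort mode it is
#' membership in a curated list of phosphorylation-related SNPs.  Both
#' channels may be present simultaneously; dual-evidence selection requires
#' every supplied channel to pass.
#'
#' @param snp_ids character vector of SNP identifiers.
#' @param gwas_pvalue optional numeric vector of raw GWAS p-values.
#' @param prior_member optional logical vector of prior-list membership.
#' @param n_tests number of tests behind the Bonferroni correction; defaults
#'   to the number of SNPs supplied.
#' @return An object of class `"external_evidence"`.
#' @export
external_evidence <- function(snp_ids, gwas_pvalue = NULL, prior_member = NULL,
                              n_tests = length(snp_ids)) {
  snp_ids <- as.character(snp_ids)
  if (is.null(gwas_pvalue) && is.null(prior_member))
    stop("supply at least one of gwas_pvalue / prior_member", call. = FALSE)
  if (!is.null(gwas_pvalue) && length(gwas_pvalue) != length(snp_ids))
    stop("gwas_pvalue length mismatch", call. = FALSE)
  if (!is.null(prior_member) && length(prior_member) != length(snp_ids))
    stop("prior_member length mismatch", call. = FALSE)
  structure(list(snp_ids = snp_ids, gwas_pvalue = gwas_pvalue,
                 prior_member = prior_member, n_tests = n_tests),
            class = "external_evidence")
}

new_iv_set <- function(snp_ids, strategy, provenance) {
  structure(list(snp_ids = as.character(snp_ids), strategy = strategy,
                 provenance = provenance), class = "iv_set")
}

#' @export
print.iv_set <- function(x, ...) {
  cat(sprintf("Instrument set (strategy '%s'): %d SNP(s)\n",
              x$strategy, length(x$snp_ids)))
  if (length(x$snp_ids))
    cat(" ", paste(utils::head(x$snp_ids, 10), collapse = ", "),
        if (length(x$snp_ids) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
length.iv_set <- function(x) length(x$snp_ids)

check_alignment <- function(internal, external) {
  if (!identical(as.character(internal$snp_id), external$snp_ids))
    stop("snp identifiers of internal and external evidence are misaligned",
         call. = FALSE)
}

#' Dual-evidence instrument selection
#'
#' The flagship selection rule: a SNP becomes an instrument when it is
#' supported both internally and externally.  Internal support is a raw
#' association p-value below `alpha_internal` in the small cohort (a
#' deliberately relaxed threshold — small cohorts rarely reach genome-wide
#' significance even for real effects).  External support is, per supplied
#' channel, a GWAS p-value below the Bonferroni-adjusted level
#' `alpha_external / n_tests`, and/or membership in the prior SNP list.
#' Requiring the conjunction controls the false-positive risk that the
#' relaxed internal threshold alone would incur.
#'
#' @param internal a `"summary_stats"` data frame for the SNP-exposure
#'   associations in the small cohort.
#' @param external an [external_evidence()] object aligned with `internal`.
#' @param alpha_internal raw internal threshold (default 0.05).
#' @param alpha_external familywise GWAS threshold before Bonferroni division
#'   (default 0.05).
#' @return An `"iv_set"`; its `provenance` records which criteria each
#'   selected SNP passed.
#' @export
select_iv_dual <- function(internal, external, alpha_internal = 0.05,
                           alpha_external = 0.05) {
  check_alignment(internal, external)
  pass_int <- !is.na(internal$pvalue) & internal$pvalue < alpha_internal &
    !internal$degenerate
  pass_ext <- rep(TRUE, nrow(internal))
  prov <- data.frame(snp_id = internal$snp_id, internal = pass_int)
  if (!is.null(external$gwas_pvalue)) {
    pg <- !is.na(external$gwas_pvalue) &
      external$gwas_pvalue < alpha_external / external$n_tests
    pass_ext <- pass_ext & pg
    prov$gwas <- pg
  }
  if (!is.null(external$prior_member)) {
    pm <- !is.na(external$prior_member) & external$prior_member
    pass_ext <- pass_ext & pm
    prov$prior <- pm
  }
  keep <- pass_int & pass_ext
  new_iv_set(internal$snp_id[keep], "dual", prov[keep, , drop = FALSE])
}

#' FDR-based instrument selection
#'
#' Selects every SNP whose Benjamini-Hochberg adjusted internal association
#' p-value falls below `q` — the conventional strategy for large cohorts,
#' included as a benchmark comparator.
#'
#' @param internal a `"summary_stats"` data frame.
#' @param q BH threshold (default 0.05).
#' @return An `"iv_set"`.
#' @export
select_iv_fdr <- function(internal, q = 0.05) {
  padj <- bh_adjust(internal$pvalue)
  keep <- !is.na(padj) & padj < q & !internal$degenerate
  new_iv_set(internal$snp_id[keep], "fdr_mr",
             data.frame(snp_id = internal$snp_id[keep],
                        p_adj = padj[keep]))
}

#' Minimum-p instrument selection
#'
#' Among the BH-significant SNPs (adjusted p below `q`), keeps the single SNP
#' with the smallest raw p-value; ties are broken by input order.  Empty when
#' nothing is BH-significant.
#'
#' @inheritParams select_iv_fdr
#' @return An `"iv_set"` with at most one SNP.
#' @export
select_iv_min <- function(internal, q = 0.05) {
  padj <- bh_adjust(internal$pvalue)
  cand <- which(!is.na(padj) & padj < q & !internal$degenerate)
  if (!length(cand))
    return(new_iv_set(character(), "min_mr",
                      data.frame(snp_id = character(), p = numeric())))
  best <- cand[which.min(internal$pvalue[cand])]
  new_iv_set(internal$snp_id[best], "min_mr",
             data.frame(snp_id = internal$snp_id[best],
                        p = internal$pvalue[best]))
}

#' GWAS-only instrument selection
#'
#' Selects SNPs on external GWAS evidence alone (raw GWAS p below
#' `alpha / n_tests`), ignoring the small cohort — the strategy of classical
#' two-sample MR, included as a benchmark comparator.
#'
#' @param external an [external_evidence()] object with `gwas_pvalue`.
#' @param alpha familywise threshold before Bonferroni division.
#' @return An `"iv_set"`.
#' @export
select_iv_gwas <- function(external, alpha = 0.05) {
  if (is.null(external$gwas_pvalue))
    stop("external evidence has no GWAS p-values", call. = FALSE)
  keep <- !is.na(external$gwas_pvalue) &
    external$gwas_pvalue < alpha / external$n_tests
  new_iv_set(external$snp_ids[keep], "gwas_mr",
             data.frame(snp_id = external$snp_ids[keep],
                        gwas_p = external$gwas_pvalue[keep]))
}

#' Greedy LD pruning
#'
#' Removes linked SNPs: candidates are visited in order of ascending p-value
#' (ties by input position) and a SNP is kept only if its squared Pearson
#' correlation with every already-kept SNP's genotypes is at most `r2_max`.
#' The most significant SNP of every linked group therefore survives.
#' Constant genotype columns carry no linkage information; their r-squared
#' against anything is treated as 0 and they are flagged.
#'
#' @param genotypes samples x SNPs dosage matrix over the candidate SNPs
#'   (the LD reference: in-sample genotypes or an external panel).
#' @param pvalues per-SNP p-values aligned with the columns.
#' @param r2_max maximum allowed squared correlation (default 0.2).
#' @param snp_ids identifiers; default `colnames(genotypes)`.
#' @return Character vector of surviving SNP identifiers, in input order;
#'   attribute `"flagged_constant"` lists constant columns encountered.
#' @export
ld_prune <- function(genotypes, pvalues, r2_max = 0.2,
                     snp_ids = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  J <- ncol(genotypes)
  stopifnot(length(pvalues) == J)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(J))
  if (J == 0L) return(character())
  sds <- apply(genotypes, 2L, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  ord <- order(pvalues, seq_len(J))
  kept <- integer()
  for (j in ord) {
    ok <- TRUE
    if (!constant[j]) {
      for (k in kept) {
        if (constant[k]) next
        r <- suppressWarnings(
          stats::cor(genotypes[, j], genotypes[, k],
                     use = "pairwise.complete.obs"))
        if (!is.na(r) && r * r > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, j)
  }
  out <- snp_ids[sort(kept)]
  attr(out, "flagged_constant") <- snp_ids[constant]
  out
}

#' Cis-window membership
#'
#' Flags SNPs lying within `window` base pairs of a feature's gene region:
#' same chromosome and position inside
#' `[max(1, start - window), end + window]`, boundaries inclusive (1-based
#' coordinates).
#'
#' @param snp_chrom,snp_pos chromosome labels and 1-based positions of SNPs.
#' @param region list or one-row data frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param window cis window in bp (default 1 Mb each side).
#' @return Logical vector, one entry per SNP.
#' @export
cis_filter <- function(snp_chrom, snp_pos, region, window = 1e6) {
  stopifnot(length(snp_chrom) == length(snp_pos))
  lo <- max(1, region$start - window)
  hi <- region$end + window
  as.character(snp_chrom) == as.character(region$chrom) &
    snp_pos >= lo & snp_pos <= hi
}

#' SNP quality filters
#'
#' Keeps SNPs with a variation rate (fraction of samples carrying at least
#' one alternate allele) of at least `variation_min` and a minor allele
#' frequency strictly above `maf_min`; MAF is the dosage-derived allele
#' frequency folded to at most 0.5.  Missing genotypes are ignored per SNP.
#'
#' @param genotypes samples x SNPs dosage matrix (0/1/2, `NA` allowed).
#' @param maf_min minimum MAF, exclusive (default 0.01).
#' @param variation_min minimum variation rate, inclusive (default 0.10).
#' @return Character vector of surviving SNP identifiers (column names).
#' @export
filter_snps <- function(genotypes, maf_min = 0.01, variation_min = 0.10) {
  genotypes <- as.matrix(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
  keep <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(FALSE)
    varrate <- mean(g > 0)
    af <- mean(g) / 2
    maf <- min(af, 1 - af)
    varrate >= variation_min && maf > maf_min
  }, logical(1))
  ids[keep]
}

#' Feature missingness filter
#'
#' Keeps omics features whose fraction of missing values does not exceed
#' `max_missing`.
#'
#' @param mat features x samples matrix (`NA` marks missing).
#' @param max_missing maximum tolerated missing fraction (default 0.90).
#' @return Character vector of surviving feature identifiers (row names).
#' @export
filter_features <- function(mat, max_missing = 0.90) {
  mat <- as.matrix(mat)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("feature", seq_len(nrow(mat)))
  keep <- rowMeans(is.na(mat)) <= max_missing
  ids[keep]
}
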