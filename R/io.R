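SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "23", "24")

#' Read genotypes from a VCF file
#'
#' Parses GT fields into 0/1/2 dosages: `0/0` (and `0|0`) is homozygous
#' reference, `0/1`, `1/0` and their phased forms are heterozygous, `1/1`
#' homozygous alternate; `./.` is recorded as missing.  Half-missing calls
#' (e.g. `./1`) are rejected with an error.  Only biallelic SNPs are kept;
#' multi-allelic or indel records are skipped with a logged count (or raise
#' an error in `strict` mode).  Sex-chromosome records are excluded by
#' default.
#'
#' @param path VCF file (plain or bgzipped; parsed with the vcfR package).
#' @param strict error on non-biallelic SNP records instead of skipping.
#' @param drop_sex_chromosomes exclude X/Y records (default `TRUE`).
#' @return A list with `genotypes` (samples x SNPs integer matrix) and
#'   `snp_info` (data frame `id`, `chrom`, `pos`); skipped-record counts are
#'   attached as attribute `"skipped"`.
#' @export
read_genotypes <- function(path, strict = FALSE, drop_sex_chromosomes = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  skipped <- c(multiallelic = 0L, not_snp = 0L, sex_chromosome = 0L)

  biallelic_snp <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  skipped["multiallelic"] <- sum(grepl(",", fix$ALT, fixed = TRUE))
  skipped["not_snp"] <- sum(!biallelic_snp) - skipped["multiallelic"]
  if (strict && any(!biallelic_snp))
    stop(sum(!biallelic_snp), " non-biallelic-SNP record(s) in strict mode",
         call. = FALSE)
  keep <- biallelic_snp
  if (drop_sex_chromosomes) {
    sex <- fix$CHROM %in% SEX_CHROMS
    skipped["sex_chromosome"] <- sum(sex & keep)
    keep <- keep & !sex
  }
  if (!any(keep)) stop("no usable SNP records in ", path, call. = FALSE)

  gt <- vcfR::extract.gt(vcf[keep, ], element = "GT")
  dos <- gt_to_dosage(gt)
  ids <- fix$ID[keep]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[keep][noid], ":", fix$POS[keep][noid])
  genotypes <- t(dos)
  colnames(genotypes) <- ids
  info <- data.frame(id = ids, chrom = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     stringsAsFactors = FALSE)
  structure(list(genotypes = genotypes, snp_info = info), skipped = skipped)
}

gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
           "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  known <- gt %in% names(map)
  missing_gt <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  bad <- !known & !missing_gt
  if (any(bad))
    stop("unsupported GT call(s), e.g. '", gt[bad][1],
         "' (half-missing or multi-allelic genotypes are rejected)",
         call. = FALSE)
  out <- matrix(map[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  out
}

#' Read genotypes from a dosage TSV
#'
#' Expected columns: `id`, `chrom`, `pos`, then one 0/1/2 column per sample
#' (NA tokens: empty, `NA`, `nan`).
#'
#' @param path TSV file.
#' @return Same shape as [read_genotypes()].
#' @export
read_dosages <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA", "nan"))
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("dosage TSV must have columns id, chrom, pos", call. = FALSE)
  samples <- setdiff(names(df), need)
  G <- t(as.matrix(df[, samples, drop = FALSE]))
  storage.mode(G) <- "integer"
  colnames(G) <- df$id
  rownames(G) <- samples
  list(genotypes = G,
       snp_info = data.frame(id = df$id, chrom = df$chrom,
                             pos = as.integer(df$pos),
                             stringsAsFactors = FALSE))
}

#' Read an omics matrix (features x samples)
#'
#' Expected columns: `feature`, `gene`, then one numeric column per sample;
#' NA tokens are empty strings, `NA` and `nan`.
#'
#' @param path TSV file.
#' @return A list with `matrix` (features x samples) and `genes` (named
#'   character vector feature -> gene).
#' @export
read_omics_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA", "nan"))
  if (!all(c("feature", "gene") %in% names(df)))
    stop("omics TSV must have columns feature, gene", call. = FALSE)
  samples <- setdiff(names(df), c("feature", "gene"))
  m <- as.matrix(df[, samples, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature
  list(matrix = m, genes = stats::setNames(df$gene, df$feature))
}

#' Read sample covariates
#'
#' Expected columns: `sample`, then covariate columns (e.g. `age`, `sex`,
#' `smoking`).
#'
#' @param path TSV file.
#' @return Data frame with sample identifiers as row names.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "nan"))
  if (!"sample" %in% names(df))
    stop("covariates TSV must have a 'sample' column", call. = FALSE)
  rownames(df) <- df$sample
  df$sample <- NULL
  df
}

#' Read gene regions
#'
#' BED-like TSV with columns `gene`, `chrom`, `start`, `end`; coordinates
#' are declared 1-based inclusive.
#'
#' @param path TSV file.
#' @return Data frame with those columns.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("regions TSV must have columns gene, chrom, start, end", call. = FALSE)
  df[, need]
}

#' Read a prior SNP list
#'
#' One SNP identifier per line (a header line `snp_id` is tolerated);
#' additional columns (e.g. a substrate gene) are ignored.
#'
#' @param path TSV file.
#' @return Character vector of SNP identifiers.
#' @export
read_prior_snps <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  ids <- as.character(df[[1]])
  ids <- ids[!ids %in% c("snp_id", "")]
  unique(ids)
}

#' Load a screening cohort from files
#'
#' Reads every input of the screening pipeline and assembles a
#' [cohort_data()], reconciling sample sets: the intersection of samples
#' across genotypes, both omics matrices and covariates is used (in genotype
#' order) and any dropped samples are reported with a warning.
#'
#' @param dir directory holding default-named files (as written by
#'   [write_fixture()]); or supply explicit paths.
#' @param vcf,dosages path to genotypes (exactly one of the two).
#' @param phospho,protein,covariates,regions,priors remaining input paths.
#' @return A `"cohort_data"` object.
#' @export
load_cohort <- function(dir = NULL,
                        vcf = file.path(dir, "genotypes.vcf"),
                        dosages = NULL,
                        phospho = file.path(dir, "phospho.tsv"),
                        protein = file.path(dir, "protein.tsv"),
                        covariates = file.path(dir, "covariates.tsv"),
                        regions = file.path(dir, "regions.tsv"),
                        priors = file.path(dir, "prior_snps.tsv")) {
  geno <- if (!is.null(dosages)) read_dosages(dosages) else read_genotypes(vcf)
  ph <- read_omics_matrix(phospho)
  pr <- read_omics_matrix(protein)
  cov <- read_covariates(covariates)
  reg <- read_regions(regions)
  prior <- read_prior_snps(priors)

  samples <- Reduce(intersect, list(rownames(geno$genotypes),
                                    colnames(ph$matrix),
                                    colnames(pr$matrix),
                                    rownames(cov)))
  all_samples <- unique(c(rownames(geno$genotypes), colnames(ph$matrix),
                          colnames(pr$matrix), rownames(cov)))
  dropped <- setdiff(all_samples, samples)
  if (length(dropped))
    warning("dropped ", length(dropped),
            " sample(s) absent from some inputs: ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
  if (!length(samples)) stop("no samples shared across inputs", call. = FALSE)

  cohort_data(geno$genotypes[samples, , drop = FALSE], geno$snp_info,
              ph$matrix[, samples, drop = FALSE], ph$genes,
              pr$matrix[, samples, drop = FALSE], pr$genes,
              cov[samples, , drop = FALSE], reg, prior)
}
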