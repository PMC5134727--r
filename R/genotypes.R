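#' Genotype matrix container
#'
#' Holds an n subjects x m SNPs dosage matrix counting copies of the A1
#' (typically minor) allele, together with SNP metadata.  Dosages are 0, 1, 2
#' or `NA` (missing); after [mean_impute_genotypes()] they may be fractional
#' values in \[0, 2\].
#'
#' @param dosages numeric matrix, subjects in rows, SNPs in columns.
#' @param snps data frame of SNP metadata with columns `snp_id`, `chrom`,
#'   `pos`, `a1`, `a2`.  Defaults are synthesized from column names.
#' @param subject_ids character vector of subject identifiers.
#' @return an object of class `"genotype_matrix"`: a list with elements
#'   `dosages`, `snps`, `subject_ids`.
#' @export
genotype_matrix <- function(dosages, snps = NULL, subject_ids = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(dosages) %||% sprintf("S%04d", seq_len(n))
  }
  if (anyDuplicated(subject_ids)) stop_wgp("duplicate subject ids")
  if (is.null(snps)) {
    ids <- colnames(dosages) %||% sprintf("snp%06d", seq_len(m))
    snps <- data.frame(snp_id = ids,
                       chrom = as.character(rep_len(1:22, m)),
                       pos = seq_len(m) * 1000L,
                       a1 = "A", a2 = "G",
                       stringsAsFactors = FALSE)
  }
  snps$chrom <- as.character(snps$chrom)
  if (anyDuplicated(snps$snp_id)) stop_wgp("duplicate SNP ids")
  if (nrow(snps) != m) stop_wgp("snps metadata does not match dosage columns")
  ok <- snps$chrom %in% c(as.character(1:22), "X", "Y", "MT")
  if (!all(ok)) stop_wgp("invalid chromosome label: ", snps$chrom[!ok][1])
  rng <- range(dosages, na.rm = TRUE)
  if (m > 0 && n > 0 && (rng[1] < 0 || rng[2] > 2))
    stop_wgp("dosages must lie in [0, 2]")
  dimnames(dosages) <- list(subject_ids, snps$snp_id)
  structure(list(dosages = dosages, snps = snps, subject_ids = subject_ids),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' A1-allele frequencies and minor allele frequencies
#'
#' @param g a [genotype_matrix()].
#' @return `allele_freq`: per-SNP frequency of the counted (A1) allele from
#'   non-missing dosages; `maf`: the folded minor allele frequency
#'   `pmin(p, 1 - p)`.
#' @export
allele_freq <- function(g) colMeans(g$dosages, na.rm = TRUE) / 2

#' @rdname allele_freq
#' @export
maf <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

subset_snps <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$snps[keep, , drop = FALSE], g$subject_ids)
}

qc_report <- function(step, n_input, kept, removed_ids) {
  structure(list(step = step, n_input = n_input, n_final = n_input - length(removed_ids),
                 removed = removed_ids), class = "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat(sprintf("QC step '%s': %d -> %d SNPs (%d removed)\n",
              x$step, x$n_input, x$n_final, length(x$removed)))
  invisible(x)
}

#' Retain autosomal SNPs only
#'
#' @param g a [genotype_matrix()].
#' @return list with elements `genotypes` (filtered) and `report`.
#' @export
autosome_filter <- function(g) {
  keep <- g$snps$chrom %in% as.character(1:22)
  list(genotypes = subset_snps(g, keep),
       report = qc_report("autosome", ncol(g$dosages), keep, g$snps$snp_id[!keep]))
}

#' Minor-allele-frequency filter
#'
#' Removes SNPs whose minor allele frequency, computed from non-missing
#' dosages over all subjects, falls below `threshold`.
#'
#' @param g a [genotype_matrix()].
#' @param threshold MAF floor in \[0, 0.5\]; SNPs with MAF < threshold drop.
#' @return list with `genotypes` and `report`.
#' @export
maf_filter <- function(g, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  keep <- maf(g) >= threshold
  if (!any(keep)) stop_wgp("MAF filter removed every SNP")
  list(genotypes = subset_snps(g, keep),
       report = qc_report("maf", ncol(g$dosages), keep, g$snps$snp_id[!keep]))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the Hardy-Weinberg expectation computed from the sample allele frequency.
#' Monomorphic SNPs return p = 1.  Requires raw (unimputed) integer dosages.
#'
#' @param g a [genotype_matrix()].
#' @param statistic return the chi-square statistics instead of p-values
#'   (monomorphic SNPs give statistic 0).
#' @return named numeric vector of per-SNP p-values (or statistics).
#' @export
hwe_test <- function(g, statistic = FALSE) {
  d <- g$dosages
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
    stop_wgp("hwe_test requires integer dosages (run before imputation)")
  out <- vapply(seq_len(ncol(d)), function(i) {
    x <- d[, i]; x <- x[!is.na(x)]
    if (!length(x)) stop_wgp("SNP ", colnames(d)[i], " has no observed genotypes")
    n0 <- sum(x == 0); n1 <- sum(x == 1); n2 <- sum(x == 2)
    n <- n0 + n1 + n2
    p <- (2 * n2 + n1) / (2 * n)
    if (p <= 0 || p >= 1) return(if (statistic) 0 else 1)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n0, n1, n2) - e)^2 / e)
    if (statistic) stat else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1), USE.NAMES = FALSE)
  names(out) <- colnames(d)
  out
}

#' Hardy-Weinberg filter
#'
#' @param g a [genotype_matrix()].
#' @param p_threshold retain SNPs with HWE p-value >= this (default 0.001).
#' @return list with `genotypes` and `report`.
#' @export
hwe_filter <- function(g, p_threshold = 0.001) {
  keep <- hwe_test(g) >= p_threshold
  if (!any(keep)) stop_wgp("HWE filter removed every SNP")
  list(genotypes = subset_snps(g, keep),
       report = qc_report("hwe", ncol(g$dosages), keep, g$snps$snp_id[!keep]))
}

#' Standard genotype QC pipeline
#'
#' Applies, in order: autosome filter, MAF filter, HWE filter.  The order is
#' recorded in the report; the pipeline is idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param maf_threshold MAF floor (default 0.05).
#' @param hwe_p HWE p-value floor (default 0.001).
#' @return list with `genotypes` and `report` (a list of per-step
#'   [qc_report]s plus totals).
#' @export
qc_pipeline <- function(g, maf_threshold = 0.05, hwe_p = 0.001) {
  a <- autosome_filter(g)
  m <- maf_filter(a$genotypes, maf_threshold)
  h <- hwe_filter(m$genotypes, hwe_p)
  list(genotypes = h$genotypes,
       report = list(order = c("autosome", "maf", "hwe"),
                     n_input_snps = ncol(g$dosages),
                     autosome = a$report, maf = m$report, hwe = h$report,
                     n_final = ncol(h$genotypes$dosages)))
}

#' Mean-impute missing genotype dosages
#'
#' Missing dosages are replaced by the SNP's mean dosage over non-missing
#' subjects (kept fractional, not rounded), which biases association toward
#' the null.
#'
#' @param g a [genotype_matrix()].
#' @return a [genotype_matrix()] with no missing values.
#' @export
mean_impute_genotypes <- function(g) {
  d <- g$dosages
  nmiss <- colSums(is.na(d))
  if (any(nmiss == nrow(d)))
    stop_wgp("SNP entirely missing: ",
             paste(colnames(d)[nmiss == nrow(d)], collapse = ", "))
  if (any(nmiss > 0)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  g$dosages <- d
  g
}
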