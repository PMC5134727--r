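#' Kinship (genomic relatedness) matrix container
#'
#' @param values n x n symmetric numeric matrix with subject dimnames.
#' @param n_snps number of SNPs used to build the matrix.
#' @param scheme weighting-scheme provenance label.
#' @return an object of class `"kinship_matrix"`.
#' @export
kinship_matrix <- function(values, n_snps = NA_integer_, scheme = "standard") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_wgp("kinship matrix must be square")
  if (max(abs(values - t(values))) > 1e-10)
    stop_wgp("kinship matrix must be symmetric (tolerance 1e-10)")
  if (is.null(rownames(values)))
    dimnames(values) <- list(sprintf("S%04d", seq_len(nrow(values))),
                             sprintf("S%04d", seq_len(nrow(values))))
  structure(list(values = values, subject_ids = rownames(values),
                 n_snps = n_snps, scheme = scheme),
            class = "kinship_matrix")
}

#' @exportS3Method base::print
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d subjects, scheme=%s, %s SNPs, mean diag %.3f\n",
              nrow(x$values), x$scheme,
              ifelse(is.na(x$n_snps), "?", x$n_snps),
              mean(diag(x$values))))
  invisible(x)
}

#' @export
dim.kinship_matrix <- function(x) dim(x$values)

standardize_dosages <- function(g, check_weights = NULL) {
  p <- allele_freq(g)
  v <- 2 * p * (1 - p)
  bad <- v == 0
  if (any(bad)) {
    w <- check_weights %||% rep(1, length(v))
    if (any(w[bad] != 0))
      stop_wgp("monomorphic SNP with nonzero weight (",
               paste(utils::head(g$snps$snp_id[bad & w != 0], 3), collapse = ", "),
               "); apply QC filters first")
  }
  sweep(sweep(g$dosages, 2, 2 * p, `-`), 2,
        ifelse(v > 0, sqrt(v), 1), `/`)
}

#' Compute a weighted genomic relatedness matrix
#'
#' The GRM is a weighted sum of products of standardized SNP dosages:
#' `A_jk = sum_i w_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)) / sum_i w_i`
#' with `p_i` the sample allele frequency of the counted allele.  The
#' `1/(2p(1-p))` factor is the standard inverse-variance weight under which
#' rarer alleles count more heavily; `weights` act on this standardized
#' scale, so uniform weights give the standard GRM with diagonal near 1.
#' The normalization by `sum(w)` makes the matrix invariant to rescaling the
#' weight vector.
#'
#' @param g a [genotype_matrix()] with no missing dosages (impute first).
#' @param weights per-SNP non-negative weights on the standardized scale, or
#'   `NULL` for uniform (standard inverse-variance) weighting; alternatively a
#'   `snp_weights` object from a scheme constructor.
#' @param scheme provenance label stored on the result.
#' @return a [kinship_matrix()].
#' @export
compute_grm <- function(g, weights = NULL, scheme = NULL) {
  if (anyNA(g$dosages)) stop_wgp("missing dosages: run mean_impute_genotypes first")
  m <- ncol(g$dosages)
  if (m < 1) stop_wgp("need at least one SNP")
  if (inherits(weights, "snp_weights")) {
    scheme <- scheme %||% weights$scheme
    if (!identical(weights$snp_id, g$snps$snp_id))
      weights <- weights$weight[match(g$snps$snp_id, weights$snp_id)]
    else weights <- weights$weight
    if (anyNA(weights)) stop_wgp("weight vector does not cover the SNP set")
  }
  w <- weights %||% rep(1, m)
  if (length(w) != m) stop_wgp("weight length != number of SNPs")
  if (any(w < 0)) stop_wgp("weights must be non-negative")
  if (sum(w) <= 0) stop_wgp("all weights are zero")
  z <- standardize_dosages(g, check_weights = w)
  a <- tcrossprod(sweep(z, 2, w, `*`), z) / sum(w)
  a <- (a + t(a)) / 2
  dimnames(a) <- list(g$subject_ids, g$subject_ids)
  kinship_matrix(a, n_snps = sum(w > 0), scheme = scheme %||% "standard")
}

new_snp_weights <- function(snp_id, weight, scheme) {
  if (any(weight < 0)) stop_wgp("weights must be non-negative")
  if (all(weight == 0)) stop_wgp("all-zero weight vector under scheme ", scheme)
  structure(list(snp_id = snp_id, weight = weight, scheme = scheme),
            class = "snp_weights")
}

.scheme_conjunction <- function(weight, mode, scores_ids, g) {
  if (mode == "replace") return(weight)
  if (is.null(g)) stop_wgp("mode='conjunction' needs the genotype matrix")
  p <- allele_freq(g)[match(scores_ids, g$snps$snp_id)]
  v <- 2 * p * (1 - p)
  weight * ifelse(v > 0, 1 / v, 0)
}

#' SNP weighting schemes from functional priority scores
#'
#' `apply_scheme_w1` weights each SNP by its total priority score;
#' `apply_scheme_w2` uses only the regulatory-evidence component (eQTL /
#' chromatin state), ignoring the minor-allele-frequency component;
#' `apply_scheme_nzw` drops SNPs with zero W1 weight and applies standard
#' inverse-variance weights to the retained subset.  By default scheme
#' weights replace the uniform weight on the standardized (inverse-variance)
#' scale; `mode = "conjunction"` multiplies in a second `1/(2p(1-p))` factor.
#'
#' @param scores data frame with `snp_id`, `total_score`,
#'   `regulatory_component` (as from [simulate_priority_scores()]).
#' @param mode `"replace"` (default) or `"conjunction"`.
#' @param g genotype matrix (required for `"conjunction"` and for NZW).
#' @return a `snp_weights` object; for NZW, a list with the subset
#'   `genotypes` and the `weights`.
#' @export
apply_scheme_w1 <- function(scores, mode = c("replace", "conjunction"), g = NULL) {
  mode <- match.arg(mode)
  new_snp_weights(scores$snp_id,
                  .scheme_conjunction(scores$total_score, mode, scores$snp_id, g),
                  "W1")
}

#' @rdname apply_scheme_w1
#' @export
apply_scheme_w2 <- function(scores, mode = c("replace", "conjunction"), g = NULL) {
  mode <- match.arg(mode)
  new_snp_weights(scores$snp_id,
                  .scheme_conjunction(scores$regulatory_component, mode,
                                      scores$snp_id, g),
                  "W2")
}

#' @rdname apply_scheme_w1
#' @export
apply_scheme_nzw <- function(scores, g) {
  idx <- match(g$snps$snp_id, scores$snp_id)
  if (anyNA(idx)) stop_wgp("scores do not cover the SNP set")
  keep <- scores$total_score[idx] > 0
  if (!any(keep)) stop_wgp("NZW subset is empty (all scores zero)")
  sub <- subset_snps(g, keep)
  list(genotypes = sub,
       weights = new_snp_weights(sub$snps$snp_id,
                                 rep(1, ncol(sub$dosages)), "NZW"))
}

#' Build a GRM under a named weighting scheme
#'
#' @param g a [genotype_matrix()] (imputed).
#' @param scheme one of `"standard"`, `"W1"`, `"W2"`, `"NZW"`.
#' @param scores priority-score table (required for W1/W2/NZW).
#' @return a [kinship_matrix()] with scheme provenance.
#' @export
grm_by_scheme <- function(g, scheme = c("standard", "W1", "W2", "NZW"),
                          scores = NULL) {
  scheme <- match.arg(scheme)
  if (scheme != "standard" && is.null(scores))
    stop_wgp("scheme ", scheme, " requires priority scores")
  switch(scheme,
    standard = compute_grm(g),
    W1 = compute_grm(g, apply_scheme_w1(scores)),
    W2 = compute_grm(g, apply_scheme_w2(scores)),
    NZW = {
      nz <- apply_scheme_nzw(scores, g)
      compute_grm(nz$genotypes, nz$weights, scheme = "NZW")
    })
}

#' Genotype principal components from a kinship matrix
#'
#' Eigenvectors of the double-centered kinship matrix, ordered by descending
#' eigenvalue and scaled by the square root of the eigenvalue.
#'
#' @param k a [kinship_matrix()] (or symmetric matrix).
#' @param n_components number of components (default 6).
#' @return n x n_components matrix of per-subject scores.
#' @export
genotype_pca <- function(k, n_components = 6) {
  v <- if (inherits(k, "kinship_matrix")) k$values else as.matrix(k)
  if (max(abs(v - t(v))) > 1e-8) stop_wgp("kinship matrix must be symmetric")
  n <- nrow(v)
  if (n_components > n - 1) stop_wgp("n_components must be <= n - 1")
  cv <- sweep(v, 1, rowMeans(v))
  cv <- sweep(cv, 2, colMeans(cv))
  e <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(n_components)], 0)
  pcs <- e$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(lam), n_components)
  dimnames(pcs) <- list(rownames(v), paste0("PC", seq_len(n_components)))
  pcs
}

#' Covariate similarity matrix
#'
#' Categorical columns are one-hot encoded, all columns standardized to zero
#' mean and unit variance, and the similarity is the average cross-product
#' over columns — the same algebra as the GRM with unit weights.  Covariates
#' must be complete (mean-impute first); zero-variance columns are dropped
#' with a warning.
#'
#' @param covariates data frame of covariates (a `subject_id` column, if
#'   present, supplies the ids).
#' @return a [kinship_matrix()] with scheme `"covariates"`.
#' @export
covariate_similarity <- function(covariates) {
  ids <- covariates$subject_id %||% rownames(covariates) %||%
    sprintf("S%04d", seq_len(nrow(covariates)))
  covariates <- covariates[, setdiff(names(covariates), "subject_id"),
                           drop = FALSE]
  if (ncol(covariates) < 1) stop_wgp("need at least one covariate column")
  if (anyNA(covariates)) stop_wgp("covariates contain NA: impute first")
  cols <- list()
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- x
    } else {
      x <- as.factor(x)
      for (lv in levels(x)) cols[[paste0(nm, ".", lv)]] <- as.numeric(x == lv)
    }
  }
  xm <- do.call(cbind, cols)
  sds <- apply(xm, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance covariate column(s): ",
            paste(colnames(xm)[sds == 0], collapse = ", "))
    xm <- xm[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
    if (ncol(xm) == 0) stop_wgp("no covariate columns with variance remain")
  }
  z <- scale(xm)
  a <- tcrossprod(z) / ncol(z)
  a <- (a + t(a)) / 2
  dimnames(a) <- list(ids, ids)
  kinship_matrix(a, n_snps = NA_integer_, scheme = "covariates")
}

#' Convex combination of similarity matrices
#'
#' @param matrices list of [kinship_matrix()] objects over identical subjects.
#' @param mixing non-negative weights summing to 1 (tolerance 1e-9).
#' @return a [kinship_matrix()] with scheme `"combined"`.
#' @export
combine_similarity <- function(matrices, mixing) {
  stopifnot(length(matrices) == length(mixing), length(matrices) >= 1)
  if (any(mixing < 0)) stop_wgp("mixing weights must be non-negative")
  if (abs(sum(mixing) - 1) > 1e-9) stop_wgp("mixing weights must sum to 1")
  ids <- matrices[[1]]$subject_ids
  for (m in matrices)
    if (!identical(m$subject_ids, ids)) stop_wgp("subject id mismatch")
  acc <- matrix(0, length(ids), length(ids))
  for (i in seq_along(matrices)) acc <- acc + mixing[i] * matrices[[i]]$values
  dimnames(acc) <- list(ids, ids)
  kinship_matrix(acc, n_snps = matrices[[1]]$n_snps,
                 scheme = paste0("combined(",
                                 paste(vapply(matrices, `[[`, "", "scheme"),
                                       collapse = "+"), ")"))
}

#' Read/write a kinship matrix as lower-triangle TSV
#'
#' Columns: id1, id2, n_snps, value; one row per pair with id1 index >= id2
#' index (GCTA-style lower triangle including the diagonal).
#'
#' @param k a [kinship_matrix()].
#' @param path output path.
#' @export
write_grm <- function(k, path) {
  n <- nrow(k$values)
  idx <- which(lower.tri(k$values, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id1 = k$subject_ids[idx[, 1]], id2 = k$subject_ids[idx[, 2]],
                   n_snps = k$n_snps, value = k$values[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ids <- unique(c(df$id2, df$id1))
  n <- length(ids)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(df$id1, ids); j <- match(df$id2, ids)
  v[cbind(i, j)] <- df$value
  v[cbind(j, i)] <- df$value
  kinship_matrix(v, n_snps = df$n_snps[1], scheme = "loaded")
}
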