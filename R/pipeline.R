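#' End-to-end run configuration
#'
#' Bundles every stage parameter for [run_pipeline()]: simulation (or input
#' paths), QC thresholds, GRM weighting scheme, predictor, evaluation
#' protocol and seed.  Defaults mirror the analysis the package implements:
#' MAF floor 0.05, HWE p floor 0.001, 75/25 splits repeated 25 times.
#'
#' @param sim a [sim_config()] describing the synthetic cohort, or `NULL`
#'   when `plink_prefix` is given.
#' @param plink_prefix optional path prefix of a bed/bim/fam set to load
#'   instead of simulating.
#' @param maf_threshold,hwe_p QC thresholds.
#' @param scheme GRM weighting scheme: standard, W1, W2 or NZW.
#' @param predictor one of gblup, kriging, nb, lasso, svm.
#' @param use_covariates integrate covariate similarity into the kernel
#'   (GRM-based predictors only).
#' @param mixing length-2 mixing weights when `use_covariates`.
#' @param protocol `"split"` (repeated 75/25) or `"loo"`.
#' @param train_fraction,n_repeats split-protocol parameters.
#' @param n_perm label permutations per evaluation.
#' @param ridge G-BLUP regularizer (`NULL` = REML-derived).
#' @param seed run-level seed.
#' @param output_dir directory for stage artifacts; `NULL` for none.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(), plink_prefix = NULL,
                       maf_threshold = 0.05, hwe_p = 0.001,
                       scheme = c("standard", "W1", "W2", "NZW"),
                       predictor = c("gblup", "kriging", "nb", "lasso", "svm"),
                       use_covariates = FALSE, mixing = c(0.5, 0.5),
                       protocol = c("split", "loo"),
                       train_fraction = 0.75, n_repeats = 25,
                       n_perm = 199, ridge = NULL, seed = 1L,
                       output_dir = NULL) {
  scheme <- match.arg(scheme)
  predictor <- match.arg(predictor)
  protocol <- match.arg(protocol)
  stopifnot(maf_threshold >= 0, maf_threshold <= 0.5,
            hwe_p >= 0, hwe_p <= 1,
            train_fraction > 0, train_fraction < 1, n_repeats >= 1,
            n_perm >= 1)
  structure(list(sim = sim, plink_prefix = plink_prefix,
                 maf_threshold = maf_threshold, hwe_p = hwe_p,
                 scheme = scheme, predictor = predictor,
                 use_covariates = use_covariates, mixing = mixing,
                 protocol = protocol, train_fraction = train_fraction,
                 n_repeats = n_repeats, n_perm = n_perm, ridge = ridge,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

.pipeline_predictor <- function(config, K, g_qc, labels, covariates) {
  switch(config$predictor,
    gblup = if (config$use_covariates) {
      function(train_ids, test_ids, sd) {
        y_tr <- labels[match(train_ids, K$subject_ids)]
        predict_with_covariates(K, covariates, y_tr, train_ids, test_ids,
                                mixing = config$mixing, ridge = config$ridge)
      }
    } else {
      function(train_ids, test_ids, sd) {
        y_tr <- labels[match(train_ids, K$subject_ids)]
        gblup_predict(K, y_tr, train_ids, test_ids, ridge = config$ridge)
      }
    },
    kriging = function(train_ids, test_ids, sd) {
      y_tr <- labels[match(train_ids, K$subject_ids)]
      kriging_simple_predict(K, y_tr, train_ids, test_ids)
    },
    nb = function(train_ids, test_ids, sd) {
      tr <- match(train_ids, g_qc$subject_ids)
      te <- match(test_ids, g_qc$subject_ids)
      fit <- naive_bayes_wgp(subset_subjects(g_qc, tr), labels[tr])
      predict(fit, subset_subjects(g_qc, te))
    },
    lasso = function(train_ids, test_ids, sd) {
      tr <- match(train_ids, g_qc$subject_ids)
      te <- match(test_ids, g_qc$subject_ids)
      fit <- lasso_wgp(subset_subjects(g_qc, tr), labels[tr], seed = sd)
      predict(fit, subset_subjects(g_qc, te))
    },
    svm = function(train_ids, test_ids, sd) {
      tr <- match(train_ids, g_qc$subject_ids)
      te <- match(test_ids, g_qc$subject_ids)
      fit <- svm_wgp(subset_subjects(g_qc, tr), labels[tr])
      predict(fit, subset_subjects(g_qc, te))
    })
}

subset_subjects <- function(g, idx) {
  genotype_matrix(g$dosages[idx, , drop = FALSE], g$snps,
                  g$subject_ids[idx])
}

#' Run the full simulate -> QC -> GRM -> heritability -> predict -> evaluate
#' pipeline
#'
#' Executes every stage from one [run_config()] and returns a manifest
#' recording the configuration echo, QC report, variance components,
#' evaluation result and (when `output_dir` is set) paths and md5 checksums
#' of the written artifacts.
#'
#' @param config a [run_config()].
#' @return the run manifest (list), invisibly classed `"run_manifest"`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  # stage: input
  if (!is.null(config$plink_prefix))
    stop_wgp("external PLINK input needs a phenotype table; compose the ",
             "stage functions (read_plink, qc_pipeline, ...) directly")
  cohort <- simulate_cohort(config$sim)
  g <- cohort$genotypes
  # stage: QC + imputation
  qc <- qc_pipeline(g, config$maf_threshold, config$hwe_p)
  g_qc <- mean_impute_genotypes(qc$genotypes)
  # stage: phenotype (impute, dichotomize already done by the simulator)
  phen <- mean_impute_table(cohort$phenotypes)
  labels <- phen$label
  covariates <- cohort$covariates
  # stage: GRM
  K <- grm_by_scheme(g_qc, config$scheme, cohort$scores)
  # stage: heritability
  fit <- greml(phen$trait, K)
  # stage: predict + evaluate
  pred <- .pipeline_predictor(config, K, g_qc, labels, covariates)
  evalr <- if (config$protocol == "loo") {
    if (!config$predictor %in% c("gblup", "kriging"))
      stop_wgp("LOO protocol is defined for GRM-based predictors")
    loo_eval(K, labels, method = config$predictor, ridge = config$ridge,
             n_perm = config$n_perm, seed = derive_seed(config$seed, "eval"))
  } else {
    repeated_split_eval(pred, labels, K$subject_ids,
                        train_fraction = config$train_fraction,
                        n_repeats = config$n_repeats,
                        n_perm = config$n_perm,
                        seed = derive_seed(config$seed, "eval"))
  }
  manifest <- list(
    config = unclass(config),
    n_subjects = length(labels),
    qc = list(n_input_snps = qc$report$n_input_snps,
              n_final = qc$report$n_final,
              order = qc$report$order,
              n_removed = c(autosome = length(qc$report$autosome$removed),
                            maf = length(qc$report$maf$removed),
                            hwe = length(qc$report$hwe$removed))),
    grm = list(scheme = K$scheme, n_snps_used = K$n_snps),
    heritability = list(h2 = fit$h2, se_h2 = fit$se_h2,
                        sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                        loglik = fit$loglik, converged = fit$converged,
                        boundary = fit$boundary),
    evaluation = list(protocol = evalr$protocol, auc = evalr$auc,
                      ch_auc = evalr$ch_auc, p_empirical = evalr$p_empirical,
                      sd_auc = evalr$sd_auc,
                      per_repeat = evalr$per_repeat),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(grm = file.path(config$output_dir, "grm.tsv"),
               hsq = file.path(config$output_dir, "greml.json"),
               eval = file.path(config$output_dir, "evaluation.json"),
               manifest = file.path(config$output_dir, "manifest.json"))
    write_grm(K, paths["grm"])
    greml_as_json(fit, paths["hsq"])
    jsonlite::write_json(manifest$evaluation, paths["eval"],
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest$artifacts <- list(paths = as.list(paths[1:3]),
                               md5 = as.list(tools::md5sum(paths[1:3])))
    man_out <- manifest; man_out$elapsed_s <- NULL
    jsonlite::write_json(man_out, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", force = TRUE)
  }
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @exportS3Method base::print
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run: n=%d, %d/%d SNPs after QC, scheme=%s\n",
              x$n_subjects, x$qc$n_final, x$qc$n_input_snps, x$grm$scheme))
  cat(sprintf("  h2 = %.3f (SE %.3f); %s mean AUC %.3f (p %.4f)\n",
              x$heritability$h2, x$heritability$se_h2,
              x$evaluation$protocol, x$evaluation$auc,
              x$evaluation$p_empirical))
  invisible(x)
}

#' Compare GRM weighting schemes under shared randomness
#'
#' Runs the identical evaluation under each scheme with the same run-level
#' seed, so splits and permutations are shared, and reports per-scheme mean
#' AUC plus paired differences against the first scheme.
#'
#' @param config a [run_config()] (its `scheme` field is overridden).
#' @param schemes character vector of >= 2 schemes.
#' @return data frame: scheme, mean_auc, mean_ch_auc, mean_p,
#'   paired_diff_vs_first.
#' @export
compare_schemes <- function(config, schemes = c("standard", "NZW")) {
  stopifnot(length(schemes) >= 2)
  runs <- lapply(schemes, function(s) {
    cfg <- config; cfg$scheme <- s
    run_pipeline(cfg)
  })
  base_auc <- runs[[1]]$evaluation$per_repeat$auc
  data.frame(
    scheme = schemes,
    mean_auc = vapply(runs, function(r) r$evaluation$auc, numeric(1)),
    mean_ch_auc = vapply(runs, function(r) r$evaluation$ch_auc, numeric(1)),
    mean_p = vapply(runs, function(r) r$evaluation$p_empirical, numeric(1)),
    paired_diff_vs_first = vapply(runs, function(r)
      mean(r$evaluation$per_repeat$auc - base_auc), numeric(1)),
    stringsAsFactors = FALSE)
}
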