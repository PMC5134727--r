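#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the analysis cohort the package is designed around: 832
#' unrelated subjects, a post-QC MAF floor of 0.05, functional-priority
#' scores in \[0, 0.12\] with 43.1% of SNPs carrying score exactly zero
#' (259,156 of 455,481 SNPs retained by the non-zero-weight subset), and
#' longitudinal lung-pattern proportions NG 26.56%, NG-ED 20.55%, RG 26.68%,
#' RG-ED 21.27% with the remainder unclassified.  SNP count defaults to a
#' desk-scale 5,000.
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs.
#' @param maf_range pair of allele frequencies in (0, 0.5]; per-SNP
#'   frequencies are drawn uniformly from this interval.
#' @param h2_true narrow-sense heritability of the simulated trait in \[0,1\].
#' @param causal_fraction fraction of SNPs with nonzero effect, in (0, 1].
#' @param priority_informativeness enrichment (>= 0) of causal SNPs among
#'   SNPs with non-zero priority score; 0 means scores carry no information.
#' @param zero_score_fraction fraction of SNPs with priority score exactly 0.
#' @param covariate_spec list of covariate descriptors, each a list with
#'   `name`, `dist` ("normal" or "bernoulli"), `pars` (mean/sd or prob) and
#'   `effect` (per-SD effect on the trait).
#' @param missing_rate MCAR missingness rate for phenotype/covariate tables.
#' @param pattern_props named proportions for NG, NG-ED, RG, RG-ED lung
#'   patterns (remainder unclassified).
#' @param seed run-level integer seed; all stages derive named substreams.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 832, n_snps = 5000,
                       maf_range = c(0.05, 0.5), h2_true = 0.5,
                       causal_fraction = 0.05,
                       priority_informativeness = 0,
                       zero_score_fraction = 1 - 259156 / 455481,
                       covariate_spec = default_covariate_spec(),
                       missing_rate = 0,
                       pattern_props = c(NG = 0.2656, `NG-ED` = 0.2055,
                                         RG = 0.2668, `RG-ED` = 0.2127),
                       seed = 1L) {
  stopifnot(n_subjects >= 2, n_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            h2_true >= 0, h2_true <= 1,
            causal_fraction > 0, causal_fraction <= 1,
            priority_informativeness >= 0,
            zero_score_fraction >= 0, zero_score_fraction < 1,
            missing_rate >= 0, missing_rate < 1,
            all(pattern_props >= 0), sum(pattern_props) <= 1)
  structure(list(n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
                 maf_range = maf_range, h2_true = h2_true,
                 causal_fraction = causal_fraction,
                 priority_informativeness = priority_informativeness,
                 zero_score_fraction = zero_score_fraction,
                 covariate_spec = covariate_spec,
                 missing_rate = missing_rate,
                 pattern_props = pattern_props,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_covariate_spec <- function() {
  list(list(name = "age", dist = "normal", pars = c(8.95, 2.13), effect = 0),
       list(name = "sex_male", dist = "bernoulli", pars = 0.607, effect = 0),
       list(name = "trt_steroid", dist = "bernoulli", pars = 0.303, effect = 0),
       list(name = "height_cm", dist = "normal", pars = c(133.8, 13.82), effect = 0),
       list(name = "bmi", dist = "normal", pars = c(18.22, 3.41), effect = 0),
       list(name = "vitamin_d", dist = "normal", pars = c(37.81, 15.6), effect = 0))
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each SNP i receives a frequency p_i uniform on `maf_range`; dosages are
#' independent Binomial(2, p_i) draws per subject, so simulated SNPs satisfy
#' Hardy-Weinberg equilibrium by construction.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with autosomal chromosome/position labels.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects; m <- config$n_snps
  set.seed(derive_seed(config$seed, "genotypes"))
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  d <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  snps <- data.frame(snp_id = sprintf("snp%06d", seq_len(m)),
                     chrom = as.character(rep_len(1:22, m)),
                     pos = 10000L + 137L * seq_len(m),
                     a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  genotype_matrix(d, snps, sprintf("S%04d", seq_len(n)))
}

#' Simulate an additive polygenic phenotype with known heritability
#'
#' Effects for a causal subset are drawn i.i.d. Gaussian on standardized
#' genotypes with total genetic variance `h2_true`; environmental noise has
#' variance `1 - h2_true`, so the expected phenotypic variance is 1 and the
#' expected variance ratio equals `h2_true`.  Covariates with non-zero
#' `effect` add fixed contributions on top of the genetic + noise trait.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [sim_config()].
#' @param covariates optional data frame of simulated covariates (from
#'   [simulate_covariates()]); used only for specs with non-zero effects.
#' @return list with `phenotypes` (data frame: subject_id, trait, label) and
#'   `truth` (causal ids, effect vector, breeding values, realized h2).
#' @export
simulate_polygenic_phenotype <- function(genotypes, config, covariates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes$dosages); m <- ncol(genotypes$dosages)
  h2 <- config$h2_true
  m_causal <- max(1L, round(config$causal_fraction * m))
  if (h2 == 1 && m_causal == 0) stop_wgp("h2 = 1 requires causal SNPs")
  set.seed(derive_seed(config$seed, "phenotype"))
  causal <- sort(sample.int(m, m_causal))
  beta <- numeric(m)
  if (h2 > 0) beta[causal] <- stats::rnorm(m_causal, 0, sqrt(h2 / m_causal))
  p <- allele_freq(genotypes)
  sd_g <- sqrt(2 * p * (1 - p))
  if (any(sd_g == 0 & beta != 0)) {
    beta[sd_g == 0] <- 0  # monomorphic SNP cannot carry signal
  }
  z_beta <- ifelse(sd_g > 0, beta / sd_g, 0)
  g <- as.vector(genotypes$dosages %*% z_beta) - sum(2 * p * z_beta)
  e <- stats::rnorm(n, 0, sqrt(max(0, 1 - h2)))
  y <- g + e
  if (!is.null(covariates)) {
    for (cv in config$covariate_spec) {
      if (!is.null(cv$effect) && cv$effect != 0 && cv$name %in% names(covariates)) {
        x <- covariates[[cv$name]]
        y <- y + cv$effect * as.vector(scale(x))
      }
    }
  }
  lab <- dichotomize_about_mean(y)
  truth <- list(causal_snp_ids = genotypes$snps$snp_id[causal],
                effects = stats::setNames(beta, genotypes$snps$snp_id),
                breeding_values = stats::setNames(g, genotypes$subject_ids),
                h2_realized = if (stats::var(y) > 0) stats::var(g) / stats::var(y) else 0)
  list(phenotypes = data.frame(subject_id = genotypes$subject_ids,
                               trait = y, label = lab$labels,
                               stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate functional SNP-prioritization scores
#'
#' Produces per-SNP priority scores in \[0, 0.12\], split into a
#' regulatory-evidence component (eQTL/chromatin) and a minor-allele-frequency
#' component.  A configurable fraction of SNPs scores exactly zero; causal
#' SNPs are over-represented among the non-zero scores in proportion to
#' `priority_informativeness` (0 = independent of causal status).
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth ground-truth list from [simulate_polygenic_phenotype()].
#' @param config a [sim_config()].
#' @return data frame: `snp_id`, `total_score`, `regulatory_component`,
#'   `maf_component`.
#' @export
simulate_priority_scores <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- ncol(genotypes$dosages)
  ids <- genotypes$snps$snp_id
  if (!all(truth$causal_snp_ids %in% ids))
    stop_wgp("ground truth refers to SNPs absent from the genotype matrix")
  set.seed(derive_seed(config$seed, "priority"))
  n_nonzero <- round((1 - config$zero_score_fraction) * m)
  causal <- ids %in% truth$causal_snp_ids
  w <- 1 + config$priority_informativeness * causal
  nonzero <- rep(FALSE, m)
  nonzero[sample.int(m, n_nonzero, prob = w)] <- TRUE
  reg <- numeric(m); mafc <- numeric(m)
  mafs <- maf(genotypes)
  # among non-zero SNPs, ~80% carry regulatory evidence; MAF component grows
  # with minor allele frequency, capped so total stays within [0, 0.12]
  has_reg <- nonzero & (stats::runif(m) < 0.8)
  reg[has_reg] <- 0.08 * stats::rbeta(sum(has_reg), 1.5, 4)
  mafc[nonzero] <- 0.04 * (mafs[nonzero] / 0.5)
  total <- pmin(reg + mafc, 0.12)
  data.frame(snp_id = ids, total_score = total,
             regulatory_component = reg, maf_component = mafc,
             stringsAsFactors = FALSE)
}

#' Simulate demographic covariates
#'
#' @param config a [sim_config()].
#' @param subject_ids subject identifiers.
#' @return data frame with one column per covariate in `covariate_spec`.
#' @export
simulate_covariates <- function(config, subject_ids) {
  set.seed(derive_seed(config$seed, "covariates"))
  n <- length(subject_ids)
  out <- data.frame(subject_id = subject_ids, stringsAsFactors = FALSE)
  for (cv in config$covariate_spec) {
    out[[cv$name]] <- switch(cv$dist,
      normal = stats::rnorm(n, cv$pars[1], cv$pars[2]),
      bernoulli = stats::rbinom(n, 1L, cv$pars[1]),
      stop_wgp("unknown covariate distribution: ", cv$dist))
  }
  out
}

#' Assign longitudinal lung-pattern labels
#'
#' @param n cohort size.
#' @param props named proportions for NG, NG-ED, RG, RG-ED; the remainder is
#'   labelled `"unclassified"`.
#' @param seed integer seed.
#' @return character vector of assignments.
#' @export
sample_patterns <- function(n, props = c(NG = 0.2656, `NG-ED` = 0.2055,
                                         RG = 0.2668, `RG-ED` = 0.2127),
                            seed = 1L) {
  set.seed(seed)
  lv <- c(names(props), "unclassified")
  counts <- round(props * n)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  lab <- c(rep(names(props), counts), rep("unclassified", n - sum(counts)))
  sample(factor(lab, levels = lv))
}

#' Simulate longitudinal percent-predicted FEV1 trajectories
#'
#' Generates annual (age, FEV1 %predicted) series from age 6 to 24 realizing
#' the assigned growth pattern.  Normal-growth (NG) series sit above the
#' internal 25th-percentile reference, reduced-growth (RG) below; early
#' decline (ED) series peak at the end of adolescence (age 19) and then fall
#' by 12% of peak by the final visit, while non-ED series plateau.  Per-visit
#' Gaussian noise is added.  The percentile reference is an internal
#' synthetic population curve (percent-predicted ~ Normal(100, 13)).
#'
#' @param subject_ids subject identifiers.
#' @param assignments per-subject labels among NG, NG-ED, RG, RG-ED (an
#'   `"unclassified"` assignment yields a short, unclassifiable series).
#' @param seed integer seed.
#' @param noise_sd per-visit measurement noise SD in %predicted units.
#' @param ages vector of visit ages (years).
#' @return data frame: subject_id, age, fev1_pct_pred, percentile_rank.
#' @export
simulate_trajectories <- function(subject_ids, assignments, seed = 1L,
                                  noise_sd = 2, ages = 6:24) {
  ok <- c("NG", "NG-ED", "RG", "RG-ED", "unclassified")
  assignments <- as.character(assignments)
  if (!all(assignments %in% ok))
    stop_wgp("unknown pattern assignment: ",
             paste(setdiff(assignments, ok), collapse = ", "))
  set.seed(seed)
  res <- vector("list", length(subject_ids))
  for (i in seq_along(subject_ids)) {
    a <- assignments[i]
    if (a == "unclassified") {          # too few visits to classify
      ag <- ages[1:3]
      v <- 95 + stats::rnorm(3, 0, noise_sd)
    } else {
      ag <- ages
      level <- if (startsWith(a, "NG")) 106 else 84
      ed <- endsWith(a, "ED")
      peak_age <- 19
      v <- numeric(length(ag))
      rise <- pmin((ag - ag[1]) / (peak_age - ag[1]), 1) * 4
      v <- level + rise
      if (ed) {
        post <- ag > peak_age
        peak_val <- level + 4
        v[post] <- peak_val * (1 - 0.12 * (ag[post] - peak_age) /
                                 (max(ag) - peak_age))
      }
      v <- v + stats::rnorm(length(v), 0, noise_sd)
    }
    res[[i]] <- data.frame(subject_id = subject_ids[i], age = ag,
                           fev1_pct_pred = v, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$percentile_rank <- fev1_percentile(out$fev1_pct_pred)
  out
}

#' Inject missing-completely-at-random values into a phenotype table
#'
#' @param table data frame; the `subject_id` column is never blanked.
#' @param rate missingness rate in \[0, 1).
#' @param seed integer seed.
#' @return the table with entries set to `NA`; the missingness mask is
#'   attached as attribute `"missing_mask"` for auditing.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  if (rate >= 1 || rate < 0) stop_wgp("missingness rate must be in [0, 1)")
  cols <- setdiff(names(table), "subject_id")
  mask <- matrix(FALSE, nrow(table), length(cols), dimnames = list(NULL, cols))
  if (rate > 0) {
    set.seed(seed)
    for (j in cols) {
      miss <- stats::runif(nrow(table)) < rate
      table[[j]][miss] <- NA
      mask[, j] <- miss
    }
  }
  attr(table, "missing_mask") <- mask
  table
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates genotypes, polygenic phenotype, priority scores, covariates,
#' lung-pattern assignments and trajectories from one [sim_config()].
#'
#' @param config a [sim_config()].
#' @return list: `genotypes`, `phenotypes`, `covariates`, `scores`,
#'   `trajectories`, `assignments`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  g <- simulate_genotypes(config)
  cov <- simulate_covariates(config, g$subject_ids)
  ph <- simulate_polygenic_phenotype(g, config, covariates = cov)
  sc <- simulate_priority_scores(g, ph$truth, config)
  assign <- sample_patterns(length(g$subject_ids), config$pattern_props,
                            derive_seed(config$seed, "patterns"))
  traj <- simulate_trajectories(g$subject_ids, assign,
                                seed = derive_seed(config$seed, "trajectories"))
  phen <- merge(ph$phenotypes, cov, by = "subject_id", sort = FALSE)
  if (config$missing_rate > 0)
    phen <- inject_missingness(phen, config$missing_rate,
                               derive_seed(config$seed, "missingness"))
  list(genotypes = g, phenotypes = phen, covariates = cov, scores = sc,
       trajectories = traj, assignments = assign, truth = ph$truth,
       config = config)
}
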