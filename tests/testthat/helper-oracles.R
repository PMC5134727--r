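# Independent oracles used to check the package implementations.  These are
# deliberately naive (loops, direct solves, exhaustive enumeration) and share
# no code with the package internals.

# AUC by exhaustive case/control pair comparison, ties counted 0.5
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# restricted log-likelihood by direct dense algebra (no cholesky shortcuts)
oracle_reml_ll <- function(y, X, A, sg, se) {
  n <- length(y); p <- ncol(X)
  V <- sg * A + se * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(y) %*% P %*% y + (n - p) * log(2 * pi)))
}

# grid search over (sigma2_g, sigma2_e); returns the grid optimum
oracle_reml_grid <- function(y, X, A, n_grid = 200) {
  vy <- var(y)
  grid <- seq(vy * 1e-4, 3 * vy, length.out = n_grid)
  best <- list(ll = -Inf)
  for (sg in grid) for (se in grid) {
    ll <- tryCatch(oracle_reml_ll(y, X, A, sg, se), error = function(e) -Inf)
    if (ll > best$ll) best <- list(ll = ll, sg = sg, se = se)
  }
  best$h2 <- best$sg / (best$sg + best$se)
  best$step <- diff(grid[1:2])
  best
}

# G-BLUP through Henderson's mixed-model equations with Z = I on the
# training block, then u_test = A_xt %*% solve(A_tt) %*% u_train
oracle_mme_gblup <- function(K, y_train, train_ids, test_ids, ridge) {
  v <- if (inherits(K, "kinship_matrix")) K$values else K
  Att <- v[train_ids, train_ids]
  Axt <- v[test_ids, train_ids, drop = FALSE]
  nt <- length(train_ids)
  X <- matrix(1, nt, 1)
  lhs <- rbind(cbind(t(X) %*% X, t(X)),
               cbind(X, diag(nt) + ridge * solve(Att)))
  rhs <- c(t(X) %*% y_train, y_train)
  sol <- solve(lhs, rhs)
  mu <- sol[1]
  u_train <- sol[-1]
  drop(Axt %*% solve(Att, u_train)) + mu
}

# GRM entry by the definitional double loop
oracle_grm_entry <- function(dosages, w, j, k) {
  p <- colMeans(dosages) / 2
  tot <- 0
  for (i in seq_len(ncol(dosages))) {
    tot <- tot + w[i] * (dosages[j, i] - 2 * p[i]) * (dosages[k, i] - 2 * p[i]) /
      (2 * p[i] * (1 - p[i]))
  }
  tot / sum(w)
}

# HWE chi-square from genotype counts, straight from the definition
oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  pchisq(sum((c(n0, n1, n2) - e)^2 / e), df = 1, lower.tail = FALSE)
}

# small fully-typed genotype fixture
make_geno <- function(dosages, chrom = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  snps <- data.frame(snp_id = sprintf("s%03d", seq_len(m)),
                     chrom = chrom %||% as.character(rep_len(1:22, m)),
                     pos = seq_len(m), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(dosages, snps, sprintf("I%03d", seq_len(nrow(dosages))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulated cohort + standard GRM in one call, for predictor/eval tests
quick_cohort <- function(n = 200, m = 400, h2 = 0.6, seed = 1,
                         causal_fraction = 0.05) {
  cfg <- sim_config(n_subjects = n, n_snps = m, h2_true = h2,
                    causal_fraction = causal_fraction, seed = seed)
  g <- simulate_genotypes(cfg)
  ph <- simulate_polygenic_phenotype(g, cfg)
  # small samples can leave SNPs monomorphic; drop them as QC would
  g <- maf_filter(g, 0.01)$genotypes
  K <- compute_grm(mean_impute_genotypes(g))
  list(g = g, K = K, trait = ph$phenotypes$trait,
       label = ph$phenotypes$label, truth = ph$truth, cfg = cfg)
}
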