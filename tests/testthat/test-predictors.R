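split_ids <- function(ids, n_test, seed = 1) {
  set.seed(seed)
  test <- sample(ids, n_test)
  list(train = setdiff(ids, test), test = test)
}

test_that("G-BLUP matches the mixed-model-equations oracle", {
  co <- quick_cohort(n = 20, m = 100, h2 = 0.7, seed = 1, causal_fraction = 0.5)
  sp <- split_ids(co$K$subject_ids, 5)
  y_tr <- co$trait[match(sp$train, co$K$subject_ids)]
  for (ridge in c(0.5, 1, 3)) {
    got <- gblup_predict(co$K, y_tr, sp$train, sp$test, ridge = ridge)
    want <- oracle_mme_gblup(co$K, y_tr, sp$train, sp$test, ridge)
    expect_equal(got$score, unname(want), tolerance = 1e-8)
  }
})

test_that("G-BLUP limits: infinite shrinkage and uninformative kinship", {
  co <- quick_cohort(n = 30, m = 60, seed = 2)
  sp <- split_ids(co$K$subject_ids, 8)
  y_tr <- co$trait[match(sp$train, co$K$subject_ids)]
  big <- gblup_predict(co$K, y_tr, sp$train, sp$test, ridge = 1e9)
  expect_equal(big$score, rep(mean(y_tr), 8), tolerance = 1e-6)
  Kid <- kinship_matrix(diag(30), scheme = "identity")
  dimnames(Kid$values) <- list(co$K$subject_ids, co$K$subject_ids)
  Kid$subject_ids <- co$K$subject_ids
  id <- gblup_predict(Kid, y_tr, sp$train, sp$test, ridge = 1)
  expect_equal(id$score, rep(mean(y_tr), 8), tolerance = 1e-12)
})

test_that("G-BLUP is equivariant under label shift and scale", {
  co <- quick_cohort(n = 40, m = 80, seed = 3)
  sp <- split_ids(co$K$subject_ids, 10)
  y_tr <- co$trait[match(sp$train, co$K$subject_ids)]
  base <- gblup_predict(co$K, y_tr, sp$train, sp$test, ridge = 1)
  shift <- gblup_predict(co$K, y_tr + 5, sp$train, sp$test, ridge = 1)
  expect_equal(shift$score, base$score + 5, tolerance = 1e-10)
  scl <- gblup_predict(co$K, y_tr * 3, sp$train, sp$test, ridge = 1)
  expect_equal(scl$score - mean(y_tr * 3),
               3 * (base$score - mean(y_tr)), tolerance = 1e-10)
})

test_that("simple kriging behaves on degenerate kernels and neighbors", {
  co <- quick_cohort(n = 30, m = 60, seed = 4)
  ids <- co$K$subject_ids
  # duplicate a training subject as the test subject: k = 1 recovers its label
  K2 <- co$K
  K2$values <- rbind(cbind(K2$values, K2$values[, 1]),
                     c(K2$values[1, ], K2$values[1, 1]))
  ids2 <- c(ids, "DUP")
  dimnames(K2$values) <- list(ids2, ids2)
  K2$subject_ids <- ids2
  y_tr <- co$trait
  got <- kriging_simple_predict(K2, y_tr, ids, "DUP", k_neighbors = 1)
  expect_equal(got$score, co$trait[1], tolerance = 1e-10)
  # uniform kinship carries no ranking information: prediction = training mean
  Ku <- kinship_matrix(matrix(1, 30, 30) + diag(1e-9, 30))
  dimnames(Ku$values) <- list(ids, ids); Ku$subject_ids <- ids
  sp <- split_ids(ids, 5)
  u <- kriging_simple_predict(Ku, co$trait[match(sp$train, ids)],
                              sp$train, sp$test)
  expect_equal(u$score, rep(mean(co$trait[match(sp$train, ids)]), 5),
               tolerance = 1e-6)
})

test_that("kriging and G-BLUP rank subjects consistently on heritable traits", {
  co <- quick_cohort(n = 200, m = 400, h2 = 0.8, seed = 5)
  sp <- split_ids(co$K$subject_ids, 50)
  y_tr <- co$trait[match(sp$train, co$K$subject_ids)]
  a <- gblup_predict(co$K, y_tr, sp$train, sp$test, ridge = 1)
  b <- kriging_simple_predict(co$K, y_tr, sp$train, sp$test)
  expect_gt(cor(a$score, b$score, method = "spearman"), 0.7)
})

test_that("closed-form LOO equals naive per-subject refitting", {
  co <- quick_cohort(n = 50, m = 100, h2 = 0.6, seed = 6)
  ids <- co$K$subject_ids
  fast <- loo_predict(co$K, co$trait, ridge = 1.5)
  naive <- vapply(seq_along(ids), function(j) {
    gblup_predict(co$K, co$trait[-j], ids[-j], ids[j], ridge = 1.5)$score
  }, numeric(1))
  expect_equal(fast$score, naive, tolerance = 1e-10)
  # permuting subject order permutes scores identically
  perm <- sample(50)
  Kp <- kinship_matrix(co$K$values[perm, perm])
  fast_p <- loo_predict(Kp, co$trait[perm], ridge = 1.5)
  expect_equal(fast_p$score, fast$score[perm], tolerance = 1e-10)
  expect_error(loo_predict(co$K, co$trait[1:2]), "")
})

test_that("covariate-kernel integration recovers covariate-driven traits", {
  set.seed(7)
  co <- quick_cohort(n = 200, m = 300, h2 = 0, seed = 7)
  ids <- co$K$subject_ids
  x <- rnorm(200)
  y <- x + rnorm(200, 0, 0.5)       # trait driven purely by the covariate
  lab <- as.integer(y > mean(y))
  cv <- data.frame(subject_id = ids, x = x)
  sp <- split_ids(ids, 50)
  y_tr <- lab[match(sp$train, ids)]
  y_te <- lab[match(sp$test, ids)]
  gen <- gblup_predict(co$K, y_tr, sp$train, sp$test, ridge = 1)
  covonly <- predict_with_covariates(co$K, cv, y_tr, sp$train, sp$test,
                                     mixing = c(0, 1), ridge = 1)
  expect_gt(auc(covonly$score, y_te), auc(gen$score, y_te))
  # mixing (1, 0) reduces to genetics-only
  genmix <- predict_with_covariates(co$K, cv, y_tr, sp$train, sp$test,
                                    mixing = c(1, 0), ridge = 1)
  expect_equal(genmix$score, gen$score, tolerance = 1e-12)
})

test_that("combining genetic and covariate kernels does not lose accuracy", {
  aucs <- matrix(NA_real_, 10, 3,
                 dimnames = list(NULL, c("gen", "cov", "both")))
  for (r in 1:10) {
    cfg <- sim_config(n_subjects = 200, n_snps = 300, h2_true = 0.4,
                      causal_fraction = 0.2, seed = 700 + r)
    cfg$covariate_spec[[1]]$effect <- 0.8     # age drives the trait too
    g <- simulate_genotypes(cfg)
    cov <- simulate_covariates(cfg, g$subject_ids)
    ph <- simulate_polygenic_phenotype(g, cfg, covariates = cov)
    K <- compute_grm(g)
    ids <- g$subject_ids
    lab <- ph$phenotypes$label
    set.seed(r); test <- sample(ids, 50); train <- setdiff(ids, test)
    y_tr <- lab[match(train, ids)]; y_te <- lab[match(test, ids)]
    sc_g <- gblup_predict(K, y_tr, train, test, ridge = 1)
    sc_c <- predict_with_covariates(K, cov, y_tr, train, test,
                                    mixing = c(0, 1), ridge = 1)
    sc_b <- predict_with_covariates(K, cov, y_tr, train, test,
                                    mixing = c(0.5, 0.5), ridge = 1)
    aucs[r, ] <- c(auc(sc_g$score, y_te), auc(sc_c$score, y_te),
                   auc(sc_b$score, y_te))
  }
  expect_gte(mean(aucs[, "both"]), max(colMeans(aucs[, 1:2])) - 0.02)
})

test_that("naive Bayes matches a hand-computed two-SNP posterior", {
  d <- rbind(c(0, 2), c(0, 1), c(1, 2), c(2, 0), c(2, 1), c(1, 0))
  lab <- c(1, 1, 1, 0, 0, 0)
  g <- make_geno(d)
  fit <- naive_bayes_wgp(g, lab)
  sc <- predict(fit, g)
  # hand computation with add-one smoothing over 3 genotype cells
  p_g <- function(cnt) (cnt + 1) / (sum(cnt) + 3)
  c1 <- rbind(c(2, 1, 0), c(0, 1, 2))   # class-1 counts for snp1, snp2 (0/1/2)
  c0 <- rbind(c(0, 1, 2), c(2, 1, 0))
  hand <- function(x) {
    sum(vapply(1:2, function(i)
      log(p_g(c1[i, ])[x[i] + 1]) - log(p_g(c0[i, ])[x[i] + 1]), numeric(1)))
  }
  want <- apply(d, 1, hand) + log(0.5 / 0.5)
  expect_equal(sc$score, unname(want), tolerance = 1e-12)
  # a label-independent SNP contributes ~0 log-odds
  d2 <- cbind(d[, 1], c(1, 1, 1, 1, 1, 1))
  fit2 <- naive_bayes_wgp(make_geno(d2), lab)
  expect_equal(unname(fit2$log_ratio[, 2]), rep(0, 3), tolerance = 1e-12)
  expect_error(naive_bayes_wgp(g, rep(1, 6)), "single-class")
})

test_that("naive Bayes lets a perfectly separating SNP dominate", {
  set.seed(8)
  noise <- matrix(rbinom(40 * 5, 2, 0.5), 40)
  sep <- rep(c(0, 2), each = 20)
  lab <- rep(c(0, 1), each = 20)
  g <- make_geno(cbind(sep, noise))
  sc <- predict(naive_bayes_wgp(g, lab), g)
  expect_equal(auc(sc$score, lab), 1)
})

test_that("LASSO predictor selects signal and honours the penalty limit", {
  set.seed(9)
  n <- 120; m <- 30
  d <- matrix(rbinom(n * m, 2, 0.4), n)
  eta <- 2.5 * (d[, 1] - mean(d[, 1]))
  lab <- rbinom(n, 1, plogis(eta))
  g <- make_geno(d)
  fit <- lasso_wgp(g, lab, seed = 1)
  cf <- as.matrix(coef(fit$cv, s = "lambda.min"))[-1, 1]
  expect_gt(abs(cf[1]), 0)
  expect_gt(abs(cf[1]), max(abs(cf[-1])) - 1e-9)
  # near-infinite penalty: intercept-only model, constant scores
  sc_inf <- predict(fit, g, s = 1e6)
  expect_lt(diff(range(sc_inf$score)), 1e-8)
  # prediction for a test subject ignores other test rows (no leakage)
  sc_all <- predict(fit, g)
  perm <- sample(n)
  sc_perm <- predict(fit, make_geno(d[perm, , drop = FALSE]))
  expect_equal(sc_perm$score, sc_all$score[perm], tolerance = 1e-12)
})

test_that("linear SVM separates separable data and flips with labels", {
  set.seed(10)
  n <- 60
  d <- cbind(rep(c(0, 2), each = n / 2), matrix(rbinom(n * 10, 2, 0.5), n))
  lab <- rep(c(0, 1), each = n / 2)
  g <- make_geno(d)
  fit <- svm_wgp(g, lab)
  sc <- predict(fit, g)
  expect_equal(auc(sc$score, lab), 1)
  fit_fl <- svm_wgp(g, 1 - lab)
  sc_fl <- predict(fit_fl, g)
  expect_lt(cor(sc$score, sc_fl$score), -0.99)
})
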