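test_that("GRM matches the definitional double-loop oracle", {
  set.seed(21)
  d <- matrix(rbinom(10 * 20, 2, rep(runif(20, 0.1, 0.5), each = 10)), nrow = 10)
  g <- make_geno(d)
  w <- runif(20, 0.1, 1)
  K <- compute_grm(g, w)
  for (j in c(1, 4, 10)) for (k in c(1, 7)) {
    expect_equal(K$values[j, k], oracle_grm_entry(d, w, j, k),
                 tolerance = 1e-10)
  }
  # uniform weights: A = Z Z^T / m on standardized dosages
  K1 <- compute_grm(g)
  p <- colMeans(d) / 2
  z <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), `/`)
  expect_equal(unname(K1$values), tcrossprod(z) / 20, tolerance = 1e-10)
})

test_that("GRM is invariant to weight rescaling and symmetric-PSD", {
  co <- quick_cohort(n = 60, m = 120, seed = 31)
  g <- mean_impute_genotypes(co$g)
  w <- runif(120, 0.1, 2)
  K1 <- compute_grm(g, w)
  K2 <- compute_grm(g, 1000 * w)
  expect_equal(K1$values, K2$values, tolerance = 1e-12)
  ev <- eigen(K1$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("identical genotype vectors give identical relatedness entries", {
  d <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 0))
  K <- compute_grm(make_geno(d))
  expect_equal(K$values[1, 2], K$values[1, 1])
  expect_equal(K$values[1, 1], K$values[2, 2])
})

test_that("standard GRM diagonal averages to 1 under HWE", {
  cfg <- sim_config(n_subjects = 500, n_snps = 5000, seed = 12)
  g <- simulate_genotypes(cfg)
  K <- compute_grm(g)
  expect_equal(mean(diag(K$values)), 1, tolerance = 0.02)
})

test_that("monomorphic SNPs with nonzero weight are rejected", {
  g <- make_geno(cbind(c(0, 0, 0), c(0, 1, 2)))
  expect_error(compute_grm(g), "monomorphic")
  expect_silent(compute_grm(g, c(0, 1)))
})

test_that("priority weighting schemes split components as specified", {
  sc <- data.frame(snp_id = sprintf("s%03d", 1:4),
                   total_score = c(0.05, 0.04, 0, 0.06),
                   regulatory_component = c(0.05, 0, 0, 0.02),
                   maf_component = c(0, 0.04, 0, 0.04))
  w1 <- apply_scheme_w1(sc)
  w2 <- apply_scheme_w2(sc)
  expect_equal(w1$weight, sc$total_score)
  expect_equal(w2$weight, sc$regulatory_component)
  # SNP 2 is purely MAF-driven: weight 0 under W2, > 0 under W1
  expect_gt(w1$weight[2], 0); expect_equal(w2$weight[2], 0)
  # W2 == W1 when MAF components vanish
  sc0 <- sc; sc0$maf_component <- 0
  sc0$total_score <- sc0$regulatory_component
  expect_equal(apply_scheme_w1(sc0)$weight, apply_scheme_w2(sc0)$weight)
  expect_error(apply_scheme_w1(transform(sc, total_score = 0)), "zero")
})

test_that("zero-weight SNPs contribute nothing to the GRM", {
  set.seed(33)
  d <- matrix(rbinom(8 * 10, 2, 0.4), nrow = 8)
  g <- make_geno(d)
  sc <- data.frame(snp_id = g$snps$snp_id,
                   total_score = c(runif(6, 0.01, 0.1), rep(0, 4)),
                   regulatory_component = 0, maf_component = 0)
  K_w1 <- compute_grm(g, apply_scheme_w1(sc))
  w_sub <- sc$total_score[1:6]
  K_manual <- compute_grm(make_geno(d[, 1:6]), w_sub)
  expect_equal(unname(K_w1$values), unname(K_manual$values), tolerance = 1e-12)
})

test_that("NZW subsets to positive-score SNPs with standard weights", {
  set.seed(34)
  d <- matrix(rbinom(20 * 10, 2, 0.4), nrow = 20)
  g <- make_geno(d)
  sc <- data.frame(snp_id = g$snps$snp_id,
                   total_score = rep(c(0.08, 0), c(6, 4)),
                   regulatory_component = 0, maf_component = 0)
  nz <- apply_scheme_nzw(sc, g)
  expect_equal(ncol(nz$genotypes$dosages), 6)
  expect_equal(nz$weights$weight, rep(1, 6))
  K_nzw <- grm_by_scheme(g, "NZW", sc)
  K_manual <- compute_grm(make_geno(d[, 1:6]))
  expect_equal(unname(K_nzw$values), unname(K_manual$values), tolerance = 1e-12)
  expect_identical(K_nzw$scheme, "NZW")
  expect_equal(K_nzw$n_snps, 6)
  # all-positive scores: identity subset
  sc_pos <- transform(sc, total_score = 0.05)
  expect_equal(ncol(apply_scheme_nzw(sc_pos, g)$genotypes$dosages), 10)
  expect_error(apply_scheme_nzw(transform(sc, total_score = 0), g), "empty")
})

test_that("genotype PCA separates a two-population mixture", {
  set.seed(55)
  n <- 150; m <- 400
  pop <- rep(c(0, 1), each = n / 2)
  p1 <- runif(m, 0.1, 0.5); p2 <- pmin(0.95, p1 + runif(m, 0.1, 0.3))
  d <- t(vapply(seq_len(n), function(i)
    rbinom(m, 2, if (pop[i] == 0) p1 else p2), numeric(m)))
  K <- compute_grm(make_geno(d))
  pcs <- genotype_pca(K, 6)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  expect_lt(max(abs(crossprod(pcs[, 1], pcs[, 2]))), 1e-8 * nrow(pcs))
  expect_equal(ncol(pcs), 6)
  expect_error(genotype_pca(matrix(c(1, 2, 0, 1), 2), 1), "symmetric")
})

test_that("covariate similarity follows the unit-weight GRM algebra", {
  cv <- data.frame(subject_id = c("a", "b", "c"),
                   x1 = c(1, 2, 3), x2 = c(0, 0, 1))
  K <- covariate_similarity(cv)
  z1 <- scale(cv$x1); z2 <- scale(cv$x2)
  expected <- (tcrossprod(z1) + tcrossprod(z2)) / 2
  expect_equal(unname(K$values), unname(expected), tolerance = 1e-12)
  # single binary covariate: within-group similarity exceeds between-group
  cvb <- data.frame(g = rep(c("x", "y"), each = 4))
  Kb <- covariate_similarity(cvb)
  expect_gt(Kb$values[1, 2], Kb$values[1, 5])
  # identical covariate rows are maximally similar
  expect_equal(Kb$values[1, 2], Kb$values[1, 1])
  expect_warning(covariate_similarity(data.frame(a = rnorm(5), b = 1)),
                 "zero-variance")
})

test_that("similarity combination is a checked convex combination", {
  co <- quick_cohort(n = 40, m = 80, seed = 41)
  Kc <- covariate_similarity(data.frame(subject_id = co$K$subject_ids,
                                        z = rnorm(40)))
  expect_equal(combine_similarity(list(co$K, Kc), c(1, 0))$values,
               co$K$values)
  expect_equal(combine_similarity(list(co$K, co$K), c(0.5, 0.5))$values,
               co$K$values, tolerance = 1e-12)
  half <- combine_similarity(list(co$K, Kc), c(0.3, 0.7))
  expect_equal(half$values, 0.3 * co$K$values + 0.7 * Kc$values)
  expect_error(combine_similarity(list(co$K, Kc), c(0.5, 0.4)), "sum")
  expect_error(combine_similarity(list(co$K, Kc), c(1.5, -0.5)), "negative")
})

test_that("GRM text format round-trips", {
  co <- quick_cohort(n = 25, m = 50, seed = 44)
  path <- file.path(tempdir(), "grm.tsv")
  write_grm(co$K, path)
  K2 <- read_grm(path)
  expect_equal(K2$values[co$K$subject_ids, co$K$subject_ids], co$K$values,
               tolerance = 1e-12)
})
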