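test_that("PLINK bed/bim/fam round-trips losslessly", {
  cfg <- sim_config(n_subjects = 37, n_snps = 23, seed = 4)
  g <- simulate_genotypes(cfg)
  g$dosages[cbind(c(1, 5, 9), c(2, 7, 11))] <- NA   # sprinkle missing
  prefix <- file.path(tempdir(), "rt")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_equal(unname(g2$dosages), unname(g$dosages), ignore_attr = TRUE)
  expect_identical(g2$snps$snp_id, g$snps$snp_id)
  expect_identical(g2$snps$chrom, g$snps$chrom)
  expect_identical(g2$subject_ids, g$subject_ids)
})

test_that("hand-built bed bytes decode to the expected dosages", {
  # 3 subjects, 2 SNPs; codes low-bits-first: SNP1 (hom-A1, missing, het)
  # -> byte 0x24; SNP2 (hom-A2, het, hom-A1) -> byte 0x0b
  prefix <- file.path(tempdir(), "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x24, 0x0b)), paste0(prefix, ".bed"))
  writeLines(c("1\trs1\t0\t100\tA\tG", "2\trs2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("F1\tP1\t0\t0\t0\t-9", "F2\tP2\t0\t0\t0\t-9",
               "F3\tP3\t0\t0\t0\t-9"), paste0(prefix, ".fam"))
  g <- read_plink(prefix)
  expect_identical(unname(g$dosages),
                   matrix(c(2, NA, 1, 0, 1, 2), nrow = 3))
  expect_identical(g$subject_ids, c("P1", "P2", "P3"))
})

test_that("inconsistent bed/fam sizes and bad magic are rejected", {
  cfg <- sim_config(n_subjects = 8, n_snps = 4, seed = 6)
  g <- simulate_genotypes(cfg)
  prefix <- file.path(tempdir(), "bad")
  write_plink(g, prefix)
  fam <- readLines(paste0(prefix, ".fam"))
  writeLines(c(fam, "F9\tP9\t0\t0\t0\t-9"), paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "inconsistent")
  writeLines(fam[1:8], paste0(prefix, ".fam"))
  bed <- readBin(paste0(prefix, ".bed"), "raw", 100)
  bed[1] <- as.raw(0x00)
  writeBin(bed, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
})

test_that("MAF filter counts alleles correctly", {
  g <- make_geno(cbind(c(0, 0, 1, 1, 2),       # freq 4/10 = 0.40
                       c(0, 0, 0, 0, 0),       # monomorphic
                       c(0, 0, 0, 0, 1)))      # maf 0.10
  expect_equal(unname(allele_freq(g)), c(0.4, 0, 0.1))
  out <- maf_filter(g, 0.05)
  expect_identical(out$genotypes$snps$snp_id, c("s001", "s003"))
  expect_identical(out$report$removed, "s002")
  out0 <- maf_filter(g, 0)
  expect_identical(out0$genotypes$snps$snp_id, g$snps$snp_id)
})

test_that("HWE test matches the definitional oracle", {
  # exact HWE proportions -> statistic 0, p = 1
  g1 <- make_geno(matrix(rep(c(0, 1, 2), c(25, 50, 25)), ncol = 1))
  expect_equal(unname(hwe_test(g1)), 1)
  expect_equal(unname(hwe_test(g1, statistic = TRUE)), 0)
  # worked example: counts (40, 20, 40) -> E = (25, 50, 25), chi-square 36
  g2 <- make_geno(matrix(rep(c(0, 1, 2), c(40, 20, 40)), ncol = 1))
  expect_equal(unname(hwe_test(g2, statistic = TRUE)), 36, tolerance = 1e-12)
  expect_equal(unname(hwe_test(g2)), oracle_hwe_p(40, 20, 40),
               tolerance = 1e-12)
  expect_lt(unname(hwe_test(g2)), 0.001)   # removed at the 0.001 floor
  # exhaustive sweep over genotype-count triples with n <= 30
  for (n in c(4, 9, 17, 30)) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      n2 <- n - n0 - n1
      gg <- make_geno(matrix(rep(c(0, 1, 2), c(n0, n1, n2)), ncol = 1))
      expect_equal(unname(hwe_test(gg)), oracle_hwe_p(n0, n1, n2),
                   tolerance = 1e-10)
    }
  }
})

test_that("autosome filter keeps chromosomes 1-22 only", {
  g <- make_geno(matrix(rbinom(50, 2, 0.3), nrow = 5),
                 chrom = c(as.character(1:7), "X", "Y", "MT"))
  out <- autosome_filter(g)
  expect_equal(ncol(out$genotypes$dosages), 7)
  expect_setequal(out$report$removed, c("s008", "s009", "s010"))
  out2 <- autosome_filter(out$genotypes)
  expect_equal(length(out2$report$removed), 0)
})

test_that("mean imputation fills with column means and preserves them", {
  g <- make_geno(cbind(c(0, 2, NA), c(1, 1, 1)))
  imp <- mean_impute_genotypes(g)
  expect_equal(unname(imp$dosages[3, 1]), 1.0)
  expect_equal(colMeans(imp$dosages), colMeans(g$dosages, na.rm = TRUE))
  g2 <- make_geno(cbind(c(0, 1, 2)))
  expect_identical(mean_impute_genotypes(g2)$dosages, g2$dosages)
  g3 <- make_geno(cbind(c(NA, NA, NA), c(0, 1, 2)))
  expect_error(mean_impute_genotypes(g3), "s001")
})

test_that("QC pipeline applies autosome -> MAF -> HWE and is idempotent", {
  set.seed(42)
  hwe_ok <- function(p, n) rbinom(n, 2, p)
  d <- cbind(hwe_ok(0.3, 100), hwe_ok(0.4, 100), hwe_ok(0.25, 100),
             rep(0, 100),                          # MAF 0 -> fails MAF
             c(rep(0, 98), 1, 1),                  # MAF 0.01 -> fails MAF
             rep(c(0, 1, 2), c(40, 20, 40)))       # fails HWE at 0.001
  g <- make_geno(d)
  out <- qc_pipeline(g, maf_threshold = 0.05, hwe_p = 0.001)
  expect_equal(out$report$n_final, 3)
  expect_setequal(out$report$maf$removed, c("s004", "s005"))
  expect_identical(out$report$hwe$removed, "s006")
  again <- qc_pipeline(out$genotypes, 0.05, 0.001)
  expect_equal(again$report$n_final, out$report$n_final)
  expect_identical(again$genotypes$dosages, out$genotypes$dosages)
})

test_that("plain-text dosage dialect round-trips", {
  cfg <- sim_config(n_subjects = 12, n_snps = 7, seed = 8)
  g <- simulate_genotypes(cfg)
  g$dosages[2, 3] <- NA
  path <- file.path(tempdir(), "dos.tsv")
  write_dosage(g, path)
  g2 <- read_dosage(path)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_identical(g2$subject_ids, g$subject_ids)
})
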