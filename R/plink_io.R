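# PLINK 1 binary (bed/bim/fam) and plain-text dosage readers/writers.
# bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then per SNP
# ceiling(n/4) bytes; each byte packs 4 subjects, 2 bits each, first subject
# in the lowest-order bits.  2-bit codes: 00 hom A1 (dosage 2), 01 missing,
# 10 het (1), 11 hom A2 (0).

.bed_code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)

#' Read a PLINK bed/bim/fam file set
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return a [genotype_matrix()] with dosages counting A1 alleles.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop_wgp("missing file: ", f)
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = c("character", "character", "numeric",
                                             "integer", "character", "character"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed, what = "raw", n = 3 + m * bytes_per_snp + 8)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_wgp("not a PLINK bed file (magic byte mismatch): ", bed)
  if (raw[3] != as.raw(0x01))
    stop_wgp("only SNP-major bed files are supported")
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp)
    stop_wgp("bed payload size ", length(body), " inconsistent with fam/bim (",
             m * bytes_per_snp, " bytes expected)")
  ints <- as.integer(body)
  # expand each byte into 4 two-bit codes, low bits first
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = 4 * bytes_per_snp, ncol = m)
  d <- matrix(.bed_code_to_dosage[as.character(codes[seq_len(n), , drop = FALSE])],
              nrow = n, ncol = m)
  snps <- data.frame(snp_id = bim_df[[2]], chrom = bim_df[[1]],
                     pos = bim_df[[4]], a1 = bim_df[[5]], a2 = bim_df[[6]],
                     stringsAsFactors = FALSE)
  genotype_matrix(d, snps, subject_ids = as.character(fam_df[[2]]))
}

#' Write a PLINK bed/bim/fam file set
#'
#' @param g a [genotype_matrix()] with integer (unimputed) dosages.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  d <- g$dosages
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
    stop_wgp("write_plink requires integer dosages")
  n <- nrow(d); m <- ncol(d)
  code <- matrix(3L, nrow = n, ncol = m)         # hom A2
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[is.na(d)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  i4 <- seq(1, 4 * bytes_per_snp, by = 4)
  packed <- code[i4, , drop = FALSE] + 4L * code[i4 + 1, , drop = FALSE] +
    16L * code[i4 + 2, , drop = FALSE] + 64L * code[i4 + 3, , drop = FALSE]
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(as.vector(packed))),
           paste0(prefix, ".bed"))
  utils::write.table(
    data.frame(g$snps$chrom, g$snps$snp_id, 0, g$snps$pos, g$snps$a1, g$snps$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$subject_ids, g$subject_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read/write the plain-text dosage dialect
#'
#' Header row of SNP ids, then one row per subject: subject id followed by
#' dosages 0/1/2 (or fractional after imputation) with `NA` for missing.
#'
#' @param path file path.
#' @param g a [genotype_matrix()] (for writing).
#' @return for `read_dosage`, a [genotype_matrix()].
#' @export
read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  genotype_matrix(d, subject_ids = as.character(df[[1]]))
}

#' @rdname read_dosage
#' @export
write_dosage <- function(g, path) {
  df <- data.frame(subject_id = g$subject_ids, g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
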