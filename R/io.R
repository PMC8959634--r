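#' Read a PLINK bed/bim/fam genotype triplet
#'
#' Decodes the binary bed format (v1.00 magic bytes 0x6c 0x1b,
#' SNP-major mode byte 0x01; 2-bit genotype codes, four samples per
#' byte).  Dosages count the A1 allele of the bim file: code 00 -> 2,
#' 10 -> 1, 11 -> 0, 01 -> missing.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam`
#'   must exist.
#' @return a `genotype_matrix`.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)

  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  ids <- fam_df[[2]]
  if (anyDuplicated(ids)) stop("duplicate IID in fam file")
  n <- length(ids); m <- nrow(bim_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (magic byte mismatch)")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) != 3 + bps * m)
    stop("truncated bed file: expected ", 3 + bps * m, " bytes, found ",
         length(raw))

  # 2-bit code -> dosage lookup for all 256 byte values x 4 sample slots
  codes <- as.integer(raw[-(1:3)])
  lut <- matrix(NA_integer_, 256, 4)
  code_map <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  for (b in 0:255) for (s in 1:4)
    lut[b + 1, s] <- code_map[[as.character(bitwAnd(bitwShiftR(b, 2L * (s - 1L)), 3L))]]
  dos <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    bytes <- codes[((j - 1) * bps + 1):(j * bps)]
    vals <- lut[cbind(rep(bytes + 1L, each = 4), rep(1:4, bps))]
    dos[, j] <- vals[seq_len(n)]
  }
  genotype_matrix(dos, sample_ids = ids, snp_ids = bim_df[[2]])
}

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' @param g a `genotype_matrix`.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  n <- nrow(dos); m <- ncol(dos)
  fam <- data.frame(g$sample_ids, g$sample_ids, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(1, g$snp_ids, 0, seq_len(m), "A", "G")
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  bps <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bps - n
  for (j in seq_len(m)) {
    cd <- c(code_of(dos[, j]), rep(0L, pad))
    byte <- cd[seq(1, 4 * bps, 4)] + 4L * cd[seq(2, 4 * bps, 4)] +
      16L * cd[seq(3, 4 * bps, 4)] + 64L * cd[seq(4, 4 * bps, 4)]
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Write a GRM in the GCTA binary triplet format
#'
#' `prefix.grm.bin`: float32 lower triangle (including diagonal) in pair
#' order (1,1), (2,1), (2,2), ...; `prefix.grm.N.bin`: float32 SNP count
#' per pair; `prefix.grm.id`: FID/IID table.
#'
#' @param k a `grm`.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
write_grm <- function(k, prefix) {
  stopifnot(inherits(k, "grm"))
  n <- nrow(k$K)
  idx <- which(lower.tri(k$K, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- k$K[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  nsnp <- if (is.na(k$n_snps)) 0 else k$n_snps
  writeBin(rep(as.numeric(nsnp), length(vals)), con, size = 4)
  close(con)
  write.table(data.frame(k$sample_ids, k$sample_ids),
              paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM triplet
#'
#' @param prefix path prefix of `prefix.grm.bin`, `prefix.grm.N.bin`,
#'   `prefix.grm.id`.
#' @return a `grm`.
#' @export
read_grm <- function(prefix) {
  idf <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(idf)
  nv <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nv, size = 4)
  if (length(vals) != nv) stop("truncated grm.bin")
  K <- matrix(0, n, n)
  K[upper.tri(K, diag = TRUE)] <- 0
  idx <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  K[idx] <- vals
  K <- K + t(K) - diag(diag(K))
  nfile <- paste0(prefix, ".grm.N.bin")
  n_snps <- if (file.exists(nfile))
    as.integer(readBin(nfile, "numeric", n = 1, size = 4)) else NA_integer_
  grm(K, idf[[2]], n_snps)
}

#' Read a two-column IID/value TSV
#'
#' The phenotype/covariate exchange format: a header line `IID<tab>value`
#' (any value column name), one row per individual.
#'
#' @param path file path.
#' @return data frame with `IID` and the value column.
#' @export
read_iid_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (names(d)[1] != "IID") stop("first column must be IID")
  if (anyDuplicated(d$IID)) stop("duplicate IID in ", path)
  d
}

#' Write a two-column IID/value TSV
#'
#' @param ids individual identifiers.
#' @param values numeric values.
#' @param path output path.
#' @param value_name header name of the value column.
#' @return invisibly, the path.
#' @export
write_iid_tsv <- function(ids, values, path, value_name = "value") {
  d <- data.frame(IID = ids, v = values)
  names(d)[2] <- value_name
  write.table(d, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
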