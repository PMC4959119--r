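# PLINK 1 binary (BED/BIM/FAM) reader and writer.  SNP-major layout only:
# magic bytes 0x6C 0x1B, mode byte 0x01, genotypes packed 4 subjects per
# byte (subject 1 in the two least-significant bits) with 2-bit codes
# 00 = hom A1 (dosage 2), 10 = het (1), 11 = hom A2 (0), 01 = missing.

PLINK_MAGIC <- as.raw(c(0x6C, 0x1B))

#' Read genotypes from a PLINK 1 binary fileset or dosage TSV
#'
#' `path` may be a PLINK prefix (with `.bed`/`.bim`/`.fam` alongside), an
#' explicit `.bed` path, or a headered dosage TSV (subjects x SNPs, first
#' column subject id).
#'
#' @param path File prefix or path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  if (file.exists(paste0(prefix, ".bed"))) return(read_plink(prefix))
  if (file.exists(path)) return(read_dosage_tsv(path))
  stop_pf("no PLINK fileset or dosage TSV at %s", path)
}

read_dosage_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  ids <- d[[1]]
  D <- as.matrix(d[, -1, drop = FALSE])
  snp_records <- data.frame(id = colnames(D),
                            chrom = 1L, pos = seq_len(ncol(D)),
                            a1 = "A", a2 = "G")
  genotype_matrix(D, snp_records, data.frame(id = ids))
}

#' Write a genotype matrix as a PLINK 1 binary fileset
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  sr <- G$snp_records
  write.table(
    data.frame(sr$chrom, sr$id, 0, sr$pos, sr$a1, sr$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  sam <- G$sample_records
  sex <- if ("sex" %in% names(sam)) sam$sex + 1L else 0L
  phe <- if ("group" %in% names(sam)) sam$group + 1L else -9L
  write.table(
    data.frame(sam$id, sam$id, 0, 0, sex, phe),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  D <- G$dosages
  n <- nrow(D)
  codes <- matrix(3L, nrow = 4L * ceiling(n / 4), ncol = ncol(D))
  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  for (j in seq_len(ncol(D))) {
    x <- D[, j]
    cc <- ifelse(is.na(x), 1L, code_of[as.character(x)])
    codes[seq_len(n), j] <- cc
    codes[seq.int(n + 1, length.out = nrow(codes) - n), j] <- 0L  # pad bits
  }
  dim(codes) <- c(4L, length(codes) / 4L)
  bytes <- as.raw(codes[1, ] + codes[2, ] * 4L + codes[3, ] * 16L +
                    codes[4, ] * 64L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(PLINK_MAGIC, as.raw(0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"),
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"),
                    col.names = c("fid", "id", "pid", "mid", "sex", "pheno"))
  n <- nrow(fam); p <- nrow(bim)
  bpv <- ceiling(n / 4)
  expected <- 3 + bpv * p
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = expected + 1)
  if (length(raw) < 3 || !identical(raw[1:2], PLINK_MAGIC)) {
    stop_pf("not a PLINK 1 BED file (magic byte mismatch)")
  }
  if (raw[3] != as.raw(0x01)) {
    stop_pf("unsupported BED mode 0x%02x (only SNP-major 0x01)", as.integer(raw[3]))
  }
  if (length(raw) != expected) {
    stop_pf("truncated BED: expected %d bytes, found %d", expected, length(raw))
  }
  body <- as.integer(raw[-(1:3)])
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  dim(codes) <- c(4L * bpv, p)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage_of <- c(2, NA, 1, 0)          # codes 0,1,2,3
  D <- matrix(dosage_of[codes + 1L], n, p)
  sample_records <- data.frame(id = as.character(fam$id))
  if (any(fam$sex %in% 1:2)) sample_records$sex <- fam$sex - 1L
  if (any(fam$pheno %in% 1:2)) sample_records$group <- fam$pheno - 1L
  genotype_matrix(D, bim[, c("id", "chrom", "pos", "a1", "a2")],
                  sample_records)
}

#' Decode one SNP-major BED genotype byte (4 subjects)
#'
#' Exposed for verifying the 2-bit decoding against the file-format table.
#'
#' @param byte A raw byte or integer 0-255.
#' @return Dosages of the 4 encoded subjects (A1-allele count, NA missing).
#' @export
decode_bed_byte <- function(byte) {
  b <- as.integer(byte)
  codes <- c(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  c(2, NA, 1, 0)[codes + 1L]
}
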