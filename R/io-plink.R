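# Minimal PLINK 1 binary (.bed/.bim/.fam) codec, SNP-major layout.
# Byte layout: magic 0x6c 0x1b, mode 0x01; then ceil(N/4) bytes per SNP,
# two bits per sample starting at the low-order bits. Two-bit codes:
# 00 = homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2.
# Dosages count copies of the A1 allele (.bim column 5), which is mapped to
# the container's alternate allele.

#' Read PLINK bed/bim/fam genotypes
#'
#' Reads unphased dosages for the QC stages. The A1 allele of the `.bim`
#' file becomes the counted (alternate) allele.
#'
#' @param prefix Path prefix: `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [dosage_genotypes()] object (entries 0/1/2 or `NA`).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(sprintf("missing PLINK file `%s`", f),
                               class = "hapblup_io_error")
  }
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "snp_id", "cm", "pos",
                                            "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(fam_df[[2L]])
  n <- length(samples); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK .bed file (bad magic bytes)", class = "hapblup_format_error")
  }
  if (raw[3] != as.raw(0x01)) {
    abort("only SNP-major .bed files are supported", class = "hapblup_format_error")
  }
  bps <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bps * m) {
    abort("bed payload size does not match bim/fam dimensions",
          class = "hapblup_format_error")
  }
  # expand each byte into 4 two-bit codes (low bits first)
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  dim(codes) <- c(4L * bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)  # A1 copy count
  dos <- matrix(lut[codes + 1L], n, m)
  map <- tibble(snp_id = as.character(bim_df$snp_id),
                chrom = as.character(bim_df$chrom),
                pos = as.integer(bim_df$pos),
                ref = as.character(bim_df$a2), alt = as.character(bim_df$a1))
  dosage_genotypes(dos, samples, map)
}

#' Write genotypes as PLINK bed/bim/fam
#'
#' Counterpart of [read_plink()]; phased input is collapsed to unphased
#' dosages. Mainly used to build test inputs in code.
#'
#' @param geno A [phased_genotypes()] or [dosage_genotypes()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, `prefix`.
#' @export
write_plink <- function(geno, prefix) {
  d <- dosage(geno)
  n <- nrow(d); m <- ncol(d)
  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0, map$pos, map$alt, map$ref),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(rownames(d), rownames(d), 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, sep = " ",
    row.names = FALSE, col.names = FALSE)
  code_of <- function(g) {
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2] <- 0L
    out[!is.na(g) & g == 1] <- 2L
    out[!is.na(g) & g == 0] <- 3L
    out
  }
  bps <- ceiling(n / 4)
  bytes <- raw(3 + bps * m)
  bytes[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  for (j in seq_len(m)) {
    cd <- code_of(d[, j])
    length(cd) <- 4L * bps  # pad with NA -> treat as 0
    cd[is.na(cd)] <- 0L
    quads <- matrix(cd, 4L)
    bytes[3L + (j - 1L) * bps + seq_len(bps)] <-
      as.raw(quads[1, ] + 4L * quads[2, ] + 16L * quads[3, ] + 64L * quads[4, ])
  }
  writeBin(bytes, paste0(prefix, ".bed"))
  invisible(prefix)
}
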