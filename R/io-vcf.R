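#' Write phased genotypes as VCF 4.2
#'
#' Emits a minimal phased VCF with `|`-separated GT fields, one record per
#' biallelic SNP, in map order.
#'
#' @param geno A [phased_genotypes()] object.
#' @param path Output file path (plain text).
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(geno, path) {
  h <- geno$haplotypes
  n <- length(geno$samples)
  a1 <- h[seq(1L, 2L * n, 2L), , drop = FALSE]
  a2 <- h[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(t(a1), "|", t(a2)), nrow = ncol(h))  # m x N
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapblup",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t"))
  body <- paste(geno$map$chrom, geno$map$pos, geno$map$snp_id, geno$map$ref,
                geno$map$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open `%s` for writing: %s", path, conditionMessage(e)),
          class = "hapblup_io_error")
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a phased VCF into a genotype container
#'
#' Accepts VCF 4.2 with biallelic SNPs and fully phased GT fields. Unphased
#' or multi-allelic records are rejected with their positions listed, since
#' haplotype-allele recoding needs ordered chromosome copies.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A [phased_genotypes()] object.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "") | is.na(fix$ALT) |
    nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    abort(sprintf("multi-allelic or non-SNP records are not supported: %s",
                  paste(head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 10L),
                        collapse = ", ")),
          class = "hapblup_format_error")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt)) {
    bad <- which(rowSums(is.na(gt)) > 0)
    abort(sprintf("missing genotypes at %d site(s); impute before import (e.g. %s)",
                  length(bad),
                  paste(head(paste0(fix$CHROM[bad], ":", fix$POS[bad]), 5L),
                        collapse = ", ")),
          class = "hapblup_format_error")
  }
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    bad <- which(rowSums(matrix(unphased, nrow = nrow(gt))) > 0)
    abort(sprintf("unphased genotypes ('/' separator) at %d site(s): %s; phase before import",
                  length(bad),
                  paste(head(paste0(fix$CHROM[bad], ":", fix$POS[bad]), 10L),
                        collapse = ", ")),
          class = "hapblup_phasing_error")
  }
  m <- nrow(gt); samples <- colnames(gt)
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = m)
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = m)
  if (anyNA(h1) || anyNA(h2) || any(h1 > 1L) || any(h2 > 1L)) {
    abort("GT fields must be biallelic 0|0, 0|1, 1|0 or 1|1",
          class = "hapblup_format_error")
  }
  # rows 2i-1 / 2i per individual
  haps <- matrix(0L, 2L * length(samples), m)
  haps[seq(1L, 2L * length(samples), 2L), ] <- t(h1)
  haps[seq(2L, 2L * length(samples), 2L), ] <- t(h2)
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, "_", fix$POS), ids)
  }
  map <- tibble(snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT)
  phased_genotypes(haps, samples, map)
}

#' Read a pedigree CSV
#'
#' Expects columns `animal`, `sire`, `dam`, `birthdate` (ISO dates); `0`
#' denotes an unknown parent.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_pedigree_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    animal = readr::col_character(), sire = readr::col_character(),
    dam = readr::col_character(), birthdate = readr::col_date()))
}

#' Read a phenotype CSV
#'
#' Expects columns `animal`, `parity`, `hys`, `value`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_phenotypes_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    animal = readr::col_character(), parity = readr::col_integer(),
    hys = readr::col_character(), value = readr::col_double()))
}
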