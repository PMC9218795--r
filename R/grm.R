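#' Genomic relationship matrix from a dosage matrix
#'
#' Centers each column by twice its allele frequency and scales the
#' cross-product by the heterozygosity sum:
#' `G = M M' / (2 * sum(p_i * (1 - p_i)))`, with `M[, i] = dosage_i - 2 p_i`
#' and `p_i` the observed column frequency. The identical formula applied to
#' haplotype-allele columns yields the haplotype relationship matrix GH.
#'
#' @param dm A `dosage_matrix` (from [snp_dosage_matrix()] or
#'   [recode_haplotype_dosages()]), or a plain numeric matrix (frequencies
#'   taken as column means / 2).
#' @param source Optional source label override.
#' @return An object of class `grm`: `mat` (symmetric `N x N`), `samples`,
#'   `divisor` (the `2 * sum(p(1-p))` actually used) and `source`.
#' @export
compute_grm <- function(dm, source = NULL) {
  if (is.matrix(dm)) dm <- new_dosage_matrix(dm, colMeans(dm) / 2,
                                             source %||% "snp")
  p <- dm$freq
  divisor <- 2 * sum(p * (1 - p))
  if (divisor <= 0) {
    abort("all columns are monomorphic: relationship matrix divisor is zero",
          class = "hapblup_degenerate_panel_error")
  }
  M <- sweep(dm$mat, 2L, 2 * p)
  G <- tcrossprod(M) / divisor
  structure(list(mat = G, samples = rownames(dm$mat), divisor = divisor,
                 source = source %||% dm$source),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d x %d (%s columns), divisor %.4g, mean diagonal %.4g\n",
              nrow(x$mat), ncol(x$mat), x$source, x$divisor,
              mean(diag(x$mat))))
  invisible(x)
}

#' Single-SNP-haplotype identity between G and GH
#'
#' Treating every SNP as its own one-SNP haplotype gives each SNP two
#' complementary dosage columns (`g` and `2 - g`). Their centered columns are
#' exact negatives, so the cross-product doubles, and the frequency sum
#' `p(1-p) + (1-p)p` doubles the divisor — the haplotype matrix GH then
#' equals the SNP matrix G identically, making haplotype-based prediction
#' with singleton blocks coincide with SNP-based prediction.
#'
#' @param geno A QC'd [phased_genotypes()] object.
#' @return A list: `G`, `GH_snp1` (both `grm`) and `max_abs_diff`, the
#'   elementwise maximum absolute difference.
#' @export
grm_identity_snp1 <- function(geno) {
  G <- compute_grm(snp_dosage_matrix(geno))
  GH <- compute_grm(recode_haplotype_dosages(geno, singleton_partition(geno),
                                             include_singletons = TRUE))
  list(G = G, GH_snp1 = GH, max_abs_diff = max(abs(G$mat - GH$mat)))
}

#' Write a relationship matrix as TSV
#'
#' Full symmetric matrix with a sample-id header row and a leading sample-id
#' column.
#'
#' @param grm A `grm` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_grm_tsv <- function(grm, path) {
  df <- as.data.frame(grm$mat)
  names(df) <- grm$samples
  df <- cbind(sample = grm$samples, df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}
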