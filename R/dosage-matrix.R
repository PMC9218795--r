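# Dosage matrices: N x H real matrices of allele (or haplotype-allele) copy
# counts with per-column frequencies, the common input of the relationship
# matrix builders.

new_dosage_matrix <- function(mat, freq, source) {
  stopifnot(ncol(mat) == length(freq))
  structure(list(mat = mat, freq = freq, source = source),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d %s column(s)\n",
              nrow(x$mat), ncol(x$mat), x$source))
  invisible(x)
}

#' SNP dosage matrix
#'
#' Alternate-allele copy counts per SNP with column frequencies
#' `p_i = column mean / 2` — the `M` matrix of the SNP relationship matrix.
#'
#' @param geno Genotype container.
#' @param snp_ids Optional subset of SNP ids (map order preserved).
#' @return A `dosage_matrix` with `source = "snp"`.
#' @export
snp_dosage_matrix <- function(geno, snp_ids = NULL) {
  d <- dosage(geno)
  if (!is.null(snp_ids)) {
    j <- match(snp_ids, geno$map$snp_id)
    if (anyNA(j)) abort("unknown SNP id in `snp_ids`")
    d <- d[, sort(j), drop = FALSE]
  }
  if (anyNA(d)) abort("missing genotypes: impute or QC before building dosage matrices")
  new_dosage_matrix(d, colMeans(d) / 2, "snp")
}

#' Numerical dosage recoding of haplotype alleles
#'
#' For every block of the partition, each distinct haplotype string observed
#' across all `2N` chromosome copies becomes one pseudo-marker column whose
#' entry is the number of the individual's two haplotypes carrying that
#' string (0, 1 or 2); within a block every row sums to 2. With
#' `include_singletons = TRUE` each non-blocked SNP contributes two
#' complementary columns (alternate- and reference-allele copy counts), so
#' that every marker is represented — the single-SNP-as-haplotype mode.
#' Column frequencies are `column sum / 2N`.
#'
#' @param geno A [phased_genotypes()] object.
#' @param part A `haploblock_partition` over the same marker set.
#' @param include_singletons Include non-blocked SNPs as one-SNP haplotypes.
#' @param min_allele_count Drop haplotype-allele columns observed fewer than
#'   this many times (default 1 = keep all, no rare-allele filter).
#' @return A `dosage_matrix` with `source = "haplotype"`.
#' @export
recode_haplotype_dosages <- function(geno, part, include_singletons = TRUE,
                                     min_allele_count = 1L) {
  if (!inherits(geno, "phased_genotypes")) {
    abort("haplotype-allele recoding needs phased input",
          class = "hapblup_phasing_error")
  }
  if (!all(unlist(part$blocks$snp_ids) %in% geno$map$snp_id) ||
      !all(part$nonblocked %in% geno$map$snp_id)) {
    abort("partition refers to SNPs absent from the genotypes")
  }
  n <- length(geno$samples)
  odd <- seq(1L, 2L * n, 2L); even <- odd + 1L
  cols <- list(); freqs <- list(); nms <- list()
  for (b in seq_len(nrow(part$blocks))) {
    members <- match(part$blocks$snp_ids[[b]], geno$map$snp_id)
    s <- apply(geno$haplotypes[, members, drop = FALSE], 1L, paste0,
               collapse = "")
    lv <- part$blocks$alleles[[b]]$haplotype
    ind <- outer(s, lv, "==") * 1
    block_mat <- ind[odd, , drop = FALSE] + ind[even, , drop = FALSE]
    cnt <- colSums(block_mat)
    keep <- cnt >= min_allele_count
    cols[[length(cols) + 1L]] <- block_mat[, keep, drop = FALSE]
    freqs[[length(freqs) + 1L]] <- cnt[keep] / (2 * n)
    nms[[length(nms) + 1L]] <- paste0(part$blocks$block_id[b], ":", lv[keep])
  }
  if (include_singletons && length(part$nonblocked) > 0) {
    j <- match(part$nonblocked, geno$map$snp_id)
    g <- dosage(geno)[, j, drop = FALSE]
    sing <- matrix(0, n, 2L * length(j))
    sing[, seq(1L, 2L * length(j), 2L)] <- g
    sing[, seq(2L, 2L * length(j), 2L)] <- 2 - g
    cols[[length(cols) + 1L]] <- sing
    p_alt <- colMeans(g) / 2
    fr <- numeric(2L * length(j))
    fr[seq(1L, 2L * length(j), 2L)] <- p_alt
    fr[seq(2L, 2L * length(j), 2L)] <- 1 - p_alt
    freqs[[length(freqs) + 1L]] <- fr
    nm <- character(2L * length(j))
    nm[seq(1L, 2L * length(j), 2L)] <- paste0(part$nonblocked, ":alt")
    nm[seq(2L, 2L * length(j), 2L)] <- paste0(part$nonblocked, ":ref")
    nms[[length(nms) + 1L]] <- nm
  }
  if (length(cols) == 0L) abort("partition yields no columns to recode")
  mat <- do.call(cbind, cols)
  rownames(mat) <- geno$samples
  colnames(mat) <- unlist(nms)
  new_dosage_matrix(mat, unlist(freqs, use.names = FALSE), "haplotype")
}
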