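#' Pairwise linkage disequilibrium on genotype dosages
#'
#' Composite-LD r-squared between two loci: the squared Pearson correlation
#' of their 0/1/2 genotype dosage vectors,
#' `r2 = cov(g_i, g_j)^2 / (var(g_i) * var(g_j))`. Bounded in `[0, 1]` and
#' invariant to which allele of either locus is counted.
#'
#' @param g_i,g_j Numeric dosage vectors of equal length (>= 2), each
#'   non-constant.
#' @return `r2` in `[0, 1]`.
#' @export
pairwise_r2 <- function(g_i, g_j) {
  signed_r(g_i, g_j)^2
}

#' Signed LD correlation of genotype dosages
#'
#' Pearson correlation of dosages with its sign retained, anchored to a fixed
#' allele orientation (alternate-allele counts at both loci). The sign is the
#' quantity compared between populations to measure LD-phase consistency;
#' `signed_r()^2` equals [pairwise_r2()].
#'
#' @inheritParams pairwise_r2
#' @return `r` in `[-1, 1]`.
#' @export
signed_r <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) abort("dosage vectors must have equal length")
  if (length(g_i) < 2) abort("need at least two individuals")
  if (var(g_i) == 0 || var(g_j) == 0) {
    abort("LD is undefined for a monomorphic locus (zero dosage variance)",
          class = "hapblup_undefined_ld_error")
  }
  cor(g_i, g_j)
}

#' Between-population LD-phase consistency
#'
#' Computes signed LD `r` for every within-chromosome SNP pair closer than
#' `max_pair_distance` base pairs in each population, then returns the
#' Pearson correlation between the two populations' `r` vectors. A value of
#' 1 means identical LD phase; drift between closed populations pushes it
#' down. Pairs involving a locus monomorphic in either population are
#' skipped.
#'
#' @param geno_pop1,geno_pop2 Genotype containers over identical marker sets.
#' @param max_pair_distance Maximum pair distance in base pairs (default
#'   5 Mb, about 5 cM on the simulated map; long-range pairs carry no
#'   ancestral LD and only dilute the diagnostic with drift noise).
#' @return The phase-consistency scalar.
#' @export
ld_phase_correlation <- function(geno_pop1, geno_pop2,
                                 max_pair_distance = 5e6) {
  if (!identical(geno_pop1$map$snp_id, geno_pop2$map$snp_id)) {
    abort("the two populations must share an identical marker set")
  }
  d1 <- dosage(geno_pop1); d2 <- dosage(geno_pop2)
  r1 <- numeric(0); r2v <- numeric(0)
  for (cc in unique(geno_pop1$map$chrom)) {
    idx <- which(geno_pop1$map$chrom == cc)
    if (length(idx) < 2) next
    poly <- idx[matrixStats_colVars(d1[, idx, drop = FALSE]) > 0 &
                  matrixStats_colVars(d2[, idx, drop = FALSE]) > 0]
    if (length(poly) < 2) next
    c1 <- cor(d1[, poly, drop = FALSE])
    c2 <- cor(d2[, poly, drop = FALSE])
    pos <- geno_pop1$map$pos[poly]
    sel <- upper.tri(c1) & (abs(outer(pos, pos, "-")) <= max_pair_distance)
    r1 <- c(r1, c1[sel]); r2v <- c(r2v, c2[sel])
  }
  if (length(r1) < 2) {
    abort("fewer than two valid SNP pairs: cannot estimate LD-phase consistency",
          class = "hapblup_insufficient_data_error")
  }
  cor(r1, r2v)
}
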