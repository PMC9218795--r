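#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided SNP exact test conditioning on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Probabilities are built by recurrence from the most probable heterozygote
#' count, which is stable for desk-scale sample sizes.
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom1,n_hom2 Observed counts of the two homozygote classes.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  n_het <- as.integer(n_het); n_hom1 <- as.integer(n_hom1)
  n_hom2 <- as.integer(n_hom2)
  if (min(n_het, n_hom1, n_hom2) < 0) abort("genotype counts must be >= 0")
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  rare <- 2L * min(n_hom1, n_hom2) + n_het
  if (rare == 0L) return(1)
  hets <- seq(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  probs <- setNames(numeric(length(hets)), hets)
  # start at the conditional mode
  mid <- rare * (2 * n - rare) / (2 * n)
  mid <- hets[which.min(abs(hets - mid))]
  probs[as.character(mid)] <- 1
  h <- mid
  while (h - 2L >= hets[1]) {
    # hom counts implied by h heterozygotes
    hr <- (rare - h) / 2; hc <- n - h - hr
    probs[as.character(h - 2L)] <- probs[as.character(h)] *
      h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    h <- h - 2L
  }
  h <- mid
  while (h + 2L <= hets[length(hets)]) {
    hr <- (rare - h) / 2; hc <- n - h - hr
    probs[as.character(h + 2L)] <- probs[as.character(h)] *
      4 * hr * hc / ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  p_obs <- probs[as.character(n_het)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Variant quality control
#'
#' Applies the standard chip-QC filters in the order call rate, then minor
#' allele frequency, then Hardy-Weinberg (each computed on the SNPs retained
#' by the previous filter, using non-missing genotypes). Defaults are the
#' conventional thresholds MAF < 1%, call rate < 90%, HWE exact p < 1e-7.
#'
#' @param geno A [phased_genotypes()] or [dosage_genotypes()] object.
#' @param maf_min Minimum minor allele frequency.
#' @param callrate_min Minimum per-SNP genotyping call rate.
#' @param hwe_p_min Minimum HWE exact-test p-value.
#' @return A list of class `qc_result`: `genotypes` (same container type,
#'   filtered) and `report` (tibble with per-filter removal counts; its
#'   `notes` attribute records the test and frequency-scope conventions).
#' @export
apply_variant_qc <- function(geno, maf_min = 0.01, callrate_min = 0.90,
                             hwe_p_min = 1e-7) {
  check_prob(maf_min, "maf_min"); check_prob(callrate_min, "callrate_min")
  check_prob(hwe_p_min, "hwe_p_min")
  d <- dosage(geno)
  m0 <- ncol(d)
  keep <- seq_len(m0)

  cr <- colMeans(!is.na(d))
  fail_cr <- keep[cr < callrate_min]
  keep <- setdiff(keep, fail_cr)

  p <- colMeans(d[, keep, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_maf <- keep[maf < maf_min]
  keep <- setdiff(keep, fail_maf)

  hwe_p <- vapply(keep, function(j) {
    g <- d[, j]; g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 1), sum(g == 0), sum(g == 2))
  }, numeric(1))
  fail_hwe <- keep[hwe_p < hwe_p_min]
  keep <- setdiff(keep, fail_hwe)

  if (length(keep) == 0L) {
    abort("all SNPs removed by QC: empty marker panel",
          class = "hapblup_empty_panel_error")
  }
  report <- tibble(
    filter = c("call_rate", "maf", "hwe"),
    threshold = c(callrate_min, maf_min, hwe_p_min),
    n_input = c(m0, m0 - length(fail_cr),
                m0 - length(fail_cr) - length(fail_maf)),
    n_removed = c(length(fail_cr), length(fail_maf), length(fail_hwe)),
    n_retained = c(m0 - length(fail_cr),
                   m0 - length(fail_cr) - length(fail_maf), length(keep)))
  attr(report, "notes") <- c(
    "hwe_test=exact enumeration conditional on allele counts (not chi-square)",
    "maf_scope=frequencies computed on the input sample set as supplied; merge populations before QC for pooled-frequency filtering")
  structure(list(genotypes = subset_markers(geno, keep), report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report)
  invisible(x)
}

#' Write a QC report as TSV
#'
#' The convention notes carried by the report are written as `#`-prefixed
#' header lines.
#'
#' @param qc A `qc_result` from [apply_variant_qc()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(qc, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", attr(qc$report, "notes")), con)
  utils::write.table(qc$report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove near-duplicate SNPs in extreme LD
#'
#' Greedy left-to-right scan within each chromosome: a SNP is dropped when
#' its dosage r-squared with an earlier *kept* SNP reaches `r2_cut`; dropped
#' SNPs seed no further comparisons, so exactly one representative of each
#' duplicate run survives (the first in map order).
#'
#' @param geno Genotype container.
#' @param r2_cut LD threshold in `(0, 1]` at or above which the later SNP of
#'   a pair is removed (default 0.999).
#' @param max_window_snps Lookback window, in kept-SNP count, for pairwise
#'   comparisons (default: whole chromosome).
#' @return A list: `genotypes` (filtered) and `pairs` (tibble `kept`,
#'   `removed`, `r2` recording why each SNP was dropped).
#' @export
prune_duplicate_ld <- function(geno, r2_cut = 0.999, max_window_snps = Inf) {
  if (!is.numeric(r2_cut) || r2_cut <= 0 || r2_cut > 1) {
    stop_config("r2_cut", "must be in (0, 1]")
  }
  d <- dosage(geno)
  keep_all <- integer(0)
  pairs <- list()
  for (cc in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == cc)
    kept <- integer(0)
    for (j in idx) {
      cand <- utils::tail(kept, if (is.finite(max_window_snps)) max_window_snps else length(kept))
      drop_it <- FALSE
      if (length(cand) > 0) {
        r2 <- suppressWarnings(
          cor(d[, cand, drop = FALSE], d[, j], use = "pairwise.complete.obs"))^2
        hit <- which(!is.na(r2) & r2 >= r2_cut)
        if (length(hit) > 0) {
          drop_it <- TRUE
          pairs[[length(pairs) + 1L]] <- tibble(
            kept = geno$map$snp_id[cand[hit[1]]],
            removed = geno$map$snp_id[j], r2 = r2[hit[1]])
        }
      }
      if (!drop_it) kept <- c(kept, j)
    }
    keep_all <- c(keep_all, kept)
  }
  list(genotypes = subset_markers(geno, keep_all),
       pairs = if (length(pairs)) bind_rows(pairs) else
         tibble(kept = character(), removed = character(), r2 = numeric()))
}
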