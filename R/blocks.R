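#' The default ladder of LD thresholds
#'
#' Nine levels of the pairwise-r2 threshold used to build haploblocks:
#' 0.1, 0.2, ..., 0.9. In the limit r2 -> 0 a whole chromosome becomes one
#' block; in the limit r2 -> 1 every SNP stands alone.
#'
#' @param thresholds Strictly increasing values in `(0, 1)`.
#' @return The validated numeric ladder.
#' @export
ld_threshold_ladder <- function(thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0)) {
    stop_config("thresholds", "must be strictly increasing values in (0, 1)")
  }
  thresholds
}

# Internal constructor; `blocks` is a tibble with block_id, chrom,
# start_pos, end_pos, n_snps, snp_ids (list), alleles (list of tibbles).
new_haploblock_partition <- function(threshold, blocks, nonblocked, map) {
  structure(list(threshold = threshold, blocks = blocks,
                 nonblocked = nonblocked, map = map),
            class = "haploblock_partition")
}

#' @export
print.haploblock_partition <- function(x, ...) {
  cat(sprintf("<haploblock_partition> threshold %.3g: %d block(s) covering %d SNPs, %d singleton SNP(s)\n",
              x$threshold, nrow(x$blocks), sum(x$blocks$n_snps),
              length(x$nonblocked)))
  invisible(x)
}

# Distinct haplotype strings and frequencies for one block (columns `cols`).
.block_alleles <- function(hap, cols) {
  s <- apply(hap[, cols, drop = FALSE], 1L, paste0, collapse = "")
  tb <- sort(table(s), decreasing = TRUE)
  tibble(haplotype = names(tb), freq = as.numeric(tb) / length(s))
}

#' Build variable-length haploblocks at one LD threshold
#'
#' Greedy left-to-right complete-linkage grouping of consecutive SNPs within
#' each chromosome: a block opens at the first unassigned SNP and the next
#' consecutive SNP joins only if its dosage r-squared with *every* current
#' member (within a `max_window_snps` lookback) is at or above the threshold;
#' when extension fails the block closes and a new one opens. Runs of size
#' one are reclassified as non-blocked singleton SNPs. Ties at exactly the
#' threshold are included ("greater than or equal").
#'
#' @param geno A QC'd [phased_genotypes()] object (no monomorphic SNPs).
#' @param threshold Pairwise-r2 threshold in `(0, 1]`.
#' @param max_window_snps Complete-linkage lookback cap (default 100).
#' @return A `haploblock_partition`: `blocks` (tibble with `block_id`,
#'   `chrom`, `start_pos`, `end_pos`, `n_snps`, list-columns `snp_ids` and
#'   `alleles` with observed haplotype strings and frequencies) and
#'   `nonblocked` (singleton SNP ids).
#' @export
build_blocks <- function(geno, threshold, max_window_snps = 100) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_config("threshold", "must be in (0, 1]")
  }
  d <- dosage(geno)
  if (any(matrixStats_colVars(d) == 0)) {
    abort("monomorphic SNPs present: run apply_variant_qc() first",
          class = "hapblup_undefined_ld_error")
  }
  ord_ok <- geno$map |>
    group_by(.data$chrom) |>
    summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(ord_ok$ok)) abort("marker map must be sorted by position within chromosome")

  blocks <- list(); nonblocked <- character(0)
  for (cc in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == cc)
    i <- 1L
    runs <- list()
    while (i <= length(idx)) {
      members <- idx[i]
      j <- i + 1L
      while (j <= length(idx)) {
        cand <- idx[j]
        chk <- utils::tail(members, max_window_snps)
        r2 <- drop(cor(d[, chk, drop = FALSE], d[, cand]))^2
        if (all(r2 >= threshold)) {
          members <- c(members, cand); j <- j + 1L
        } else break
      }
      runs[[length(runs) + 1L]] <- members
      i <- j
    }
    for (members in runs) {
      if (length(members) >= 2L) {
        bid <- sprintf("%s_b%03d", cc, length(blocks) + 1L)
        blocks[[length(blocks) + 1L]] <- tibble(
          block_id = bid, chrom = cc,
          start_pos = geno$map$pos[members[1]],
          end_pos = geno$map$pos[members[length(members)]],
          n_snps = length(members),
          snp_ids = list(geno$map$snp_id[members]),
          alleles = list(.block_alleles(geno$haplotypes, members)))
      } else {
        nonblocked <- c(nonblocked, geno$map$snp_id[members])
      }
    }
  }
  blocks <- if (length(blocks)) bind_rows(blocks) else
    tibble(block_id = character(), chrom = character(),
           start_pos = integer(), end_pos = integer(), n_snps = integer(),
           snp_ids = list(), alleles = list())
  new_haploblock_partition(threshold, blocks, nonblocked, geno$map)
}

# Partition in which every SNP is a singleton (single-SNP-as-haplotype mode).
singleton_partition <- function(geno) {
  new_haploblock_partition(
    NA_real_,
    tibble(block_id = character(), chrom = character(), start_pos = integer(),
           end_pos = integer(), n_snps = integer(), snp_ids = list(),
           alleles = list()),
    geno$map$snp_id, geno$map)
}

#' Tabulate block statistics across a threshold ladder
#'
#' Counts blocked SNPs, haploblocks and observed haplotype alleles for each
#' partition; all three shrink as the threshold rises.
#'
#' @param parts A list of `haploblock_partition` objects over a common
#'   marker set (e.g. one per ladder threshold).
#' @return A tibble of class `hb_block_stats` with columns `threshold`,
#'   `n_blocked_snps`, `n_haploblocks`, `n_haplotype_alleles`,
#'   `n_nonblocked_snps`.
#' @export
block_statistics <- function(parts) {
  if (inherits(parts, "haploblock_partition")) parts <- list(parts)
  out <- purrr::map_dfr(parts, function(p) {
    tibble(threshold = p$threshold,
           n_blocked_snps = sum(p$blocks$n_snps),
           n_haploblocks = nrow(p$blocks),
           n_haplotype_alleles = sum(vapply(p$blocks$alleles, nrow, integer(1))),
           n_nonblocked_snps = length(p$nonblocked))
  })
  class(out) <- c("hb_block_stats", class(out))
  out
}

#' Write a haploblock partition as a BED-like TSV
#'
#' Columns: chromosome, start and end position (1-based inclusive), SNP
#' count, comma-separated SNP ids.
#'
#' @param part A `haploblock_partition`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_block_partition <- function(part, path) {
  df <- part$blocks |>
    mutate(snp_ids = vapply(.data$snp_ids, paste, character(1), collapse = ",")) |>
    select("chrom", "start_pos", "end_pos", "n_snps", "snp_ids")
  readr::write_tsv(df, path)
  invisible(path)
}
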