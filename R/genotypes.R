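#' Phased genotype container
#'
#' A `phased_genotypes` object stores N diploid individuals at m biallelic
#' SNPs as a `2N x m` binary haplotype matrix (0 = reference allele, 1 =
#' alternate allele). Rows `2i - 1` and `2i` are the two ordered chromosome
#' copies of individual `i`. The genotype dosage view (alternate-allele copy
#' count in 0/1/2) is always the column-wise sum of the haplotype pair.
#'
#' @param haplotypes Integer/numeric matrix of 0/1 values, `2N x m`.
#' @param samples Character vector of N unique sample identifiers.
#' @param map Marker map: a data frame with columns `snp_id`, `chrom`,
#'   `pos` (1-based base pairs, strictly increasing within chromosome),
#'   `ref`, `alt`, and optionally `pos_cm` (genetic position in centimorgans).
#' @param population Optional character vector of length N with a population
#'   label per sample.
#'
#' @return An object of class `phased_genotypes`.
#' @export
phased_genotypes <- function(haplotypes, samples, map, population = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  map <- as_tibble(map)
  n <- length(samples)
  if (nrow(haplotypes) != 2L * n) {
    abort("`haplotypes` must have 2 rows per sample")
  }
  if (anyDuplicated(samples)) abort("sample identifiers must be unique")
  req <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(map))) {
    abort(paste0("marker map must contain columns: ", paste(req, collapse = ", ")))
  }
  if (ncol(haplotypes) != nrow(map)) {
    abort("number of haplotype columns must equal number of map rows")
  }
  if (anyDuplicated(map$snp_id)) abort("SNP identifiers must be unique")
  bad <- map |>
    group_by(.data$chrom) |>
    summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    abort(sprintf("positions must be strictly increasing within chromosome (violated on %s)",
                  paste(bad$chrom[!bad$ok], collapse = ", ")))
  }
  if (!is.null(population) && length(population) != n) {
    abort("`population` must have one label per sample")
  }
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L))) {
    abort("haplotypes must be 0/1 with no missing entries")
  }
  colnames(haplotypes) <- map$snp_id
  rownames(haplotypes) <- paste0(rep(samples, each = 2L), c(".1", ".2"))
  structure(
    list(haplotypes = haplotypes, samples = as.character(samples),
         map = map, population = population),
    class = "phased_genotypes"
  )
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf("<phased_genotypes> %d samples x %d SNPs on %d chromosome(s)\n",
              length(x$samples), nrow(x$map), length(unique(x$map$chrom))))
  if (!is.null(x$population)) {
    tb <- table(x$population)
    cat("  populations:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genotype dosage matrix of a genotype container
#'
#' @param x A `phased_genotypes` or `dosage_genotypes` object.
#' @param ... Unused.
#' @return Numeric `N x m` matrix of alternate-allele copy counts (0/1/2),
#'   with sample row names and SNP column names. Unphased containers may
#'   contain `NA` for missing genotypes.
#' @export
dosage <- function(x, ...) UseMethod("dosage")

#' @export
dosage.phased_genotypes <- function(x, ...) {
  h <- x$haplotypes
  n <- length(x$samples)
  d <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(d) <- x$samples
  storage.mode(d) <- "double"
  d
}

#' @export
dosage.dosage_genotypes <- function(x, ...) x$dosage

#' Unphased genotype container
#'
#' Holds an `N x m` dosage matrix (0/1/2, `NA` = missing) with a marker map,
#' as read from PLINK bed/bim/fam. Used for QC stages that do not need phase.
#'
#' @param dosage Numeric matrix `N x m` with entries in 0/1/2 or `NA`.
#' @param samples Character vector of N sample ids.
#' @inheritParams phased_genotypes
#' @return An object of class `dosage_genotypes`.
#' @export
dosage_genotypes <- function(dosage, samples, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  map <- as_tibble(map)
  if (nrow(dosage) != length(samples)) abort("one dosage row per sample required")
  if (ncol(dosage) != nrow(map)) abort("one dosage column per map row required")
  rownames(dosage) <- samples
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, samples = as.character(samples), map = map),
            class = "dosage_genotypes")
}

#' @export
print.dosage_genotypes <- function(x, ...) {
  cat(sprintf("<dosage_genotypes> %d samples x %d SNPs (unphased)\n",
              length(x$samples), nrow(x$map)))
  invisible(x)
}

#' Subset a genotype container to marker indices
#'
#' @param geno Genotype container.
#' @param idx Column (map-order) indices to keep; sorted and deduplicated.
#' @return A container of the same class restricted to those markers.
#' @export
subset_markers <- function(geno, idx) {
  idx <- sort(unique(idx))
  if (inherits(geno, "phased_genotypes")) {
    phased_genotypes(geno$haplotypes[, idx, drop = FALSE], geno$samples,
                     geno$map[idx, , drop = FALSE], geno$population)
  } else {
    dosage_genotypes(geno$dosage[, idx, drop = FALSE], geno$samples,
                     geno$map[idx, , drop = FALSE])
  }
}

#' Subset a phased container to sample ids
#'
#' @param geno A [phased_genotypes()] object.
#' @param ids Sample ids to keep, in the requested order.
#' @return A [phased_genotypes()] object with those samples.
#' @export
subset_samples <- function(geno, ids) {
  stopifnot(inherits(geno, "phased_genotypes"))
  i <- match(ids, geno$samples)
  if (anyNA(i)) abort("unknown sample id in subset")
  rows <- as.vector(rbind(2L * i - 1L, 2L * i))
  phased_genotypes(geno$haplotypes[rows, , drop = FALSE], geno$samples[i],
                   geno$map, geno$population[i])
}

#' Merge two phased populations sharing a marker panel
#'
#' Stacks the samples of two `phased_genotypes` objects defined on an
#' identical marker map, preserving per-sample population labels.
#'
#' @param pop1,pop2 `phased_genotypes` objects with identical maps.
#' @param labels Length-2 character: population labels used when the inputs
#'   carry none.
#' @return A `phased_genotypes` object with all samples.
#' @export
merge_populations <- function(pop1, pop2, labels = c("pop1", "pop2")) {
  if (!identical(pop1$map$snp_id, pop2$map$snp_id)) {
    abort("populations must share an identical marker panel")
  }
  phased_genotypes(
    rbind(pop1$haplotypes, pop2$haplotypes),
    c(pop1$samples, pop2$samples),
    pop1$map,
    c(pop1$population %||% rep(labels[1], length(pop1$samples)),
      pop2$population %||% rep(labels[2], length(pop2$samples)))
  )
}
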