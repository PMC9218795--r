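#' Assign an additive QTL architecture and simulation ground truth
#'
#' Samples `n_qtl` causal loci among the polymorphic SNPs of `geno`, draws
#' standard-normal allele substitution effects, and rescales them so the
#' realized additive genetic variance among the supplied animals equals
#' `sigma_a2` exactly. Permanent-environment and residual variances are then
#' derived from the configured heritability and repeatability:
#' `sigma_pe2 = sigma_a2 * (repeatability - h2) / h2` and
#' `sigma_e2 = sigma_a2 * (1 - repeatability) / h2`.
#'
#' @param geno [phased_genotypes()] of the animals whose true breeding values
#'   anchor the variance scale (typically the merged genotyped set).
#' @param config A [sim_config()].
#' @param rng_seed Integer seed; defaults to `config$seed + 2`.
#' @param sigma_a2 Target additive variance (trait units squared).
#' @return A list of class `sim_truth`: `qtl_snp_ids`, `qtl_indices`,
#'   `qtl_effects`, `true_breeding_values` (named by animal), and
#'   `variance_components_true` (`sigma_a2`, `sigma_pe2`, `sigma_e2`).
#' @export
assign_qtl_effects <- function(geno, config, rng_seed = config$seed + 2L,
                               sigma_a2 = 1) {
  with_seed(rng_seed, {
    d <- dosage(geno)
    poly <- which(matrixStats_colVars(d) > 0)
    if (length(poly) < config$n_qtl) {
      abort("not enough polymorphic SNPs to place the requested QTL")
    }
    qtl <- sort(sample(poly, config$n_qtl))
    eff <- rnorm(config$n_qtl)
    tbv <- drop(d[, qtl, drop = FALSE] %*% eff)
    v <- var(tbv)
    if (v <= 0) abort("degenerate QTL draw: zero additive variance")
    scale <- sqrt(sigma_a2 / v)
    eff <- eff * scale
    tbv <- tbv * scale
    if (config$h2 == 0) {
      abort("h2 = 0 leaves phenotype variances undefined; use h2 > 0")
    }
    sigma_pe2 <- sigma_a2 * (config$repeatability - config$h2) / config$h2
    sigma_e2 <- sigma_a2 * (1 - config$repeatability) / config$h2
    structure(
      list(qtl_snp_ids = geno$map$snp_id[qtl], qtl_indices = qtl,
           qtl_effects = eff,
           true_breeding_values = setNames(tbv, geno$samples),
           variance_components_true = c(sigma_a2 = sigma_a2,
                                        sigma_pe2 = sigma_pe2,
                                        sigma_e2 = sigma_e2)),
      class = "sim_truth")
  })
}

# Column variances of a plain matrix without an extra dependency.
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Simulate repeated phenotype records
#'
#' Every animal in `pop` is treated as a sow with `n_parities` records
#' `y = hys + a + pe + e`: `a` is the animal's true breeding value from the
#' QTL architecture, `pe ~ N(0, sigma_pe2)` is drawn once per animal,
#' `e ~ N(0, sigma_e2)` independently per record, and the herd-year-season
#' class of each record is drawn uniformly from `n_hys_levels` classes whose
#' effects are `N(0, hys_sd^2)`.
#'
#' @param pop [phased_genotypes()] of the animals to phenotype.
#' @param truth A `sim_truth` from [assign_qtl_effects()] covering `pop`'s
#'   samples.
#' @param config A [sim_config()].
#' @param rng_seed Integer seed; defaults to `config$seed + 3`.
#' @return A tibble with columns `animal`, `parity`, `hys`, `value`.
#' @export
simulate_phenotype_records <- function(pop, truth, config,
                                       rng_seed = config$seed + 3L) {
  if (!inherits(truth, "sim_truth")) abort("`truth` must come from assign_qtl_effects()")
  if (config$repeatability < config$h2) {
    stop_config("repeatability", "must be >= h2")
  }
  tbv <- truth$true_breeding_values[pop$samples]
  if (anyNA(tbv)) abort("`truth` lacks breeding values for some animals in `pop`")
  vc <- truth$variance_components_true
  with_seed(rng_seed, {
    n <- length(pop$samples)
    hys_eff <- rnorm(config$n_hys_levels, 0, config$hys_sd)
    pe <- rnorm(n, 0, sqrt(vc[["sigma_pe2"]]))
    recs <- tidyr::expand_grid(animal = pop$samples,
                               parity = seq_len(config$n_parities))
    k <- nrow(recs)
    hys_i <- sample.int(config$n_hys_levels, k, replace = TRUE)
    ai <- match(recs$animal, pop$samples)
    recs$hys <- sprintf("hys%02d", hys_i)
    recs$value <- as.numeric(hys_eff[hys_i] + tbv[ai] + pe[ai] +
                               rnorm(k, 0, sqrt(vc[["sigma_e2"]])))
    recs
  })
}
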