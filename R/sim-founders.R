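#' Simulate founder haplotypes
#'
#' Draws `2 * n_founders` haplotypes at `n_snps` biallelic loci. Per-locus
#' alternate-allele frequencies come from the configured spectrum
#' (`"ushaped"` Beta(0.5, 0.5) clipped to `[0.02, 0.98]`, or `"uniform"` on
#' `[0.05, 0.95]`). Loci are placed uniformly at random on a genetic map of
#' `chrom_length_morgans` per chromosome; physical positions assume 1 cM per
#' Mb. With `founder_ld_cm > 0` each haplotype is a first-order Markov chain
#' along the chromosome whose allele correlation between loci `d` cM apart
#' is `exp(-d / founder_ld_cm)`, emulating the LD of a finite ancestral
#' population; both descendant populations inherit this shared LD.
#'
#' @param config A [sim_config()].
#' @param rng_seed Integer seed; defaults to `config$seed`.
#' @return A [phased_genotypes()] object for the founder pool.
#' @export
generate_founder_haplotypes <- function(config, rng_seed = config$seed) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  with_seed(rng_seed, {
    m <- config$n_snps
    n <- config$n_founders
    nchr <- config$n_chromosomes
    per_chr <- rep(m %/% nchr, nchr)
    extra <- m %% nchr
    if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
    map <- purrr::map_dfr(seq_len(nchr), function(c_i) {
      mc <- per_chr[c_i]
      pos_m <- sort(runif(mc, 0, max(config$chrom_length_morgans, 1e-9)))
      # strictly increasing physical positions at 1 cM/Mb
      bp <- as.integer(round(pos_m * 1e8)) + 1L
      bp <- bp + cumsum(c(0L, as.integer(diff(bp) <= 0)))
      while (any(diff(bp) <= 0)) bp <- bp + cumsum(c(0L, as.integer(diff(bp) <= 0)))
      tibble(snp_id = sprintf("snp_%d_%04d", c_i, seq_len(mc)),
             chrom = paste0("chr", c_i), pos = bp,
             ref = "A", alt = "B", pos_cm = pos_m * 100)
    })
    p <- switch(config$maf_spectrum,
                ushaped = pmin(pmax(rbeta(m, 0.5, 0.5), 0.02), 0.98),
                uniform = runif(m, 0.05, 0.95))
    nh <- 2L * n
    haps <- matrix(0L, nh, m)
    lam <- config$founder_ld_cm
    for (c_i in seq_len(nchr)) {
      idx <- which(map$chrom == paste0("chr", c_i))
      haps[, idx[1]] <- rbinom(nh, 1L, p[idx[1]])
      if (length(idx) > 1L) for (t in seq_len(length(idx) - 1L)) {
        j0 <- idx[t]; j1 <- idx[t + 1L]
        rho <- if (lam > 0) exp(-(map$pos_cm[j1] - map$pos_cm[j0]) / lam) else 0
        cond <- p[j1] + rho * (haps[, j0] - p[j0]) *
          sqrt(p[j1] * (1 - p[j1]) / (p[j0] * (1 - p[j0])))
        haps[, j1] <- rbinom(nh, 1L, pmin(pmax(cond, 0), 1))
      }
    }
    phased_genotypes(haps, sprintf("FND_%04d", seq_len(n)), map)
  })
}
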