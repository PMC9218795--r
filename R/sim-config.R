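#' Simulation configuration
#'
#' Defines the study conditions for the two-population forward simulation:
#' a common founder pool splits into two closed populations of one breed that
#' then drift apart for `generations_split` discrete generations under random
#' mating and Haldane recombination. The defaults describe the package's
#' reference desk-scale dataset: two populations whose between-population
#' correlation of signed LD (r) lands near 0.5, similar minor-allele-frequency
#' spectra, an additive polygenic architecture, and repeated litter-size-like
#' records with a herd-year-season fixed effect.
#'
#' @param n_founders Number of founder animals in the common pool.
#' @param n_pop1,n_pop2 Breeding cohort size per generation of each
#'   population; the genotyped set returned by the simulator spans the last
#'   two cohorts (parents + final generation), so each population contributes
#'   `2 * n_popk` genotyped animals and the final generation has `n_popk`.
#' @param n_snps Total biallelic SNPs across the genome.
#' @param n_chromosomes Number of chromosomes; SNPs are split as evenly as
#'   possible between them.
#' @param chrom_length_morgans Genetic length of each chromosome (Morgans).
#' @param generations_split Number of drift generations after the split.
#' @param n_qtl Number of causal loci drawn from the SNP panel.
#' @param h2 Narrow-sense heritability of single records, in `[0, 1]`.
#' @param repeatability Intra-class correlation of repeated records,
#'   `h2 <= repeatability <= 1`.
#' @param n_parities Records per phenotyped animal.
#' @param n_hys_levels Number of herd-year-season classes.
#' @param hys_sd Standard deviation of herd-year-season class effects
#'   (trait units).
#' @param maf_spectrum Founder allele-frequency spectrum: `"ushaped"`
#'   (Beta(0.5, 0.5), most mass near the extremes, as after a bottleneck) or
#'   `"uniform"`.
#' @param founder_ld_cm Scale (cM) of the exponential decay of ancestral LD
#'   among founder haplotypes; adjacent loci `d` cM apart have haplotype
#'   allele correlation `exp(-d / founder_ld_cm)`. `0` gives linkage
#'   equilibrium founders. This ancestral LD is what the two descendant
#'   populations share and then lose consistency in as they drift apart.
#' @param seed Integer seed making the whole dataset reproducible.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200, n_pop1 = 100, n_pop2 = 100,
                       n_snps = 1000, n_chromosomes = 5,
                       chrom_length_morgans = 1, generations_split = 10,
                       n_qtl = 50, h2 = 0.3, repeatability = 0.5,
                       n_parities = 3, n_hys_levels = 5, hys_sd = 0.5,
                       maf_spectrum = c("ushaped", "uniform"),
                       founder_ld_cm = 3, seed = 1L) {
  maf_spectrum <- match.arg(maf_spectrum)
  if (!is.numeric(founder_ld_cm) || founder_ld_cm < 0) {
    stop_config("founder_ld_cm", "must be >= 0")
  }
  check_count(n_founders, "n_founders", 2)
  check_count(n_pop1, "n_pop1")
  check_count(n_pop2, "n_pop2")
  check_count(n_snps, "n_snps")
  check_count(n_chromosomes, "n_chromosomes")
  check_count(generations_split, "generations_split", 0)
  check_count(n_qtl, "n_qtl")
  check_count(n_parities, "n_parities")
  check_count(n_hys_levels, "n_hys_levels")
  check_prob(h2, "h2")
  check_prob(repeatability, "repeatability")
  if (repeatability < h2) stop_config("repeatability", "must be >= h2")
  if (!is.numeric(chrom_length_morgans) || chrom_length_morgans < 0) {
    stop_config("chrom_length_morgans", "must be a nonnegative number")
  }
  if (!is.numeric(hys_sd) || hys_sd < 0) stop_config("hys_sd", "must be >= 0")
  if (n_qtl > n_snps) stop_config("n_qtl", "cannot exceed n_snps")
  structure(
    list(n_founders = as.integer(n_founders), n_pop1 = as.integer(n_pop1),
         n_pop2 = as.integer(n_pop2), n_snps = as.integer(n_snps),
         n_chromosomes = as.integer(n_chromosomes),
         chrom_length_morgans = as.numeric(chrom_length_morgans),
         generations_split = as.integer(generations_split),
         n_qtl = as.integer(n_qtl), h2 = as.numeric(h2),
         repeatability = as.numeric(repeatability),
         n_parities = as.integer(n_parities),
         n_hys_levels = as.integer(n_hys_levels), hys_sd = as.numeric(hys_sd),
         maf_spectrum = maf_spectrum,
         founder_ld_cm = as.numeric(founder_ld_cm), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
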