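test_that("founder simulation is deterministic and builds a valid map", {
  cfg <- sim_config(n_founders = 4, n_snps = 10, n_chromosomes = 2,
                    n_qtl = 2, seed = 11)
  f1 <- generate_founder_haplotypes(cfg)
  f2 <- generate_founder_haplotypes(cfg)
  expect_identical(f1$haplotypes, f2$haplotypes)
  expect_identical(f1$map, f2$map)
  expect_equal(as.integer(table(f1$map$chrom)), c(5L, 5L))
  for (cc in unique(f1$map$chrom)) {
    expect_true(all(diff(f1$map$pos[f1$map$chrom == cc]) > 0))
  }
})

test_that("whole simulated datasets are reproducible from the seed", {
  cfg <- sim_config(n_founders = 40, n_pop1 = 10, n_pop2 = 10, n_snps = 60,
                    generations_split = 3, n_qtl = 5, seed = 5)
  d1 <- sim_dataset(cfg)
  d2 <- sim_dataset(cfg)
  expect_identical(d1$merged$haplotypes, d2$merged$haplotypes)
  expect_identical(d1$pedigree, d2$pedigree)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth$qtl_effects, d2$truth$qtl_effects)
})

test_that("U-shaped spectrum yields many low-MAF loci", {
  frac <- sapply(1:3, function(s) {
    f <- generate_founder_haplotypes(
      sim_config(n_founders = 200, n_snps = 2000, seed = s))
    p <- colMeans(dosage(f)) / 2
    mean(pmin(p, 1 - p) < 0.2)
  })
  expect_gt(mean(frac), 0.40)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(h2 = 0.6, repeatability = 0.4), "repeatability")
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(hys_sd = -1), "hys_sd")
})

test_that("zero drift generations subsamples founders disjointly", {
  cfg <- sim_config(n_founders = 30, n_pop1 = 10, n_pop2 = 10, n_snps = 40,
                    n_qtl = 5, generations_split = 0, seed = 2)
  f <- generate_founder_haplotypes(cfg)
  ev <- evolve_split_populations(f, cfg)
  expect_length(intersect(ev$pop1$samples, ev$pop2$samples), 0)
  fd <- dosage(f)
  expect_identical(dosage(ev$pop1), fd[ev$pop1$samples, , drop = FALSE])
  expect_identical(dosage(ev$pop2), fd[ev$pop2$samples, , drop = FALSE])

  cfg_bad <- sim_config(n_founders = 10, n_pop1 = 8, n_pop2 = 8, n_snps = 40,
                        n_qtl = 5, generations_split = 0)
  f_bad <- generate_founder_haplotypes(cfg_bad)
  expect_error(evolve_split_populations(f_bad, cfg_bad),
               class = "hapblup_sampling_error")
})

test_that("zero map length transmits unrecombined parental haplotypes", {
  cfg <- sim_config(n_founders = 20, n_pop1 = 8, n_pop2 = 8, n_snps = 30,
                    n_qtl = 5, n_chromosomes = 2, chrom_length_morgans = 0,
                    generations_split = 2, seed = 3)
  f <- generate_founder_haplotypes(cfg)
  ev <- evolve_split_populations(f, cfg)
  all_hap <- rbind(f$haplotypes, ev$pop1$haplotypes, ev$pop2$haplotypes)
  ped <- ev$pedigree
  for (geno in list(ev$pop1, ev$pop2)) {
    for (i in seq_along(geno$samples)) {
      row <- ped[ped$animal == geno$samples[i], ]
      for (hp in 1:2) {
        parent <- if (hp == 1) row$sire else row$dam
        off <- geno$haplotypes[2 * i - 2 + hp, ]
        # parent haplotypes: find them in whichever container holds them
        ppos <- regmatches(rownames(all_hap), regexpr("^[^.]+", rownames(all_hap)))
        ph <- all_hap[ppos == parent, , drop = FALSE]
        for (cc in unique(geno$map$chrom)) {
          idx <- geno$map$chrom == cc
          expect_true(identical(off[idx], ph[1, idx]) ||
                        identical(off[idx], ph[2, idx]))
        }
      }
    }
  }
})

test_that("offspring haplotypes are Mendelian mosaics of parental alleles", {
  cfg <- sim_config(n_founders = 30, n_pop1 = 10, n_pop2 = 10, n_snps = 50,
                    n_qtl = 5, generations_split = 2, seed = 4)
  f <- generate_founder_haplotypes(cfg)
  ev <- evolve_split_populations(f, cfg)
  all_hap <- rbind(f$haplotypes, ev$pop1$haplotypes, ev$pop2$haplotypes)
  ppos <- regmatches(rownames(all_hap), regexpr("^[^.]+", rownames(all_hap)))
  for (geno in list(ev$pop1, ev$pop2)) {
    ped <- ev$pedigree[match(geno$samples, ev$pedigree$animal), ]
    for (i in seq_along(geno$samples)) {
      for (hp in 1:2) {
        parent <- if (hp == 1) ped$sire[i] else ped$dam[i]
        ph <- all_hap[ppos == parent, , drop = FALSE]
        if (nrow(ph) == 0) next  # parent not genotyped (intermediate cohort)
        off <- geno$haplotypes[2 * i - 2 + hp, ]
        expect_true(all(off == ph[1, ] | off == ph[2, ]))
      }
    }
  }
})

test_that("QTL truth hits the target additive variance and rates", {
  cfg <- sim_config(seed = 9, n_founders = 60, n_pop1 = 30, n_pop2 = 30,
                    n_snps = 200, generations_split = 2, n_qtl = 20,
                    h2 = 0.4, repeatability = 0.6)
  ds <- sim_dataset(cfg)
  expect_equal(var(ds$truth$true_breeding_values), 1.0, tolerance = 1e-10)
  vc <- ds$truth$variance_components_true
  expect_equal(unname(vc["sigma_pe2"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(vc["sigma_e2"]), 1.0, tolerance = 1e-12)
})

test_that("phenotype records have the right structure and noise-free limit", {
  cfg <- sim_config(n_founders = 40, n_snps = 100, n_qtl = 10, h2 = 1,
                    repeatability = 1, hys_sd = 0, n_parities = 3, seed = 6)
  f <- generate_founder_haplotypes(cfg)
  truth <- assign_qtl_effects(f, cfg)
  rec <- simulate_phenotype_records(f, truth, cfg)
  expect_equal(nrow(rec), 40 * 3)
  expect_true(all(table(rec$animal) == 3))
  dev <- rec$value - truth$true_breeding_values[rec$animal]
  expect_lt(max(abs(dev - dev[1])), 1e-12)
})

test_that("repeated records reproduce the configured repeatability", {
  icc <- sapply(1:3, function(s) {
    cfg <- sim_config(n_founders = 500, n_snps = 150, n_qtl = 30, h2 = 0.3,
                      repeatability = 0.5, hys_sd = 0, n_parities = 3,
                      seed = s + 20)
    f <- generate_founder_haplotypes(cfg)
    truth <- assign_qtl_effects(f, cfg)
    rec <- simulate_phenotype_records(f, truth, cfg)
    k <- 3
    means <- tapply(rec$value, rec$animal, mean)
    msb <- k * var(means)
    msw <- sum(tapply(rec$value, rec$animal, function(v) sum((v - mean(v))^2))) /
      (length(means) * (k - 1))
    (msb - msw) / (msb + (k - 1) * msw)
  })
  expect_equal(mean(icc), 0.5, tolerance = 0.05)
})

test_that("more drift generations lower LD-phase consistency", {
  phase_at <- function(gs, s) {
    cfg <- sim_config(n_founders = 120, n_pop1 = 60, n_pop2 = 60,
                      n_snps = 400, n_chromosomes = 2,
                      generations_split = gs, seed = s)
    ds <- sim_dataset(cfg)
    q <- apply_variant_qc(ds$merged)$genotypes
    ids <- match(q$map$snp_id, ds$pop1$map$snp_id)
    ld_phase_correlation(subset_markers(ds$pop1, ids),
                         subset_markers(ds$pop2, ids))
  }
  lo <- mean(sapply(1:2, function(s) phase_at(4, s)))
  hi <- mean(sapply(1:2, function(s) phase_at(25, s)))
  expect_lt(hi, lo)
})

test_that("emitted files round-trip losslessly", {
  cfg <- sim_config(n_founders = 30, n_pop1 = 8, n_pop2 = 8, n_snps = 40,
                    generations_split = 2, n_qtl = 5, seed = 8)
  ds <- sim_dataset(cfg)
  out <- withr::local_tempdir()
  paths <- emit_dataset(ds$pop1, ds$pop2, ds$pedigree, ds$records, out,
                        truth = ds$truth)
  back <- read_phased_vcf(paths[["merged"]])
  expect_identical(dosage(back), dosage(ds$merged))
  expect_identical(back$haplotypes, ds$merged$haplotypes)

  ped <- read_pedigree_csv(paths[["pedigree"]])
  founders <- ped[ped$animal %in% ds$pedigree$animal[ds$pedigree$generation == 0], ]
  expect_true(all(founders$sire == "0" & founders$dam == "0"))
  expect_true(!is.unsorted(ped$birthdate))

  rec <- read_phenotypes_csv(paths[["phenotypes"]])
  expect_equal(rec$value, ds$records$value)

  tr <- read_truth(paths[["truth"]])
  expect_equal(tr$variance_components_true,
               ds$truth$variance_components_true)
  expect_equal(tr$qtl_effects, ds$truth$qtl_effects)
})
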