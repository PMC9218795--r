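# Forward-in-time breeding of two populations split from a common founder
# pool. Non-overlapping generations, random mating, Haldane recombination
# (Poisson crossover count with mean equal to the map length in Morgans).

# One gamete from a parent's two haplotypes. chr_index: list of column index
# vectors per chromosome; pos_cm: list of genetic positions per chromosome;
# len_m: chromosome length in Morgans.
.make_gamete <- function(h1, h2, chr_index, pos_cm, len_m) {
  g <- integer(length(h1))
  for (c_i in seq_along(chr_index)) {
    idx <- chr_index[[c_i]]
    k <- rpois(1L, len_m)
    start <- sample.int(2L, 1L)
    if (k == 0L) {
      g[idx] <- if (start == 1L) h1[idx] else h2[idx]
    } else {
      xo <- sort(runif(k, 0, len_m * 100))
      src <- (start + findInterval(pos_cm[[c_i]], xo)) %% 2L
      g[idx] <- ifelse(src == 1L, h1[idx], h2[idx])
    }
  }
  g
}

#' Breed two diverging populations from a common founder pool
#'
#' Splits the founders into two disjoint pools and breeds each pool
#' independently for `generations_split` non-overlapping generations under
#' random mating (sires drawn from the previous cohort's males, dams from its
#' females) with Haldane-model recombination. Drift with no migration makes
#' the two populations' LD phase diverge while their allele-frequency spectra
#' stay similar — the regime haplotype-based prediction across populations
#' has to cope with.
#'
#' The returned genotyped set of each population spans its last two cohorts
#' (the final generation plus its parent cohort) so that a forward split by
#' birthdate has both reference and validation animals. Haplotype 1 of every
#' non-founder is the gamete received from the sire, haplotype 2 from the dam.
#'
#' @param founders Founder [phased_genotypes()] from
#'   [generate_founder_haplotypes()].
#' @param config A [sim_config()].
#' @param rng_seed Integer seed; defaults to `config$seed + 1`.
#' @return A list with elements `pop1`, `pop2` ([phased_genotypes()] of the
#'   genotyped cohorts, population labels set) and `pedigree` (tibble with
#'   columns `animal`, `sire`, `dam`, `sex`, `population`, `generation`,
#'   `birthdate`; unknown parents are `"0"`).
#' @export
evolve_split_populations <- function(founders, config,
                                     rng_seed = config$seed + 1L) {
  if (!inherits(founders, "phased_genotypes")) {
    abort("`founders` must be a phased_genotypes object")
  }
  with_seed(rng_seed, {
    nf <- length(founders$samples)
    base_date <- as.Date("2000-01-01")
    chroms <- unique(founders$map$chrom)
    chr_index <- lapply(chroms, function(cc) which(founders$map$chrom == cc))
    pos_cm <- lapply(chr_index, function(idx) founders$map$pos_cm[idx])
    if (is.null(founders$map$pos_cm)) {
      abort("founder map must carry genetic positions (pos_cm)")
    }
    ped <- tibble(animal = founders$samples, sire = "0", dam = "0",
                  sex = sample(c("M", "F"), nf, replace = TRUE),
                  population = "founders", generation = 0L,
                  birthdate = base_date)

    if (config$generations_split == 0L) {
      need <- config$n_pop1 + config$n_pop2
      if (need > nf) {
        abort(sprintf(paste0("cannot subsample %d + %d animals from %d founders ",
                             "with generations_split = 0"),
                      config$n_pop1, config$n_pop2, nf),
              class = "hapblup_sampling_error")
      }
      pick <- sample.int(nf, need)
      g1 <- subset_samples(founders, founders$samples[pick[seq_len(config$n_pop1)]])
      g2 <- subset_samples(founders,
                           founders$samples[pick[config$n_pop1 + seq_len(config$n_pop2)]])
      g1$population <- rep("pop1", config$n_pop1)
      g2$population <- rep("pop2", config$n_pop2)
      ped$population[pick[seq_len(config$n_pop1)]] <- "pop1"
      ped$population[pick[config$n_pop1 + seq_len(config$n_pop2)]] <- "pop2"
      return(list(pop1 = g1, pop2 = g2, pedigree = ped))
    }

    pool <- sample.int(nf)
    pools <- list(pool[seq_len(nf %/% 2)], pool[(nf %/% 2 + 1L):nf])
    breed_pop <- function(pop_idx) {
      tag <- paste0("pop", pop_idx)
      size <- if (pop_idx == 1L) config$n_pop1 else config$n_pop2
      cur_ids <- founders$samples[pools[[pop_idx]]]
      cur_hap <- founders$haplotypes[
        as.vector(rbind(2L * pools[[pop_idx]] - 1L, 2L * pools[[pop_idx]])), ,
        drop = FALSE]
      cur_sex <- ped$sex[match(cur_ids, ped$animal)]
      ped_rows <- list()
      keep <- list()
      for (g in seq_len(config$generations_split)) {
        males <- which(cur_sex == "M"); females <- which(cur_sex == "F")
        if (length(males) == 0L || length(females) == 0L) {
          # guarantee both sexes in tiny cohorts
          flip <- sample.int(length(cur_sex), 1L)
          cur_sex[flip] <- if (length(males) == 0L) "M" else "F"
          males <- which(cur_sex == "M"); females <- which(cur_sex == "F")
        }
        sires <- sample(males, size, replace = TRUE)
        dams <- sample(females, size, replace = TRUE)
        new_hap <- matrix(0L, 2L * size, ncol(cur_hap))
        for (i in seq_len(size)) {
          new_hap[2L * i - 1L, ] <- .make_gamete(
            cur_hap[2L * sires[i] - 1L, ], cur_hap[2L * sires[i], ],
            chr_index, pos_cm, config$chrom_length_morgans)
          new_hap[2L * i, ] <- .make_gamete(
            cur_hap[2L * dams[i] - 1L, ], cur_hap[2L * dams[i], ],
            chr_index, pos_cm, config$chrom_length_morgans)
        }
        new_ids <- sprintf("P%d_G%02d_%04d", pop_idx, g, seq_len(size))
        new_sex <- sample(c("M", "F"), size, replace = TRUE)
        ped_rows[[g]] <- tibble(
          animal = new_ids, sire = cur_ids[sires], dam = cur_ids[dams],
          sex = new_sex, population = tag, generation = g,
          birthdate = base_date + 365L * g)
        if (g >= config$generations_split - 1L) {
          keep[[length(keep) + 1L]] <- list(ids = new_ids, hap = new_hap)
        }
        cur_ids <- new_ids; cur_hap <- new_hap; cur_sex <- new_sex
      }
      ids <- unlist(lapply(keep, `[[`, "ids"))
      hap <- do.call(rbind, lapply(keep, `[[`, "hap"))
      geno <- phased_genotypes(hap, ids, founders$map,
                               population = rep(tag, length(ids)))
      list(geno = geno, ped = bind_rows(ped_rows))
    }
    p1 <- breed_pop(1L)
    p2 <- breed_pop(2L)
    list(pop1 = p1$geno, pop2 = p2$geno,
         pedigree = bind_rows(ped, p1$ped, p2$ped))
  })
}
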