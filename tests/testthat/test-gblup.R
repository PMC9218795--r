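# Shared fixture: founder panel with QTL phenotypes and a reference /
# validation split by sample order.
gblup_fixture <- function(n = 120, m = 200, n_ref = 80, h2 = 0.4, seed = 81) {
  cfg <- sim_config(n_founders = n, n_snps = m, n_qtl = 30, h2 = h2,
                    repeatability = h2, n_parities = 1, seed = seed)
  g <- generate_founder_haplotypes(cfg)
  g <- apply_variant_qc(g)$genotypes
  truth <- assign_qtl_effects(g, cfg)
  set.seed(seed + 1)
  sig_e <- sqrt(1 / h2 - 1)
  y <- truth$true_breeding_values + rnorm(length(g$samples), 0, sig_e)
  ref <- g$samples[seq_len(n_ref)]
  list(geno = g, truth = truth,
       y_c = tibble::tibble(animal = names(y), y_c = unname(y)),
       ref = ref, val = setdiff(g$samples, ref))
}

test_that("GBLUP equals ridge-regression SNP-BLUP at fixed variance ratios", {
  fx <- gblup_fixture(n = 100, m = 300, n_ref = 70, seed = 82)
  dm <- snp_dosage_matrix(fx$geno)
  G <- compute_grm(dm)
  s_g <- 0.8; s_e <- 1.2
  fit <- reml_fit(fx$y_c[match(fx$ref, fx$y_c$animal), ], list(g = G),
                  varcomp = c(s_g, s_e), ridge = 0)
  # marker-effect oracle: joint unpenalized-intercept + penalized-marker solve
  M <- sweep(dm$mat, 2, 2 * dm$freq)
  Mr <- M[fx$ref, , drop = FALSE]
  y <- fx$y_c$y_c[match(fx$ref, fx$y_c$animal)]
  lambda <- s_e / (s_g / G$divisor)
  m <- ncol(Mr)
  lhs <- rbind(cbind(length(y), t(colSums(Mr))),
               cbind(colSums(Mr), crossprod(Mr) + diag(lambda, m)))
  sol <- solve(lhs, c(sum(y), crossprod(Mr, y)))
  gebv_oracle <- drop(M %*% sol[-1])
  got <- fit$gebv$gebv[match(rownames(M), fit$gebv$animal)]
  expect_lt(max(abs(got - gebv_oracle)), 1e-6)
  expect_equal(fit$mu, sol[1], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("REML recovers simulated genomic variance components", {
  fx <- gblup_fixture(n = 300, m = 400, seed = 83)
  G <- compute_grm(snp_dosage_matrix(fx$geno))
  # simulate y directly from the GBLUP covariance structure
  set.seed(84)
  L <- chol(G$mat + diag(1e-6, nrow(G$mat)))
  gv <- drop(crossprod(L, rnorm(nrow(G$mat))))
  y <- tibble::tibble(animal = fx$geno$samples,
                      y_c = 2 + gv + rnorm(length(gv), 0, 1))
  fit <- reml_fit(y, list(g = G))
  expect_true(fit$converged)
  expect_equal(unname(fit$variance_components["sigma2_g"]), 1, tolerance = 0.3)
  expect_equal(unname(fit$variance_components["sigma2_e"]), 1, tolerance = 0.3)
})

test_that("pure-noise phenotypes drive the genomic variance to zero", {
  fx <- gblup_fixture(n = 150, m = 150, seed = 85)
  G <- compute_grm(snp_dosage_matrix(fx$geno))
  ratios <- sapply(1:3, function(s) {
    set.seed(90 + s)
    y <- tibble::tibble(animal = fx$geno$samples,
                        y_c = rnorm(length(fx$geno$samples)))
    fit <- reml_fit(y, list(g = G))
    unname(fit$variance_components["sigma2_g"] /
             sum(fit$variance_components))
  })
  expect_lt(mean(ratios), 0.1)
})

test_that("a zeroed second component reproduces the one-component fit", {
  fx <- gblup_fixture(n = 100, m = 200, seed = 86)
  part <- build_blocks(fx$geno, 0.3)
  GH <- compute_grm(recode_haplotype_dosages(fx$geno, part,
                                             include_singletons = FALSE))
  Gnb <- compute_grm(snp_dosage_matrix(fx$geno, part$nonblocked))
  yref <- fx$y_c[match(fx$ref, fx$y_c$animal), ]
  f1 <- reml_fit(yref, list(block = GH), varcomp = c(0.7, 1.1))
  f2 <- reml_fit(yref, list(block = GH, nonblock = Gnb),
                 varcomp = c(0.7, 0, 1.1))
  expect_equal(f1$loglik_restricted, f2$loglik_restricted, tolerance = 1e-6)
  expect_lt(max(abs(f1$gebv$gebv - f2$gebv$gebv)), 1e-6)
})

test_that("GEBV of unphenotyped animals are invariant to phenotype shifts", {
  fx <- gblup_fixture(n = 80, m = 120, seed = 87)
  G <- compute_grm(snp_dosage_matrix(fx$geno))
  yref <- fx$y_c[match(fx$ref, fx$y_c$animal), ]
  f1 <- reml_fit(yref, list(g = G), varcomp = c(0.6, 1.0))
  yshift <- yref; yshift$y_c <- yshift$y_c + 100
  f2 <- reml_fit(yshift, list(g = G), varcomp = c(0.6, 1.0))
  expect_lt(max(abs(f1$gebv$gebv - f2$gebv$gebv)), 1e-8)
  expect_equal(f2$mu - f1$mu, 100, tolerance = 1e-8)
})

test_that("run_model degenerates gracefully when no blocks form", {
  fx <- gblup_fixture(n = 90, m = 60, seed = 88)
  d <- dosage(fx$geno)
  r2max <- 0
  for (cc in unique(fx$geno$map$chrom)) {
    idx <- which(fx$geno$map$chrom == cc)
    if (length(idx) < 2) next
    r2max <- max(r2max, max(cor(d[, idx])[upper.tri(diag(length(idx)))]^2))
  }
  t_hi <- min(1, r2max + (1 - r2max) / 2)
  part <- build_blocks(fx$geno, t_hi)
  expect_equal(nrow(part$blocks), 0L)
  yref <- fx$y_c[match(fx$ref, fx$y_c$animal), ]
  f_g <- run_model("GBLUP", fx$geno, NULL, yref)
  expect_warning(f_d <- run_model("GH_plus_GBLUP", fx$geno, part, yref),
                 "degenerates")
  expect_equal(f_d$model, "GBLUP")
  expect_equal(f_d$loglik_restricted, f_g$loglik_restricted, tolerance = 1e-6)
  expect_lt(max(abs(f_d$gebv$gebv - f_g$gebv$gebv)), 1e-6)
})

test_that("GHBLUP on all-singleton partitions equals GBLUP", {
  fx <- gblup_fixture(n = 100, m = 80, seed = 89)
  yref <- fx$y_c[match(fx$ref, fx$y_c$animal), ]
  part <- hapblup:::singleton_partition(fx$geno)
  part$blocks <- part$blocks[0, ]  # no blocks; all SNPs singleton
  f_g <- run_model("GBLUP", fx$geno, NULL, yref, ridge = 0)
  GH <- compute_grm(recode_haplotype_dosages(fx$geno, part,
                                             include_singletons = TRUE))
  f_h <- reml_fit(yref, list(g = GH), model = "GHBLUP", ridge = 0)
  expect_equal(f_h$loglik_restricted, f_g$loglik_restricted, tolerance = 1e-8)
  expect_lt(max(abs(f_h$gebv$gebv - f_g$gebv$gebv)), 1e-8)
  expect_equal(f_h$variance_components, f_g$variance_components,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("haplotype models with blocky LD fit at least as well as GBLUP", {
  lls <- sapply(1:3, function(s) {
    cfg <- sim_config(n_founders = 120, n_pop1 = 60, n_pop2 = 60,
                      n_snps = 240, n_chromosomes = 2, generations_split = 4,
                      n_qtl = 30, seed = 100 + s)
    ds <- sim_dataset(cfg)
    g <- apply_variant_qc(ds$merged)$genotypes
    yc <- tibble::tibble(animal = g$samples,
                         y_c = ds$truth$true_breeding_values[g$samples] +
                           rnorm(length(g$samples), 0, 1.2))
    ref <- g$samples[seq_len(160)]
    part <- build_blocks(g, 0.3)
    f_g <- run_model("GBLUP", g, NULL, yc, reference = ref)
    f_2 <- suppressWarnings(
      run_model("GH_plus_GBLUP", g, part, yc, reference = ref))
    f_2$loglik_restricted - f_g$loglik_restricted
  })
  expect_gt(mean(lls), -0.5)
})

test_that("gblup tidiers expose variance components and fit summary", {
  fx <- gblup_fixture(n = 60, m = 60, seed = 101)
  G <- compute_grm(snp_dosage_matrix(fx$geno))
  fit <- reml_fit(fx$y_c, list(g = G), varcomp = c(0.5, 1))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("sigma2_g", "sigma2_e"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_reference, 60L)
  expect_true(is.finite(gl$loglik_restricted))
})
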