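#' REML fit of genomic mixed models with one or two relationship matrices
#'
#' Fits `y = 1u + Z g_1 [+ Z g_2] + e` by average-information REML, where
#' each genomic effect has covariance `sigma_i^2 * G_i` over *all* genotyped
#' animals and the shared incidence `Z` selects the phenotyped (reference)
#' rows. Validation animals carry no phenotype but appear in the
#' relationship matrices, so their genomic breeding values are predicted
#' through the genomic covariances (`gebv_i = sigma_i^2 G_i Z' P y`). The
#' only fixed effect is the overall mean.
#'
#' @param y_c Corrected phenotypes of the reference animals: a tibble with
#'   columns `animal`, `y_c`, or a named numeric vector.
#' @param grms A `grm` or named list of `grm`s sharing one sample set.
#' @param varcomp Optional fixed variance components (one per genomic term
#'   plus residual, in that order): skip REML iterations and solve BLUP at
#'   these values.
#' @param ridge Diagonal inflation added to each relationship matrix as a
#'   fraction of its mean diagonal (haplotype matrices can be rank
#'   deficient).
#' @param model Label stored on the fit.
#' @param max_iter,ll_tol,par_tol REML iteration controls.
#' @return An object of class `gblup_fit`: `model`, `variance_components`
#'   (named, residual last), `mu`, `gebv` (tibble `animal`, `gebv`, one
#'   column per term for two-term fits), `loglik_restricted`, `converged`,
#'   `iterations`, `n_reference`.
#' @export
reml_fit <- function(y_c, grms, varcomp = NULL, ridge = 1e-8,
                     model = "custom", max_iter = 200L, ll_tol = 1e-8,
                     par_tol = 1e-6) {
  if (inherits(grms, "grm")) grms <- list(g = grms)
  if (is.null(names(grms)) || any(names(grms) == "")) {
    names(grms) <- paste0("g", seq_along(grms))
  }
  samples <- grms[[1]]$samples
  for (g in grms) {
    if (!identical(g$samples, samples)) {
      abort("all relationship matrices must be aligned to one sample order")
    }
  }
  if (is.data.frame(y_c)) y_c <- setNames(y_c$y_c, y_c$animal)
  ref <- names(y_c)
  if (is.null(ref)) abort("`y_c` must carry animal identifiers")
  idx <- match(ref, samples)
  if (anyNA(idx)) {
    abort(sprintf("phenotyped animals absent from the relationship matrix: %s",
                  paste(head(ref[is.na(idx)], 5), collapse = ", ")))
  }
  y <- as.numeric(y_c)
  n <- length(y)
  Ks <- lapply(grms, function(g) {
    g$mat + diag(ridge * mean(diag(g$mat)), nrow(g$mat))
  })
  Vlist <- lapply(Ks, function(K) K[idx, idx, drop = FALSE])
  X <- matrix(1, n, 1L)
  fit <- reml_engine(y, X, Vlist,
                     qlev = c(rep(length(samples), length(Ks)), n),
                     varcomp = varcomp, max_iter = max_iter,
                     ll_tol = ll_tol, par_tol = par_tol)
  theta <- fit$theta
  k <- length(Ks)
  gebv_terms <- lapply(seq_len(k), function(i) {
    theta[i] * drop(Ks[[i]][, idx, drop = FALSE] %*% fit$Py)
  })
  gebv <- tibble(animal = samples, gebv = Reduce(`+`, gebv_terms))
  if (k > 1L) {
    for (i in seq_len(k)) gebv[[paste0("gebv_", names(grms)[i])]] <- gebv_terms[[i]]
  }
  structure(list(
    model = model,
    variance_components = setNames(theta, c(paste0("sigma2_", names(grms)),
                                            "sigma2_e")),
    mu = unname(fit$beta), gebv = gebv,
    loglik_restricted = fit$loglik, converged = fit$converged,
    iterations = fit$iterations, n_reference = n,
    reference = ref), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> model %s, n_ref %d, converged %s (%d it)\n",
              x$model, x$n_reference, x$converged, x$iterations))
  vc <- paste(sprintf("%s = %.4g", names(x$variance_components),
                      x$variance_components), collapse = ", ")
  cat(" ", vc, "\n")
  invisible(x)
}

#' Run one of the three genomic prediction models
#'
#' Dispatches relationship-matrix construction and the REML fit:
#' * `GBLUP` — SNP relationship matrix on all SNPs;
#' * `GHBLUP` — haplotype relationship matrix from block haplotype alleles
#'   plus non-blocked SNPs as one-SNP haplotypes (all markers represented);
#' * `GH_plus_GBLUP` — two genomic terms: haplotype alleles of the blocks,
#'   and a SNP matrix on the non-blocked SNPs only.
#'
#' Only the reference animals' phenotypes enter the fit; breeding values are
#' returned for every genotyped animal. A partition with no blocks collapses
#' `GH_plus_GBLUP` (and `GHBLUP`) to GBLUP with a warning; a partition with
#' no singleton SNPs collapses `GH_plus_GBLUP` to the block-only haplotype
#' model with a warning.
#'
#' @param model_name `"GBLUP"`, `"GHBLUP"` or `"GH_plus_GBLUP"`.
#' @param geno QC'd [phased_genotypes()] of all genotyped animals.
#' @param part `haploblock_partition` (required for the haplotype models).
#' @param y_c Reference corrected phenotypes (tibble `animal`, `y_c` or
#'   named vector).
#' @param reference Optional character vector restricting which `y_c`
#'   animals are used as reference.
#' @param ... Passed to [reml_fit()].
#' @return A `gblup_fit`.
#' @export
run_model <- function(model_name = c("GBLUP", "GHBLUP", "GH_plus_GBLUP"),
                      geno, part = NULL, y_c, reference = NULL, ...) {
  model_name <- match.arg(model_name)
  if (is.data.frame(y_c)) y_c <- setNames(y_c$y_c, y_c$animal)
  if (!is.null(reference)) y_c <- y_c[names(y_c) %in% reference]
  if (model_name != "GBLUP") {
    if (is.null(part)) abort("haplotype models need a haploblock partition")
    if (nrow(part$blocks) == 0L) {
      warn(sprintf("no haploblocks at threshold %.3g: %s degenerates to GBLUP",
                   part$threshold, model_name))
      model_name <- "GBLUP"
    }
  }
  if (model_name == "GBLUP") {
    G <- compute_grm(snp_dosage_matrix(geno))
    return(reml_fit(y_c, list(g = G), model = "GBLUP", ...))
  }
  if (model_name == "GHBLUP") {
    GH <- compute_grm(recode_haplotype_dosages(geno, part,
                                               include_singletons = TRUE))
    return(reml_fit(y_c, list(g = GH), model = "GHBLUP", ...))
  }
  # GH_plus_GBLUP
  GH <- compute_grm(recode_haplotype_dosages(geno, part,
                                             include_singletons = FALSE))
  if (length(part$nonblocked) == 0L) {
    warn("no non-blocked SNPs: GH_plus_GBLUP reduces to the block-only haplotype model")
    return(reml_fit(y_c, list(block = GH), model = "GH_plus_GBLUP", ...))
  }
  Gnb <- compute_grm(snp_dosage_matrix(geno, part$nonblocked),
                     source = "nonblocked-snp")
  reml_fit(y_c, list(block = GH, nonblock = Gnb), model = "GH_plus_GBLUP", ...)
}
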