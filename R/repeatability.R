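#' Fit the single-trait repeatability animal model
#'
#' REML fit of `y = Xb + Za + Wpe + e` with herd-year-season as the fixed
#' effect, additive genetic effects `a ~ N(0, sigma_a2 * A)` (A the pedigree
#' numerator relationship matrix), permanent-environment effects
#' `pe ~ N(0, sigma_pe2 * I)` constant within animal, and residuals
#' `e ~ N(0, sigma_e2 * I)`. Variance components are estimated by
#' average-information REML with an EM fallback; BLUP solutions for `a`
#' (every pedigree animal) and `pe`, BLUE for the herd-year-season effects,
#' and EBV reliabilities `1 - PEV / sigma_a2` come from the converged fit.
#'
#' @param records Phenotype tibble with columns `animal`, `parity`, `hys`,
#'   `value`.
#' @param ped Pedigree tibble (`animal`, `sire`, `dam`, ...); every
#'   phenotyped animal must appear.
#' @param ancestor_depth How many ancestor generations to retain when
#'   pruning the pedigree around the phenotyped animals (default all).
#' @param max_iter,ll_tol,par_tol REML iteration controls.
#' @return An object of class `repeatability_fit` with elements
#'   `sigma_a2`, `sigma_pe2`, `sigma_e2`, `ebv` (tibble `animal`, `ebv`,
#'   `reliability`), `residuals` (per record), `fixed_effects` (tibble `hys`,
#'   `estimate`), `pe` (tibble `animal`, `pe`), `loglik`, `converged`,
#'   `iterations`, `degenerate`.
#' @export
fit_repeatability <- function(records, ped, ancestor_depth = Inf,
                              max_iter = 200L, ll_tol = 1e-8,
                              par_tol = 1e-6) {
  records <- as_tibble(records)
  if (!all(c("animal", "hys", "value") %in% names(records))) {
    abort("`records` needs columns animal, hys, value")
  }
  miss <- setdiff(unique(records$animal), ped$animal)
  if (length(miss) > 0) {
    abort(sprintf("phenotyped animals missing from pedigree: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  y <- records$value
  if (var(y) < 1e-12) {
    warn("zero-variance phenotype: degenerate fit, all components at zero")
    animals <- unique(records$animal)
    return(structure(list(
      sigma_a2 = 0, sigma_pe2 = 0, sigma_e2 = 0,
      ebv = tibble(animal = animals, ebv = 0, reliability = 0),
      residuals = rep(0, nrow(records)),
      fixed_effects = tibble(hys = sort(unique(records$hys)),
                             estimate = y[1]),
      pe = tibble(animal = animals, pe = 0),
      records = records,
      loglik = NA_real_, converged = FALSE, iterations = 0L,
      degenerate = TRUE), class = "repeatability_fit"))
  }
  # confounded herd-year-season class: all its records from one animal
  conf <- records |>
    group_by(.data$hys) |>
    summarise(one = dplyr::n_distinct(.data$animal) == 1L, .groups = "drop")
  if (any(conf$one)) {
    warn(sprintf("herd-year-season class(es) confounded with a single animal: %s",
                 paste(conf$hys[conf$one], collapse = ", ")))
  }
  ped_use <- prune_pedigree(as_tibble(ped), unique(records$animal),
                            ancestor_depth)
  A <- build_additive_relationship(ped_use)
  animals_A <- colnames(A)
  ia <- match(records$animal, animals_A)
  nrec <- nrow(records)
  Za <- matrix(0, nrec, length(animals_A))
  Za[cbind(seq_len(nrec), ia)] <- 1
  pheno_animals <- sort(unique(records$animal))
  ipe <- match(records$animal, pheno_animals)
  Zpe <- matrix(0, nrec, length(pheno_animals))
  Zpe[cbind(seq_len(nrec), ipe)] <- 1
  hys_levels <- sort(unique(records$hys))
  X <- outer(records$hys, hys_levels, "==") * 1
  ZaA <- Za %*% A
  Va <- tcrossprod(ZaA, Za)
  # with single records throughout, pe is confounded with the residual:
  # drop it and fit the plain animal model (sigma_pe2 fixed at 0)
  has_pe <- max(table(records$animal)) > 1L
  if (!has_pe) {
    warn("no animal has repeated records: sigma_pe2 is not identifiable and is fixed at 0 (animal model)")
    fit <- reml_engine(y, X, list(Va), qlev = c(length(animals_A), nrec),
                       max_iter = max_iter, ll_tol = ll_tol,
                       par_tol = par_tol)
    theta <- c(fit$theta[1], 0, fit$theta[2])
  } else {
    Vpe <- tcrossprod(Zpe)
    fit <- reml_engine(y, X, list(Va, Vpe),
                       qlev = c(length(animals_A), length(pheno_animals), nrec),
                       max_iter = max_iter, ll_tol = ll_tol,
                       par_tol = par_tol)
    theta <- fit$theta
  }
  a_hat <- theta[1] * drop(crossprod(ZaA, fit$Py))
  pe_hat <- theta[2] * drop(crossprod(Zpe, fit$Py))
  e_hat <- theta[3] * fit$Py
  # PEV of a: sigma_a2 * diag(A) - sigma_a2^2 * diag(A Za' P Za A)
  PT <- fit$P %*% ZaA
  pev <- theta[1] * diag(A) - theta[1]^2 * colSums(ZaA * PT)
  rel <- if (theta[1] > fit$lower_bound * 2) {
    pmin(pmax(1 - pev / theta[1], 0), 1)
  } else rep(0, length(animals_A))
  structure(list(
    sigma_a2 = theta[1], sigma_pe2 = theta[2], sigma_e2 = theta[3],
    ebv = tibble(animal = animals_A, ebv = a_hat, reliability = rel),
    residuals = e_hat,
    fixed_effects = tibble(hys = hys_levels, estimate = fit$beta),
    pe = tibble(animal = pheno_animals, pe = pe_hat),
    records = records,
    loglik = fit$loglik, converged = fit$converged,
    iterations = fit$iterations,
    degenerate = all(fit$at_bound)), class = "repeatability_fit")
}

#' @export
print.repeatability_fit <- function(x, ...) {
  cat(sprintf("<repeatability_fit> sigma_a2 %.4g, sigma_pe2 %.4g, sigma_e2 %.4g (h2 %.3f, rep %.3f)\n",
              x$sigma_a2, x$sigma_pe2, x$sigma_e2,
              x$sigma_a2 / (x$sigma_a2 + x$sigma_pe2 + x$sigma_e2),
              (x$sigma_a2 + x$sigma_pe2) / (x$sigma_a2 + x$sigma_pe2 + x$sigma_e2)))
  cat(sprintf("  %d animals with EBV, converged: %s (%d iterations)\n",
              nrow(x$ebv), x$converged, x$iterations))
  invisible(x)
}

#' Corrected phenotypes from a repeatability fit
#'
#' One value per phenotyped animal: its EBV plus the mean of its per-record
#' estimated residuals, `y_c(i) = a_hat_i + mean(e_hat over i's records)`.
#' The permanent-environment solution is a non-transmissible nuisance and is
#' excluded by default; `include_pe = TRUE` adds it for the alternative
#' reading of "average estimated residuals".
#'
#' @param fit A `repeatability_fit`.
#' @param include_pe Add the animal's permanent-environment BLUP.
#' @return Tibble `animal`, `y_c` (phenotyped animals only).
#' @export
corrected_phenotype <- function(fit, include_pe = FALSE) {
  if (!fit$converged && !fit$degenerate) {
    abort("repeatability fit did not converge; corrected phenotypes unavailable")
  }
  res <- tibble(animal = fit$records$animal, e = fit$residuals) |>
    group_by(.data$animal) |>
    summarise(mean_e = mean(.data$e), .groups = "drop")
  out <- res |>
    left_join(fit$ebv, by = "animal") |>
    mutate(y_c = .data$ebv + .data$mean_e)
  if (include_pe) {
    out <- out |>
      left_join(fit$pe, by = "animal") |>
      mutate(y_c = .data$y_c + .data$pe)
  }
  out |> select("animal", "y_c")
}

#' Filter animals by EBV reliability
#'
#' Retains animals whose pedigree EBV reliability reaches `min_rel`
#' (default 0.3), the conventional cut for admitting an animal's corrected
#' phenotype into genomic analyses.
#'
#' @param fit A `repeatability_fit`.
#' @param min_rel Minimum reliability in `[0, 1]`.
#' @return Character vector of retained animal ids.
#' @export
filter_by_reliability <- function(fit, min_rel = 0.3) {
  check_prob(min_rel, "min_rel")
  pheno <- unique(fit$records$animal)
  keep <- fit$ebv$animal[fit$ebv$reliability >= min_rel]
  pheno[pheno %in% keep]
}
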