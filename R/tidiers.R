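# broom-style tidiers for the fitted objects.

#' Tidy a repeatability-model fit
#'
#' @param x A `repeatability_fit`.
#' @param ... Unused.
#' @return Tibble with one row per variance component (`term`, `estimate`).
#' @export
tidy.repeatability_fit <- function(x, ...) {
  tibble(term = c("sigma2_a", "sigma2_pe", "sigma2_e"),
         estimate = c(x$sigma_a2, x$sigma_pe2, x$sigma_e2))
}

#' Glance at a repeatability-model fit
#'
#' @param x A `repeatability_fit`.
#' @param ... Unused.
#' @return One-row tibble with heritability, repeatability, restricted
#'   log-likelihood and convergence information.
#' @export
glance.repeatability_fit <- function(x, ...) {
  tot <- x$sigma_a2 + x$sigma_pe2 + x$sigma_e2
  tibble(h2 = if (tot > 0) x$sigma_a2 / tot else NA_real_,
         repeatability = if (tot > 0) (x$sigma_a2 + x$sigma_pe2) / tot else NA_real_,
         loglik_restricted = x$loglik, converged = x$converged,
         iterations = x$iterations, n_records = nrow(x$records),
         n_animals = dplyr::n_distinct(x$records$animal),
         degenerate = x$degenerate)
}

#' Tidy a genomic-model fit
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return Tibble with one row per variance component.
#' @export
tidy.gblup_fit <- function(x, ...) {
  tibble(term = names(x$variance_components),
         estimate = unname(x$variance_components))
}

#' Glance at a genomic-model fit
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return One-row tibble with the genomic variance ratio, restricted
#'   log-likelihood and convergence information.
#' @export
glance.gblup_fit <- function(x, ...) {
  vc <- x$variance_components
  tot <- sum(vc)
  tibble(model = x$model,
         h2_genomic = if (tot > 0) sum(vc[names(vc) != "sigma2_e"]) / tot else NA_real_,
         mu = x$mu, loglik_restricted = x$loglik_restricted,
         converged = x$converged, iterations = x$iterations,
         n_reference = x$n_reference)
}
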