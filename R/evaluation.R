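#' Forward split by birthdate
#'
#' Assigns each phenotyped, genotyped animal to the reference set (born on or
#' before its population's cutoff) or the validation set (born after),
#' emulating forward prediction of young animals from older ones.
#'
#' @param ped Pedigree tibble with `animal`, `birthdate` and (optionally)
#'   `population` columns.
#' @param y_c Tibble `animal`, `y_c` of animals eligible for assignment.
#' @param cutoff A single `Date`, or a named vector/list of `Date`s keyed by
#'   population label.
#' @return A tibble of class `hb_split`: `animal`, `population`,
#'   `birthdate`, `role` (`"reference"`/`"validation"`).
#' @export
split_by_birthdate <- function(ped, y_c, cutoff) {
  df <- as_tibble(y_c) |>
    left_join(ped |> select(dplyr::any_of(c("animal", "birthdate", "population"))),
              by = "animal")
  if (anyNA(df$birthdate)) {
    abort("birthdates missing for some animals in `y_c`")
  }
  if (!"population" %in% names(df)) df$population <- "all"
  cut_of <- function(popn) {
    if (length(cutoff) == 1L && is.null(names(cutoff))) return(cutoff[[1]])
    if (!popn %in% names(cutoff)) {
      abort(sprintf("no cutoff supplied for population `%s`", popn))
    }
    cutoff[[popn]]
  }
  out <- df |>
    group_by(.data$population) |>
    mutate(role = ifelse(.data$birthdate <= cut_of(.data$population[1]),
                         "reference", "validation")) |>
    ungroup()
  tab <- out |> dplyr::count(.data$population, .data$role)
  for (popn in unique(out$population)) {
    roles <- tab$role[tab$population == popn]
    if (!"validation" %in% roles) {
      abort(sprintf("empty validation set in population `%s` (cutoff after all birthdates)", popn),
            class = "hapblup_config_error")
    }
    if (!"reference" %in% roles) {
      abort(sprintf("empty reference set in population `%s` (cutoff before all birthdates)", popn),
            class = "hapblup_config_error")
    }
  }
  out <- out |> select("animal", "population", "birthdate", "role")
  class(out) <- c("hb_split", class(out))
  out
}

#' Prediction accuracy
#'
#' Pearson correlation between genomic breeding values and corrected
#' phenotypes over validation animals.
#'
#' @param gebv,y_c Paired numeric vectors (validation animals only).
#' @return Correlation in `[-1, 1]`.
#' @export
prediction_accuracy <- function(gebv, y_c) {
  if (length(gebv) != length(y_c)) abort("inputs must be paired")
  if (length(gebv) < 3) abort("need at least 3 validation animals")
  if (var(gebv) == 0 || var(y_c) == 0) {
    abort("zero variance: accuracy undefined",
          class = "hapblup_undefined_metric_error")
  }
  cor(gebv, y_c)
}

#' Regression slope of corrected phenotype on GEBV (dispersion bias)
#'
#' Ordinary least-squares slope of `y_c` on `gebv`; 1 means unbiased
#' dispersion, above 1 means over-shrunk (too little GEBV variance).
#'
#' @inheritParams prediction_accuracy
#' @return The OLS slope.
#' @export
regression_slope <- function(y_c, gebv) {
  if (length(gebv) != length(y_c)) abort("inputs must be paired")
  if (var(gebv) == 0) {
    abort("zero GEBV variance: slope undefined",
          class = "hapblup_undefined_metric_error")
  }
  cov(y_c, gebv) / var(gebv)
}

# Metrics of one fitted model on one validation set.
.scenario_metrics <- function(fit, y_c_tbl, val_animals) {
  val <- y_c_tbl |> filter(.data$animal %in% val_animals)
  g <- fit$gebv$gebv[match(val$animal, fit$gebv$animal)]
  tibble(accuracy = prediction_accuracy(g, val$y_c),
         slope = regression_slope(val$y_c, g))
}

#' Run the scenario grid
#'
#' Full factorial evaluation: marker density panels x reference sets
#' (each single population and both pooled) x models x LD thresholds, with
#' accuracy and dispersion slope reported separately per validation
#' population. GBLUP does not depend on the threshold and is fitted once per
#' (density, reference) cell. Scenario failures are caught and recorded; the
#' grid continues.
#'
#' @param geno QC'd merged [phased_genotypes()] with population labels.
#' @param y_c Tibble `animal`, `y_c` for all phenotyped genotyped animals.
#' @param split An `hb_split` from [split_by_birthdate()].
#' @param thresholds LD-threshold ladder for the haplotype models.
#' @param models Character subset of `GBLUP`, `GHBLUP`, `GH_plus_GBLUP`.
#' @param densities Named list of SNP-id vectors (`NULL` = all SNPs)
#'   defining nested marker panels, e.g. chip-like vs sequence-like.
#' @param max_window_snps Passed to [build_blocks()].
#' @param ... Passed to [reml_fit()].
#' @return A tibble of class `hb_scenario_grid`: one row per
#'   density x reference x model x threshold x validation population with
#'   `accuracy`, `slope`, variance components, convergence flag and an
#'   `error` column (`NA` when the scenario succeeded).
#' @export
run_scenario_grid <- function(geno, y_c, split,
                              thresholds = ld_threshold_ladder(),
                              models = c("GBLUP", "GHBLUP", "GH_plus_GBLUP"),
                              densities = list(dense = NULL),
                              max_window_snps = 100, ...) {
  y_c <- as_tibble(y_c)
  pops <- sort(unique(split$population))
  ref_sets <- c(as.list(pops), list(pops))
  names(ref_sets) <- c(pops, "combined")
  rows <- list()
  emit <- function(density, reference, model, threshold, fit, err = NA_character_) {
    for (vp in pops) {
      val <- split$animal[split$population == vp & split$role == "validation"]
      row <- tibble(density = density, reference = reference,
                    validation = vp, model = model, threshold = threshold,
                    accuracy = NA_real_, slope = NA_real_,
                    sigma2_g = NA_real_, sigma2_block = NA_real_,
                    sigma2_nonblock = NA_real_, sigma2_e = NA_real_,
                    converged = NA, error = err)
      if (is.null(fit)) { rows[[length(rows) + 1L]] <<- row; next }
      met <- tryCatch(.scenario_metrics(fit, y_c, val),
                      error = function(e) NULL)
      if (!is.null(met)) {
        row$accuracy <- met$accuracy; row$slope <- met$slope
      }
      vc <- fit$variance_components
      vc_get <- function(nm) if (nm %in% names(vc)) vc[[nm]] else NA_real_
      row$sigma2_g <- vc_get("sigma2_g")
      row$sigma2_block <- vc_get("sigma2_block")
      row$sigma2_nonblock <- vc_get("sigma2_nonblock")
      row$sigma2_e <- vc_get("sigma2_e")
      row$converged <- fit$converged
      rows[[length(rows) + 1L]] <<- row
    }
  }
  for (dn in names(densities)) {
    g_d <- if (is.null(densities[[dn]])) geno else
      subset_markers(geno, match(densities[[dn]], geno$map$snp_id))
    parts <- if (any(models != "GBLUP")) {
      lapply(thresholds, function(t) build_blocks(g_d, t, max_window_snps))
    } else list()
    for (rn in names(ref_sets)) {
      ref <- split$animal[split$role == "reference" &
                            split$population %in% ref_sets[[rn]]]
      y_ref <- y_c |> filter(.data$animal %in% ref)
      for (model in models) {
        if (model == "GBLUP") {
          fit <- tryCatch(run_model("GBLUP", g_d, NULL, y_ref, ...),
                          error = function(e) conditionMessage(e))
          if (is.character(fit)) emit(dn, rn, model, NA_real_, NULL, fit)
          else emit(dn, rn, model, NA_real_, fit)
        } else {
          for (ti in seq_along(thresholds)) {
            fit <- tryCatch(
              suppressWarnings(run_model(model, g_d, parts[[ti]], y_ref, ...)),
              error = function(e) conditionMessage(e))
            if (is.character(fit)) emit(dn, rn, model, thresholds[ti], NULL, fit)
            else emit(dn, rn, model, thresholds[ti], fit)
          }
        }
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("hb_scenario_grid", class(out))
  out
}
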