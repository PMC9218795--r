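# ggplot2 autoplot methods for the package's tabular results.

#' Plot block statistics across the LD-threshold ladder
#'
#' Line plot of blocked-SNP, haploblock and haplotype-allele counts against
#' the r-squared threshold; all three decrease as the threshold rises.
#'
#' @param object An `hb_block_stats` tibble from [block_statistics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hb_block_stats <- function(object, ...) {
  long <- object |>
    select("threshold", "n_blocked_snps", "n_haploblocks",
           "n_haplotype_alleles") |>
    tidyr::pivot_longer(-"threshold", names_to = "quantity",
                        values_to = "count") |>
    mutate(quantity = dplyr::recode(.data$quantity,
                                    n_blocked_snps = "blocked SNPs",
                                    n_haploblocks = "haploblocks",
                                    n_haplotype_alleles = "haplotype alleles"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$count,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(r^2 ~ "threshold"), y = "count",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a scenario grid
#'
#' Accuracy against the LD threshold, one line per model and reference set,
#' faceted by density panel and validation population. Threshold-free GBLUP
#' rows are drawn as horizontal reference lines.
#'
#' @param object An `hb_scenario_grid` from [run_scenario_grid()].
#' @param metric Column to plot: `"accuracy"` (default) or `"slope"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hb_scenario_grid <- function(object, metric = "accuracy", ...) {
  ok <- object |> filter(is.na(.data$error) | .data$error == "")
  hap <- ok |> filter(!is.na(.data$threshold))
  snp <- ok |> filter(is.na(.data$threshold))
  p <- ggplot2::ggplot(hap, ggplot2::aes(x = .data$threshold,
                                         y = .data[[metric]],
                                         colour = .data$model,
                                         linetype = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(density ~ validation) +
    ggplot2::labs(x = expression(r^2 ~ "threshold"), y = metric) +
    ggplot2::theme_minimal()
  if (nrow(snp) > 0) {
    p <- p + ggplot2::geom_hline(
      data = snp,
      ggplot2::aes(yintercept = .data[[metric]], colour = .data$model,
                   linetype = .data$reference), alpha = 0.6)
  }
  p
}
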