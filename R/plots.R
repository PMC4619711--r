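#' Plot per-population genotype frequency distributions
#'
#' Stacked genotype-frequency bars per population, faceted by rsid — the
#' standard way of eyeballing between-population differences at
#' pharmacogenomic loci. `MISSING` rows are dropped.
#'
#' @param freqs Output of [genotype_distribution()].
#' @return A ggplot object.
#' @export
plot_genotype_distribution <- function(freqs) {
  dat <- freqs[freqs$genotype != "MISSING", , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$population,
                                    y = .data$frequency,
                                    fill = .data$genotype)) +
    ggplot2::geom_col(position = "stack", color = "grey30",
                      linewidth = 0.2) +
    ggplot2::facet_wrap(~rsid) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "genotype") +
    ggplot2::labs(x = "population", y = "genotype frequency") +
    ggplot2::theme_minimal()
}

#' Plot the population burden summary
#'
#' Mean number of matched drug-response SNPs per individual, by population,
#' with +/- 1 SD error bars, for all matches and for the FDA biomarker-label
#' subset.
#'
#' @param summary Output of [group_summary()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary) {
  long <- dplyr::bind_rows(
    tibble::tibble(population = summary$population, subset = "all",
                   mean = summary$mean_all, sd = summary$sd_all),
    tibble::tibble(population = summary$population, subset = "FDA-labeled",
                   mean = summary$mean_fda, sd = summary$sd_fda)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population, y = .data$mean,
                                     fill = .data$subset)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "population",
                  y = "matched drug-response SNPs per individual") +
    ggplot2::theme_minimal()
}
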