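#' Boxplot of genotyping success by sample type
#'
#' Per-individual percentage of loci genotyped, grouped by sample type --
#' the standard panel-validation view of how hair, swab and tissue samples
#' perform.
#'
#' @param success Output of [genotyping_success()].
#' @return A ggplot object.
#' @export
plot_genotyping_success <- function(success) {
  ggplot2::ggplot(success,
                  ggplot2::aes(x = .data$sample_type,
                               y = .data$pct_genotyped)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = "Sample type", y = "% loci genotyped") +
    ggplot2::theme_minimal()
}

#' Dot-and-whisker plot of per-population diversity statistics
#'
#' Ho, He and Fis per population, faceted by statistic.
#'
#' @param stats Output of [basic_stats()].
#' @return A ggplot object.
#' @export
plot_pop_stats <- function(stats) {
  long <- stats %>%
    tidyr::pivot_longer(c("ho", "he", "fis"), names_to = "stat") %>%
    mutate(stat = factor(toupper(.data$stat), levels = c("HO", "HE", "FIS")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population,
                                     y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "Population", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pairwise Fst estimates with bootstrap intervals
#'
#' @param fst Tibble of pairwise estimates (e.g. rows of
#'   [fst_bootstrap_ci()] output), with optional `ci_low`/`ci_high`.
#' @return A ggplot object.
#' @export
plot_pairwise_fst <- function(fst) {
  fst <- mutate(fst, pair = paste(.data$pop_a, .data$pop_b, sep = " vs "))
  p <- ggplot2::ggplot(fst, ggplot2::aes(x = .data$pair, y = .data$theta)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = expression(theta~(F[ST]))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (all(c("ci_low", "ci_high") %in% names(fst))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.15)
  }
  p
}

#' Bar chart of discordance categories
#'
#' Mean mismatches per individual by category for one or more comparisons.
#'
#' @param report A `discordance_report` or a named list of them.
#' @return A ggplot object.
#' @export
plot_discordance <- function(report) {
  reports <- if (inherits(report, "discordance_report")) {
    list(comparison = report)
  } else report
  dat <- purrr::imap_dfr(reports, function(r, nm) {
    r$summary %>%
      tidyr::pivot_longer(dplyr::starts_with("mean_a_"),
                          names_to = "category", values_to = "mean_loci") %>%
      mutate(comparison = nm,
             category = sub("^mean_", "", .data$category))
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category,
                                    y = .data$mean_loci,
                                    fill = .data$comparison)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Mean discordant loci per individual") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
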