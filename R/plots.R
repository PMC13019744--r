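#' Plot ROH counts per chromosome, stacked by length class
#'
#' @param segments Segment tibble from [detect_roh].
#' @param chrom_lengths Optional chromosome-length tibble; when given, the
#'   per-chromosome average coverage is overlaid as points on a secondary
#'   axis.
#' @param n_individuals Required with `chrom_lengths` (coverage
#'   denominator).
#' @return A ggplot object.
#' @export
plot_roh_by_chromosome <- function(segments, chrom_lengths = NULL,
                                   n_individuals = NULL) {
  df <- segments |>
    mutate(
      class = roh_length_class(.data$length_bp),
      chromosome = factor(.data$chromosome,
                          levels = unique(.data$chromosome[order(chrom_rank(.data$chromosome))]))
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$chromosome, fill = .data$class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "Chromosome", y = "ROH count", fill = "Length class (Mb)") +
    ggplot2::theme_minimal()
  if (!is.null(chrom_lengths)) {
    stopifnot(!is.null(n_individuals))
    cov <- chromosome_summary(segments, chrom_lengths, n_individuals)
    cov$chromosome <- factor(cov$chromosome, levels = levels(df$chromosome))
    scale <- max(table(df$chromosome)) / max(cov$coverage_pct, 1e-9)
    p <- p +
      ggplot2::geom_point(
        data = cov,
        ggplot2::aes(x = .data$chromosome, y = .data$coverage_pct * scale),
        inherit.aes = FALSE, colour = "red"
      ) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / scale, name = "Coverage (%)")
      )
  }
  p
}

#' Plot the distribution of inbreeding coefficients
#'
#' Overlaid histograms of F_HOM and F_ROH across individuals.
#'
#' @param profiles Tibble from [inbreeding_profiles].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_inbreeding_distribution <- function(profiles, bins = 40) {
  df <- profiles |>
    select("individual_id", "f_hom", "f_roh") |>
    tidyr::pivot_longer(c("f_hom", "f_roh"), names_to = "coefficient",
                        values_to = "value") |>
    mutate(coefficient = toupper(.data$coefficient))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$coefficient)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "Inbreeding coefficient", y = "Individuals", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of per-SNP ROH incidence
#'
#' @param incidences Tibble from [snp_roh_incidence].
#' @param threshold Optional island threshold to draw as a horizontal line.
#' @return A ggplot object.
#' @export
plot_snp_incidence <- function(incidences, threshold = NULL) {
  df <- incidences |>
    mutate(chromosome = factor(.data$chromosome,
                               levels = unique(.data$chromosome[order(chrom_rank(.data$chromosome))])))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position_bp / 1e6, y = .data$fraction_in_roh,
    colour = .data$chromosome
  )) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x", switch = "x") +
    ggplot2::labs(x = "Position (Mb)", y = "Fraction of individuals in ROH") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, colour = "red",
                                 linetype = "dashed")
  }
  p
}

#' Heatmap of inbreeding-coefficient correlations
#'
#' @param object A `roh_correlations` tibble from [correlation_matrix].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.roh_correlations <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var_x, y = .data$var_y,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
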