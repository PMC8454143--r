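#' Plot the genome-wide ROH incidence track
#'
#' Per-SNP ROH rate along the genome with a horizontal line at the island
#' threshold — the classic population ROH-rate panel.
#'
#' @param track Tibble from [snp_incidence()].
#' @param rate_threshold Threshold line (default 0.2).
#' @return A ggplot object.
#' @export
plot_incidence <- function(track, rate_threshold = 0.2) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$rate)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue4") +
    ggplot2::geom_hline(yintercept = rate_threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Position (Mb)", y = "ROH rate") +
    ggplot2::theme_minimal()
}

#' Plot ROH length distribution by size class
#'
#' @param segments ROH tibble from [detect_roh()].
#' @return A ggplot object.
#' @export
plot_roh_lengths <- function(segments) {
  ggplot2::ggplot(segments,
                  ggplot2::aes(x = .data$length_bp / 1e6, fill = .data$size_class)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ROH length (Mb)", y = "Segments", fill = "Class") +
    ggplot2::theme_minimal()
}

#' Boxplot of total ROH length in the extreme phenotype groups
#'
#' @param summaries Tibble from [summarize_individuals()].
#' @param groups Tibble from [split_extremes()].
#' @return A ggplot object.
#' @export
plot_extreme_groups <- function(summaries, groups) {
  d <- dplyr::inner_join(groups, summaries, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                  y = .data$total_length_bp / 1e6,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "Phenotype group", y = "Total ROH length (Mb)") +
    ggplot2::theme_minimal()
}

#' Heatmap of an LD matrix
#'
#' @param object An `ld_matrix` from [ld_matrix()].
#' @param measure "r2" or "dprime".
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_matrix <- function(object, measure = c("r2", "dprime"), ...) {
  measure <- match.arg(measure)
  m <- object[[measure]]
  d <- as_tibble(as.data.frame(as.table(m)))
  names(d) <- c("snp1", "snp2", "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$snp1, y = .data$snp2,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1),
                                 name = if (measure == "r2") expression(r^2) else "|D'|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Boxplot of adjusted trait values for carriers vs non-carriers
#'
#' @param adjusted_values Numeric vector of adjusted trait values.
#' @param carrier Logical carrier status, same length.
#' @param trait Axis label.
#' @return A ggplot object.
#' @export
plot_carrier_boxplot <- function(adjusted_values, carrier, trait = "trait") {
  d <- tibble(value = adjusted_values,
              status = ifelse(carrier, "ROH", "non-ROH"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$status, y = .data$value,
                                  fill = .data$status)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = paste("Adjusted", trait)) +
    ggplot2::theme_minimal()
}
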