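# ggplot2 views of the main result types.

#' Plot windowed variant-density profiles
#'
#' Line plot of group-mean variant counts per window, faceted by chromosome.
#' With exactly two groups the display mirrors the classic two-group genome
#' scan: the first group plotted upward and the second downward. Centromere
#' midpoints from the genome index, when present, are drawn as vertical
#' lines.
#'
#' @param means Output of [group_mean_profile()].
#' @param genome Optional `genome_index` carrying centromere midpoints.
#' @return A ggplot object.
#' @export
plot_window_profile <- function(means, genome = NULL) {
  groups <- unique(means$group)
  d <- means
  if (length(groups) == 2) {
    d <- mutate(d, mean_n = if_else(.data$group == groups[2],
                                    -.data$mean_n, .data$mean_n))
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                       y = .data$mean_n,
                                       colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "variants per window",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(genome) && any(!is.na(genome$centromere_mid))) {
    cen <- filter(as_tibble(genome), !is.na(.data$centromere_mid))
    p <- p + ggplot2::geom_vline(data = cen,
                                 ggplot2::aes(xintercept = .data$centromere_mid / 1e6),
                                 colour = "black", linewidth = 0.3)
  }
  p
}

#' Plot a substitution spectrum
#'
#' Bar chart of the 12 directed substitution counts, coloured by
#' transition/transversion class; facets by `unit` when the table carries
#' one (e.g. per line or per group).
#'
#' @param spectrum A [substitution_spectrum()] tibble, optionally with a
#'   `unit` column for faceting.
#' @return A ggplot object.
#' @export
plot_substitution_spectrum <- function(spectrum) {
  p <- ggplot2::ggplot(spectrum,
                       ggplot2::aes(x = .data$substitution, y = .data$n,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "line-specific SNPs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("unit" %in% names(spectrum)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$unit))
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.substitution_spectrum <- function(object, ...) {
  plot_substitution_spectrum(object)
}

#' Plot a variant-sharing profile
#'
#' Bar chart of variant counts per presence pattern: line-specific patterns
#' first, then patterns of increasing sharing, with the all-lines (common)
#' pattern last.
#'
#' @param profile A [classify_sharing()] result.
#' @return A ggplot object.
#' @export
plot_sharing_profile <- function(profile) {
  d <- mutate(as_tibble(profile),
              lines = factor(.data$lines, levels = .data$lines))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lines, y = .data$n_variants)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "lines carrying the variant", y = "variants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.sharing_profile <- function(object, ...) {
  plot_sharing_profile(object)
}
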