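# ggplot2 figure helpers for the main result types

#' Bar plot of the read mismatch spectrum
#'
#' @param spectrum an `occudiff_spectrum` object from
#'   [mismatch_spectrum()].
#' @return a ggplot.
#' @export
plot_mismatch_spectrum <- function(spectrum) {
  d <- spectrum$spectrum
  ggplot2::ggplot(d, ggplot2::aes(.data$substitution, .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "single-mismatch reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Metagene density curve over scaled transcript regions
#'
#' @param density tibble from [metagene_density()].
#' @return a ggplot with region boundaries marked.
#' @export
plot_metagene <- function(density) {
  bounds <- cumsum(rle(density$region)$lengths)
  ggplot2::ggplot(density, ggplot2::aes(.data$bin, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = utils::head(bounds, -1) + 0.5,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "scaled transcript position (5'UTR | CDS | 3'UTR)",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Region distribution bars for a position set
#'
#' @param dist tibble from [region_distribution()].
#' @return a ggplot.
#' @export
plot_region_distribution <- function(dist) {
  d <- filter(dist, .data$region != "noncoding")
  d$region <- factor(d$region, levels = c("5UTR", "CDS", "3UTR"))
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of positions") +
    ggplot2::theme_minimal()
}

#' ECDF of distances to the closest significant position
#'
#' @param distances tibble from [nearest_significant_distance()].
#' @return a ggplot comparing significant and non-significant queries.
#' @export
plot_distance_ecdf <- function(distances) {
  ggplot2::ggplot(distances,
                  ggplot2::aes(.data$distance, colour = .data$query_set)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "distance to closest significant position (nt)",
                  y = "ECDF", colour = NULL) +
    ggplot2::theme_minimal()
}
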