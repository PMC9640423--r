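# ggplot2 views of the main result types.

#' Plot a raster band
#' @param object a `ripaq_raster`.
#' @param band band index to draw (default 1).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ripaq_raster <- function(object, band = 1, ...) {
  bn <- (object$band_names %||% paste0("band", seq_len(n_bands(object))))[band]
  df <- as_tibble(object) %>% filter(.data$band == bn)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "easting (m)", y = "northing (m)", fill = bn) +
    ggplot2::theme_minimal()
}

#' Plot station RSQI scores by bank
#' @param object a `ripaq_scores` tibble.
#' @param ... unused.
#' @return a ggplot: RSQI against chainage, coloured by quality category.
#' @export
autoplot.ripaq_scores <- function(object, ...) {
  pal <- c(very_low = "#d73027", low = "#fc8d59",
           moderate = "#fee08b", high = "#1a9850")
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$chainage_m, .data$rsqi,
                               fill = .data$rsqi_category)) +
    ggplot2::geom_col(width = 80) +
    ggplot2::facet_wrap(~ .data$bank, ncol = 1) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "chainage along stream (m)", y = "RSQI",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a count heat map
#' @param object a `ripaq_confusion`.
#' @param ... unused.
#' @return a ggplot tile map with counts printed in the cells.
#' @export
autoplot.ripaq_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#3182bd") +
    ggplot2::labs(x = "reference class", y = "predicted class") +
    ggplot2::theme_minimal()
}
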