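# Plot methods for result objects.

#' @export
autoplot.biv_islands <- function(object, ...) {
  df <- tibble(width = object$end - object$start)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$width)) +
    ggplot2::geom_histogram(bins = 30, ...) +
    ggplot2::labs(x = "island width (bp)", y = "islands") +
    ggplot2::theme_minimal()
}

#' Compare island width distributions across marks
#'
#' @param ... Named island tibbles, e.g. `K4me3 = islands_k4`.
#' @return A ggplot of width distributions (log10 x axis).
#' @export
plot_island_widths <- function(...) {
  sets <- list(...)
  df <- purrr::imap_dfr(sets, function(isl, nm) {
    tibble(mark = nm, width = isl$end - isl$start)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$width, fill = .data$mark)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.6, position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "width (bp)", y = "islands", fill = NULL) +
    ggplot2::theme_minimal()
}
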