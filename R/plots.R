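#' Plot a spacer-distance histogram for one motif pair
#'
#' Unique-spacer counts per spacer distance with the modal distance(s)
#' highlighted; an optional horizontal line marks the significance
#' cutoff.
#'
#' @param object A `pair_histogram` from [unique_spacer_histogram()].
#' @param cutoff Optional cutoff count to draw (e.g. `fcut(n)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_histogram <- function(object, cutoff = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$count,
                                        fill = .data$modal)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "spacer length d (bp)", y = "unique-spacer occurrences",
      title = sprintf("%s ... %s (n = %d, fmax = %d)",
                      object$A, object$B, object$n, object$fmax)) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot the spacer-length distribution of reported motif pairs
#'
#' @param object A `pair_scan` from [find_motif_pairs()].
#' @param ... Unused.
#' @return A ggplot object (bar chart of reported pairs per spacer
#'   length).
#' @export
autoplot.pair_scan <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) {
    df <- tibble(d = integer(), n = integer())
    return(ggplot2::ggplot(df, ggplot2::aes(.data$d, .data$n)) +
             ggplot2::geom_col() +
             ggplot2::labs(x = "spacer length d (bp)",
                           y = "reported motif pairs") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "spacer length d (bp)", y = "reported motif pairs") +
    ggplot2::theme_minimal()
}
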