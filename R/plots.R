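#' Heat map of per-sequence shape profiles
#'
#' One tile per (sequence, position) cell, faceted by feature, using the
#' diverging red-white-blue convention (red = low, e.g. narrow minor
#' groove; blue = high; missing cells blank, producing the white margins
#' characteristic of unflanked cores).
#'
#' @param object A `shape_tbl`.
#' @param row_order Optional character vector of `seq_id`s (e.g. from
#'   [cluster_rows()]) fixing the row order.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_tbl <- function(object, row_order = NULL, ...) {
  df <- tibble::as_tibble(object)
  ids <- row_order %||% unique(df$seq_id)
  df$seq_id <- factor(df$seq_id, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$seq_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  midpoint = NA, na.value = "white") +
    ggplot2::labs(x = "position (core coordinates)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Average shape profile plot
#'
#' @param avg Output of [average_profile()].
#' @return A ggplot object (one panel per feature).
#' @export
plot_average_profile <- function(avg) {
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "position (core coordinates)", y = "mean value") +
    ggplot2::theme_minimal()
}

#' Barcode plot of ranked probes
#'
#' Vertical bars for probes ranked by descending intensity, coloured white
#' (no site), yellow (one site) or brown (multiple sites).
#'
#' @param object A `barcode_tbl` from [barcode_probes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barcode_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = 1,
                                       fill = .data$category)) +
    ggplot2::geom_tile(colour = NA) +
    ggplot2::scale_fill_manual(values = c(white = "white", yellow = "gold",
                                          brown = "saddlebrown"),
                               drop = FALSE) +
    ggplot2::labs(x = "probes by descending intensity", y = NULL,
                  fill = "sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Per-position differential-shape significance plot
#'
#' Positions coloured by significance category (orange for the strong
#' threshold, yellow for the weak one, green background otherwise).
#'
#' @param object A `shape_differential` from [ks_differential()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_differential <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[df$tested, ],
                  ggplot2::aes(x = .data$position, y = .data$feature,
                               fill = .data$category)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(none = "darkgreen",
                                          weak = "gold", strong = "orange"),
                               drop = FALSE) +
    ggplot2::labs(x = "position (core coordinates)", y = NULL,
                  fill = "difference") +
    ggplot2::theme_minimal()
}

#' Cross-validated accuracy of the model variants
#'
#' Per-fold held-out R^2 for the sequence-only, shape-augmented and
#' shuffled-shape models.
#'
#' @param object A `regression_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regression_report <- function(object, ...) {
  df <- tidy(object)
  df$variant <- factor(df$variant,
                       levels = c("sequence_only", "sequence_plus_shape",
                                  "sequence_plus_shuffled_shape"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$r2,
                                   fill = .data$variant)) +
    ggplot2::geom_boxplot(width = 0.5, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(sequence_only = "tan4",
                                          sequence_plus_shape = "purple3",
                                          sequence_plus_shuffled_shape = "magenta3")) +
    ggplot2::labs(x = NULL, y = expression("held-out" ~ R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
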