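#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-leaf trait trajectories
#'
#' One line per tracked leaf over time; carried (missed-detection) entries
#' are drawn hollow. Leaf order in the legend follows track id, i.e. order
#' of emergence.
#'
#' @param object A `leaf_trait_series` from [extract_leaf_traits()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.leaf_trait_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frame_index, y = .data$mean_value,
                               colour = factor(.data$track_id),
                               group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status == "carried"),
                        size = 1.2, show.legend = c(shape = FALSE)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "timepoint", y = unique(object$trait_name)[1],
                  colour = "leaf (track id)") +
    ggplot2::theme_minimal()
}

#' Plot leaf counts over time
#'
#' @param counts Output of [leaf_count_series()], possibly row-bound over
#'   plants.
#' @return A ggplot object (one line per plant).
#' @export
plot_leaf_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$frame_index, y = .data$n_leaves,
                               group = .data$plant_id,
                               colour = factor(.data$plant_id))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "timepoint", y = "leaves observed",
                  colour = "plant") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of HOTA per-pair association scores
#'
#' Histogram of the A(c) association scores weighted by how many
#' true-positive matches each track pair contributes, with the mean as a
#' reference line.
#'
#' @param object A `leaf_hota` from [hota_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.leaf_hota <- function(object, ...) {
  dat <- object$assoc[rep(seq_len(nrow(object$assoc)),
                          object$assoc$n_matches), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$A)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = mean(dat$A), colour = "red") +
    ggplot2::labs(x = "association score A(c)", y = "TP matches",
                  title = sprintf("HOTA %.3f at alpha %.2f",
                                  object$hota, object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a per-timepoint group comparison
#'
#' Group means over time with the per-frame p-value trace on a secondary
#' panel-like overlay (log10 scale via transparency of significance
#' markers).
#'
#' @param object A `leaf_group_comparison` from [group_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.leaf_group_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("mean_a", "mean_b"),
                              names_to = "group", values_to = "mean")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame_index, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(object, !is.na(.data$p), .data$p < 0.05),
      ggplot2::aes(x = .data$frame_index), y = -Inf, inherit.aes = FALSE,
      shape = 8, colour = "black") +
    ggplot2::labs(x = "timepoint", y = "group mean",
                  caption = "* frames with p < 0.05") +
    ggplot2::theme_minimal()
}
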