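# ggplot2 views of the result containers.

#' Plot smallest-angle error series of frame comparisons
#'
#' One panel per comparison, colored by segment: the per-sample smallest
#' rotation angle between the two frames over the analysis window.
#'
#' @param object A `frame_comparison` tibble.
#' @param comparisons Which comparison ids to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frame_comparison <- function(object, comparisons = unique(object$comparison), ...) {
  df <- object |>
    dplyr::filter(.data$comparison %in% comparisons) |>
    dplyr::mutate(label = sprintf("#%d %s", .data$comparison, .data$error_source)) |>
    dplyr::select("label", "segment", "trial", "angle") |>
    tidyr::unnest("angle")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$angle_deg,
                                   color = .data$segment)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "smallest angle (deg)", color = "segment") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of aggregated error sources
#'
#' Cross-subject mean RMSD with STD error bars per comparison and segment.
#'
#' @param object An `error_summary` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.error_summary <- function(object, ...) {
  df <- dplyr::mutate(object, label = sprintf("#%d %s", .data$comparison,
                                              .data$error_source))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$mean_rmsd_deg,
                                   fill = .data$trial)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rmsd_deg - .data$sd_rmsd_deg,
                                        ymax = .data$mean_rmsd_deg + .data$sd_rmsd_deg),
                           position = "dodge", linewidth = 0.3) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = NULL, y = "RMSD (deg)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
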