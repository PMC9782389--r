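# broom-style tidiers for the result containers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a set of frame comparisons
#'
#' One row per comparison x segment x trial with the RMSD and maximum
#' smallest-angle error; the per-sample angle series is dropped.
#'
#' @param x A `frame_comparison` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.frame_comparison <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -dplyr::any_of("angle"))
}

#' @rdname tidy.frame_comparison
#' @export
glance.frame_comparison <- function(x, ...) {
  tibble::tibble(
    n_comparisons = nrow(x),
    n_segments = dplyr::n_distinct(x$segment),
    n_trials = dplyr::n_distinct(x$trial),
    rmsd_frame_definition_deg = mean(x$rmsd_deg[x$comparison %in% 1:3]),
    rmsd_sta_deg = mean(x$rmsd_deg[x$comparison == 4]),
    rmsd_filter_deg = mean(x$rmsd_deg[x$comparison == 5]),
    rmsd_total_deg = mean(x$rmsd_deg[x$comparison %in% 7:9]),
    max_error_deg = max(x$max_deg))
}

#' Tidy / summarize an aggregated error summary
#'
#' @param x An `error_summary` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.error_summary <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.error_summary
#' @export
glance.error_summary <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_subjects = max(x$n_subjects),
    range_frame_definition_deg = paste(round(range(x$mean_rmsd_deg[x$comparison %in% 1:3]), 1),
                                       collapse = "-"),
    range_sta_deg = paste(round(range(x$mean_rmsd_deg[x$comparison == 4]), 1),
                          collapse = "-"),
    range_filter_deg = paste(round(range(x$mean_rmsd_deg[x$comparison == 5]), 1),
                             collapse = "-"))
}
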