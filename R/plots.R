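#' Plot carrier PSI against the control pool
#'
#' Violin-style view of per-sample control PSI for each event with the
#' carrier observation overlaid, the standard way aberrant events are shown
#' against a healthy-donor pool.
#'
#' @param psi Carrier PSI observations ([specificity_test()] output).
#' @param controls Control profile ([control_profile()] output, with the
#'   `per_sample_psi` list-column).
#' @return A ggplot object.
#' @export
plot_psi_controls <- function(psi, controls) {
  ctl <- controls |>
    dplyr::select("event_key", "per_sample_psi") |>
    tidyr::unnest(cols = "per_sample_psi")
  ggplot2::ggplot(ctl, ggplot2::aes(x = .data$event_key, y = .data$per_sample_psi)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey50", scale = "width") +
    ggplot2::geom_point(data = psi, ggplot2::aes(y = .data$psi),
                        colour = "firebrick", size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "PSI",
                  title = "Carrier PSI vs healthy-donor controls") +
    ggplot2::theme_minimal()
}

#' Bar plot of splicing events by type
#'
#' @param events Event tibble ([detect_events()] output).
#' @return A ggplot object.
#' @export
plot_event_types <- function(events) {
  counts <- event_type_counts(events)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$event_type, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Splicing event type", y = "Unique events") +
    ggplot2::theme_minimal()
}

#' Stacked classification bar plot by variant position bin
#'
#' @param variants Variant tibble with `position_bin` and `classification`.
#' @return A ggplot object.
#' @export
plot_position_bins <- function(variants) {
  tab <- position_classification_table(variants)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$position_bin, y = .data$n,
                                    fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Position relative to exon", y = "Unique variants",
                  fill = "Class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
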