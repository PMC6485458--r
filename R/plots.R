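# Diagnostic plots for the main result types.

#' Plot crossover breakpoint distributions
#'
#' Reciprocal-normalised breakpoint counts per inter-marker interval, with
#' the PRDM9 motif position marked.
#'
#' @param events Event tibble from [call_events()].
#' @param map The [hotspot_map].
#' @return A ggplot object.
#' @export
plot_breakpoints <- function(events, map) {
  hist <- breakpoint_histogram(events, map)
  hist |>
    mutate(mid = (.data$bp_lo + .data$bp_hi) / 2) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$mid, y = .data$n_normalized,
                                 fill = .data$reciprocal)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = map$motif_position,
                        linetype = "dashed") +
    ggplot2::labs(x = "breakpoint interval midpoint (bp)",
                  y = "normalised crossover count",
                  title = "Crossover breakpoint distribution") +
    ggplot2::theme_minimal()
}

#' Plot per-site log rate ratios
#'
#' Allele-level reciprocal transmission imbalance along the hotspot, with
#' significance stars from the standardized Pearson residuals.
#'
#' @param logrr Output of [logrr_per_site()].
#' @param map Optional [hotspot_map] to mark the motif position.
#' @return A ggplot object.
#' @export
plot_logrr <- function(logrr, map = NULL) {
  p <- logrr |>
    ggplot2::ggplot(ggplot2::aes(x = .data$position, y = .data$logrr,
                                 colour = .data$allele)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.6,
                       show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$donor_id)) +
    ggplot2::labs(x = "position (bp)", y = "log rate ratio (RI vs RII)",
                  title = "Per-site transmission imbalance") +
    ggplot2::theme_minimal()
  if (!is.null(map)) {
    p <- p + ggplot2::geom_vline(xintercept = map$motif_position,
                                 linetype = "dashed")
  }
  p
}

#' Plot zone densities
#'
#' Run density per zone (hotspot, flanks, outside).
#'
#' @param zd A `zone_densities` object from [zone_densities()].
#' @return A ggplot object.
#' @export
plot_zone_densities <- function(zd) {
  zd$summary |>
    mutate(zone = factor(.data$zone, levels = unique(.data$zone))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$zone, y = .data$run_density,
                                 fill = .data$zone == "hotspot")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "runs per bp",
                  title = "Mononucleotide-run density by zone") +
    ggplot2::theme_minimal()
}
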