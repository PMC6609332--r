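#' Plot averaged dF/F traces with the stimulation layout
#'
#' Draws the ROI-averaged dF/F with its s.e.m. envelope; stimulation
#' trials are shaded.
#'
#' @param object A `dff_traces` tibble from [compute_dff()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dff_traces <- function(object, ...) {
  avg <- suppressWarnings(aggregate_mean_sem(object))
  protocol <- attr(object, "protocol")
  p <- ggplot2::ggplot(avg, ggplot2::aes(x = .data$time_s, y = .data$mean_dff))
  if (!is.null(protocol) && nrow(protocol)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(protocol),
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.12
    )
  }
  p +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_dff - .data$sem_dff,
                   ymax = .data$mean_dff + .data$sem_dff),
      fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
}

#' Plot a normalised frequency response
#'
#' @param object A `freq_response` from [normalize_frequency_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.freq_response <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frequency_hz, y = .data$norm_pct)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "Stimulation frequency (Hz)",
                  y = sprintf("Peak ΔF/F (%% of %g Hz)",
                              attr(object, "reference_hz"))) +
    ggplot2::theme_minimal()
}

#' Plot per-compartment labelling densities
#'
#' @param object A `density_report` from [density_report()].
#' @param ... Unused.
#' @return A ggplot object (log-scaled densities per compartment).
#' @export
autoplot.density_report <- function(object, ...) {
  ggplot2::ggplot(object$compartments,
                  ggplot2::aes(x = .data$compartment, y = .data$density)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = expression("Gold particles / " * mu * m^2),
                  subtitle = sprintf("DCV/bouton density ratio: %.2f",
                                     object$dcv_over_bouton)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated EM annotation
#'
#' Shows the bouton outline, DCV counting discs, and gold particles
#' coloured by assigned compartment.
#'
#' @param ann An [em_annotation()] with a bouton outline.
#' @return A ggplot object.
#' @export
plot_em_annotation <- function(ann) {
  stopifnot(inherits(ann, "em_annotation"))
  gold <- assign_gold_compartments(ann)
  outline <- tibble::tibble(x_nm = ann$bouton_outline[, 1],
                            y_nm = ann$bouton_outline[, 2])
  discs <- ann$dcv_centers |>
    dplyr::mutate(id = dplyr::row_number()) |>
    dplyr::reframe(
      theta = seq(0, 2 * pi, length.out = 33),
      x_nm = .data$x_nm + ann$dcv_disc_radius * cos(.data$theta),
      y_nm = .data$y_nm + ann$dcv_disc_radius * sin(.data$theta),
      .by = "id"
    )
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = outline,
                          ggplot2::aes(.data$x_nm, .data$y_nm),
                          fill = NA, colour = "black") +
    ggplot2::geom_polygon(data = discs,
                          ggplot2::aes(.data$x_nm, .data$y_nm,
                                       group = .data$id),
                          fill = "grey85", colour = "grey50") +
    ggplot2::geom_point(data = gold,
                        ggplot2::aes(.data$x_nm, .data$y_nm,
                                     colour = .data$compartment),
                        size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", colour = "compartment") +
    ggplot2::theme_minimal()
}
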