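#' Plot a phase response curve
#'
#' @param prc A PRC tibble (`phase_rad`, `shift_rad`).
#' @param unit `"rad"` or `"hours"` for both axes.
#' @return A ggplot object.
#' @export
plot_prc <- function(prc, unit = c("rad", "hours")) {
  unit <- match.arg(unit)
  check_prc(prc)
  df <- prc
  if (unit == "hours") {
    df <- dplyr::mutate(df, phase = rad_to_ct(.data$phase_rad),
                        shift = .data$shift_rad * 24 / (2 * pi))
    labs <- c("stimulus phase (CT h)", "phase shift (h)")
  } else {
    df <- dplyr::mutate(df, phase = .data$phase_rad, shift = .data$shift_rad)
    labs <- c("stimulus phase (rad)", "phase shift (rad)")
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$shift)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hill_fit <- function(object, n_curve = 200, ...) {
  rng <- object$conc_range
  xx <- 10^seq(log10(rng[1] / 3), log10(rng[2] * 3), length.out = n_curve)
  curve <- tibble(concentration = xx, response = predict(object, xx) / object$r_max)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$concentration, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "SR amplitude (normalized)",
                  subtitle = sprintf("EC50 = %.3g, n = %.2f, R² = %.3f",
                                     object$ec50, object$n_hill, object$r2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phase_line <- function(object, ...) {
  rr <- seq(object$range[1], object$range[2], length.out = 50)
  ggplot2::ggplot(tibble(R = rr, theta = object$a + object$b * rr),
                  ggplot2::aes(.data$R, .data$theta)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "SR amplitude", y = "SR phase (rad)") +
    ggplot2::theme_minimal()
}

#' Plot a plate's luminescence traces
#'
#' @param plate Long-format plate tibble (`time_h`, `well`, `luminescence`).
#' @param wells Optional metadata with `stim_time_h` to mark stimulus times.
#' @return A ggplot object.
#' @export
plot_plate <- function(plate, wells = NULL) {
  p <- ggplot2::ggplot(plate,
                       ggplot2::aes(.data$time_h, .data$luminescence,
                                    colour = .data$well)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = "luminescence (counts)") +
    ggplot2::theme_minimal()
  if (!is.null(wells) && "stim_time_h" %in% names(wells)) {
    p <- p + ggplot2::geom_vline(xintercept = unique(wells$stim_time_h),
                                 linetype = 2, colour = "grey40")
  }
  p
}
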