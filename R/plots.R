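# Figure glue: normalized-decline time courses (mean +/- SEM per group),
# the calibration surface, and the rating curves.

#' Plot normalized pressure declines (mean +/- SEM per group)
#'
#' @param results named list of `normalized_decline` objects (one per
#'   group), e.g. from [analyze_study()].
#' @return a ggplot object.
#' @export
plot_normalized_decline <- function(results) {
  df <- do.call(rbind, lapply(names(results), function(g) {
    r <- results[[g]]
    data.frame(group = g, time_min = r$time_s / 60, mean = r$mean,
               sem = r$sem)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$mean,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "normalized pressure decline",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot the carrier calibration surface
#'
#' Observed resistances (points) against the fitted surface (lines) as a
#' function of velocity, one curve per filling level.
#'
#' @param table a calibration table.
#' @param model a fitted [carrier_model()] (optional).
#' @param circuit a [circuit_config()].
#' @return a ggplot object.
#' @export
plot_calibration <- function(table, model = NULL,
                             circuit = default_circuit()) {
  q <- velocity_to_flow(table$velocity_mps, circuit$tube_inner_diameter)
  df <- data.frame(V = table$velocity_mps, L = table$level_pct,
                   R = resistance_from_ohm(table$delta_p_mmHg, q))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$V, y = .data$R,
                                        colour = factor(.data$L))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "flow velocity (m/s)",
                  y = "hydrodynamic resistance (Pa s/m^3)",
                  colour = "filling (%)") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    vg <- seq(min(df$V), max(df$V), length.out = 100)
    fit <- do.call(rbind, lapply(sort(unique(df$L)), function(l)
      data.frame(V = vg, L = l,
                 R = carrier_resistance(model, rep(l / 100, 100), vg))))
    p <- p + ggplot2::geom_line(data = fit, linewidth = 0.4)
  }
  p
}

#' Plot rating curves
#'
#' Pressure decline against lysis level (1 - filling), one curve per
#' velocity.
#'
#' @param curves a [build_rating_curves()] object.
#' @return a ggplot object.
#' @export
plot_rating_curves <- function(curves) {
  Lg <- seq(curves$L_knee, 1, length.out = 200)
  df <- do.call(rbind, lapply(curves$curves, function(cu)
    data.frame(velocity = cu$velocity, lysis = 1 - Lg,
               dp = cu$forward(Lg))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dp, y = .data$lysis,
                                   colour = factor(.data$velocity))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pressure decline (mmHg)", y = "lysis level",
                  colour = "velocity (m/s)") +
    ggplot2::theme_minimal()
}
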