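# ggplot2 displays for the main result types.

#' Plot a segmented track as latitude through time
#'
#' The classic migration profile: latitude against date, colored by
#' flight/stopover role, mirroring how segmentations are assessed
#' visually.
#'
#' @param object A `mig_segments`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mig_segments <- function(object, ...) {
  df <- object$steps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_start, y = .data$lat_from,
                                   color = .data$role)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = NULL, y = "Latitude (°N)", color = "Segment role",
                  title = unique(df$individual_id)[1]) +
    ggplot2::theme_minimal()
}

#' Plot a utilization distribution
#'
#' Filled raster of cell probabilities on the projected grid (km).
#'
#' @param object A `mig_ud`.
#' @param trim Hide cells below this mass quantile (display only).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mig_ud <- function(object, trim = 0, ...) {
  g <- object$grid
  df <- expand.grid(ix = seq_len(g$ncol), iy = seq_len(g$nrow))
  df$x <- g$xmin + (df$ix - 0.5) * g$cell_km
  df$y <- g$ymin + (df$iy - 0.5) * g$cell_km
  df$p <- as.vector(t(object$values))[(df$iy - 1) * g$ncol + df$ix]
  df <- df[df$p > stats::quantile(object$values[object$values > 0], trim), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "UD mass") +
    ggplot2::labs(x = "Easting (km)", y = "Northing (km)") +
    ggplot2::theme_minimal()
}

#' Plot model-averaged coefficients with confidence intervals
#' @param object A `mig_modavg`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mig_modavg <- function(object, ...) {
  df <- object$coefficients
  df <- df[df$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Standardized coefficient (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot daily movement with the quiet-day threshold
#'
#' Daily total distance over the breeding window with the 2 km/day
#' nesting threshold; incubation shows as a sustained run below the
#' line.
#'
#' @param daily Output of [daily_movement()].
#' @param cfg A [breeding_config()] supplying the threshold.
#' @return A ggplot.
#' @export
plot_daily_movement <- function(daily, cfg = breeding_config()) {
  ggplot2::ggplot(daily[!daily$missing, ],
                  ggplot2::aes(x = .data$date, y = .data$total_km)) +
    ggplot2::geom_col(width = 0.8, fill = "grey35") +
    ggplot2::geom_hline(yintercept = cfg$daily_max_km, color = "red",
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "Daily distance (km)") +
    ggplot2::theme_minimal()
}
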