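# Step-length / turning-angle series construction.

#' Build a step series from fixes
#'
#' Converts each individual's fix series into steps: great-circle length
#' (km), signed turning angle (radians, change of bearing, left turns
#' positive; undefined for the first step), elapsed interval (minutes),
#' and the speed covariate. The covariate is the device ground speed at
#' the step's starting fix plus 0.1 km/h (the offset avoids
#' zero-inflation); where the device speed is absent it falls back to
#' step length over interval plus the same offset.
#'
#' @param fixes Fix tibble (each individual needs at least 3 fixes).
#' @return Step tibble: `individual_id`, `t_start`, `t_end`, `step_km`,
#'   `angle_rad`, `interval_min`, `speed_cov`, plus step endpoint
#'   coordinates (`lon_from`, `lat_from`, `lon_to`, `lat_to`).
#' @export
build_steps <- function(fixes) {
  assert_fixes(fixes)
  fixes |>
    group_by(.data$individual_id) |>
    group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 3) abort("build_steps: need at least 3 fixes per individual")
      i <- seq_len(n - 1)
      len <- haversine_km(df$lon[i], df$lat[i], df$lon[i + 1], df$lat[i + 1])
      brg <- bearing_rad(df$lon[i], df$lat[i], df$lon[i + 1], df$lat[i + 1])
      # left (counterclockwise) turns positive; compass bearings grow
      # clockwise, hence the sign flip
      ang <- c(NA_real_, wrap_angle(-diff(brg)))
      # a zero-length step has no bearing; its angle (and the next) is undefined
      zero <- len < 1e-9
      ang[zero] <- NA_real_
      ang[which(zero[-length(zero)]) + 1] <- NA_real_
      interval <- as.numeric(difftime(df$timestamp[i + 1], df$timestamp[i],
                                      units = "mins"))
      spd <- df$ground_speed[i]
      cov <- ifelse(is.na(spd), len / (interval / 60), spd) + 0.1
      tibble(t_start = df$timestamp[i], t_end = df$timestamp[i + 1],
             step_km = len, angle_rad = ang, interval_min = interval,
             speed_cov = cov,
             lon_from = df$lon[i], lat_from = df$lat[i],
             lon_to = df$lon[i + 1], lat_to = df$lat[i + 1])
    }) |>
    ungroup()
}
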