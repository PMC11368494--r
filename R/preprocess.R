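# Quality control, regular resampling, net-squared-displacement onset
# detection, and the spring-analysis window.

#' Preprocessing configuration
#'
#' Defaults follow the standard goose-telemetry workflow: drop fixes with
#' horizontal dilution of precision above 5, regularize to 30-minute
#' intervals, call migration onset at the first northward movement bout
#' displacing at least 50 km from the wintering area, and analyze from
#' 7 days before onset through 1 August.
#'
#' @param max_hdop HDOP threshold; fixes with measured HDOP strictly
#'   above this are removed (missing HDOP is retained).
#' @param target_interval Resampling target, minutes.
#' @param resample_tolerance Slot tolerance, minutes (must be below half
#'   the target interval).
#' @param onset_displacement_km Minimum net bout displacement calling
#'   migration onset.
#' @param pre_onset_buffer_days Days of wintering context retained before
#'   onset.
#' @param season_end Month-day (`"08-01"`) ending the season window.
#' @param bout_regression_km Displacement regression tolerated within an
#'   outbound bout before the bout is considered broken.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_hdop = 5, target_interval = 30,
                      resample_tolerance = 5, onset_displacement_km = 50,
                      pre_onset_buffer_days = 7, season_end = "08-01",
                      bout_regression_km = 2) {
  stopifnot(max_hdop > 0, target_interval > 0, resample_tolerance > 0,
            onset_displacement_km > 0, pre_onset_buffer_days > 0,
            resample_tolerance < target_interval / 2)
  structure(list(max_hdop = max_hdop, target_interval = target_interval,
                 resample_tolerance = resample_tolerance,
                 onset_displacement_km = onset_displacement_km,
                 pre_onset_buffer_days = pre_onset_buffer_days,
                 season_end = season_end,
                 bout_regression_km = bout_regression_km),
            class = "qc_config")
}

#' Remove poor-quality fixes by HDOP
#'
#' Retains fixes whose HDOP is at most `max_hdop` or missing; the removal
#' is strictly-greater-than, so a fix at exactly the threshold survives.
#'
#' @param fixes Fix tibble (see [read_tracks()]); may hold several
#'   individuals.
#' @param max_hdop Threshold (default 5).
#' @return Filtered fix tibble, order preserved.
#' @export
filter_hdop <- function(fixes, max_hdop = 5) {
  assert_fixes(fixes)
  keep <- is.na(fixes$hdop) | fixes$hdop <= max_hdop
  out <- fixes[keep, , drop = FALSE]
  if (nrow(out) == 0) abort("all fixes removed by the HDOP filter")
  removed <- sum(!keep)
  if (removed > 0) inform(paste0("filter_hdop: removed ", removed, " fix(es)"))
  out
}

#' Regularize the sampling interval
#'
#' Thins each individual to one fix per time slot, slots anchored at the
#' individual's first fix and spaced `target_interval` minutes apart. The
#' fix nearest a slot within `tolerance` minutes is kept; slots with no
#' in-tolerance fix stay empty (gaps are never interpolated). A 15-minute
#' duty cycle therefore becomes a 30-minute series; an already-regular
#' series passes through unchanged.
#'
#' @param fixes Fix tibble.
#' @param target_interval Minutes between retained fixes.
#' @param tolerance Slot half-width, minutes.
#' @return Resampled fix tibble.
#' @export
resample_interval <- function(fixes, target_interval = 30, tolerance = 5) {
  assert_fixes(fixes)
  if (nrow(fixes) == 0) return(fixes)
  fixes |>
    group_by(.data$individual_id) |>
    group_modify(function(df, key) {
      t0 <- df$timestamp[1]
      mins <- as.numeric(difftime(df$timestamp, t0, units = "mins"))
      slot <- round(mins / target_interval)
      offset <- abs(mins - slot * target_interval)
      df$..slot <- slot
      df$..off <- offset
      df <- df[offset <= tolerance, , drop = FALSE]
      df <- df[order(df$..slot, df$..off), , drop = FALSE]
      df <- df[!duplicated(df$..slot), , drop = FALSE]
      df <- df[order(df$timestamp), , drop = FALSE]
      df$..slot <- NULL; df$..off <- NULL
      df
    }) |>
    ungroup()
}

#' Net squared displacement from a reference fix
#'
#' Adds `nsd_km2`, the squared great-circle distance (km^2) of every fix
#' from the reference fix of its individual.
#'
#' @param fixes Fix tibble.
#' @param reference_index Index of the reference fix within each
#'   individual's time-ordered series (default 1, the first fix).
#' @return Fix tibble with `nsd_km2` and `displacement_km` columns.
#' @export
net_squared_displacement <- function(fixes, reference_index = 1) {
  assert_fixes(fixes)
  fixes |>
    group_by(.data$individual_id) |>
    group_modify(function(df, key) {
      if (reference_index < 1 || reference_index > nrow(df)) {
        abort("reference_index outside the track")
      }
      d <- haversine_km(df$lon[reference_index], df$lat[reference_index],
                        df$lon, df$lat)
      df$displacement_km <- d
      df$nsd_km2 <- d^2
      df
    }) |>
    ungroup()
}

# maximal outbound bouts: runs of consecutive steps each gaining more
# than `slack` km of displacement from the reference. The per-step gain
# requirement separates sustained departures from residence jitter
# (which gains and loses well under the slack every step) and makes the
# bout start coincide with the first true departure step.
outbound_bouts <- function(displacement_km, slack) {
  n <- length(displacement_km)
  if (n < 2) return(tibble(start = integer(), end = integer()))
  ok <- diff(displacement_km) > slack
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep] + 1)  # fix indices
}

#' Detect migration onset from net squared displacement
#'
#' Onset is the start of the first movement bout that (a) displaces the
#' individual at least `onset_displacement_km` from its pre-bout
#' position and (b) carries a positive net latitude change. A bout is a
#' maximal run of consecutive steps each of which gains more than
#' `bout_regression_km` of displacement from the track's reference fix;
#' the per-step gain requirement keeps residence jitter from blurring
#' the bout start. Individuals with no qualifying bout get `detected = FALSE`
#' (a sentinel, not an error) so incomplete migrations can be dropped.
#'
#' @param fixes Fix tibble (reference = first fix of each individual).
#' @param cfg A [qc_config()].
#' @return One row per individual: `individual_id`, `detected`,
#'   `onset_time`, `onset_index` (index of the bout's first fix).
#' @export
detect_migration_onset <- function(fixes, cfg = qc_config()) {
  assert_fixes(fixes)
  fixes |>
    group_by(.data$individual_id) |>
    group_modify(function(df, key) {
      d <- haversine_km(df$lon[1], df$lat[1], df$lon, df$lat)
      bouts <- outbound_bouts(d, cfg$bout_regression_km)
      for (i in seq_len(nrow(bouts))) {
        s <- bouts$start[i]; e <- bouts$end[i]
        net <- haversine_km(df$lon[s], df$lat[s], df$lon[e], df$lat[e])
        if (net >= cfg$onset_displacement_km && df$lat[e] > df$lat[s]) {
          return(tibble(detected = TRUE, onset_time = df$timestamp[s],
                        onset_index = s))
        }
      }
      tibble(detected = FALSE,
             onset_time = as.POSIXct(NA_real_, tz = "UTC"),
             onset_index = NA_integer_)
    }) |>
    ungroup()
}

#' Window a track around migration onset
#'
#' Retains fixes from `pre_onset_buffer_days` before each individual's
#' onset through the season end (1 August of the onset year, inclusive
#' through 23:59:59 UTC).
#'
#' @param fixes Fix tibble.
#' @param onsets Output of [detect_migration_onset()] (individuals with
#'   `detected = FALSE` are dropped).
#' @param cfg A [qc_config()].
#' @return Windowed fix tibble.
#' @export
window_track <- function(fixes, onsets, cfg = qc_config()) {
  assert_fixes(fixes)
  onsets <- onsets[onsets$detected, , drop = FALSE]
  out <- fixes |>
    inner_join(select(onsets, "individual_id", "onset_time"),
               by = "individual_id") |>
    group_by(.data$individual_id) |>
    filter({
      t0 <- .data$onset_time - cfg$pre_onset_buffer_days * 86400
      end_day <- lubridate::ymd(paste0(lubridate::year(.data$onset_time),
                                       "-", cfg$season_end), tz = "UTC")
      .data$timestamp >= t0 & .data$timestamp < end_day + 86400
    }) |>
    ungroup() |>
    select(-"onset_time")
  if (nrow(out) == 0) abort("window_track: no fixes fall inside the window")
  out
}

#' Clip tracks at a per-individual endpoint date
#'
#' The migration trajectory conventionally ends at incubation initiation
#' (or the cohort median for non-attempters); clipping before fitting
#' keeps nest-attendance fixes from entering the movement model.
#'
#' @param fixes Fix tibble.
#' @param endpoints Tibble `individual_id`, `endpoint` (Date); fixes on
#'   or after the endpoint are dropped. Individuals without an endpoint
#'   row keep all fixes.
#' @return Clipped fix tibble.
#' @export
clip_to_endpoint <- function(fixes, endpoints) {
  assert_fixes(fixes)
  fixes |>
    left_join(endpoints, by = "individual_id") |>
    filter(is.na(.data$endpoint) |
             as.Date(.data$timestamp, tz = "UTC") < .data$endpoint) |>
    select(-"endpoint")
}
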