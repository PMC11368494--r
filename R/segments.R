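# Merge decoded states into flight/stopover segments and derive the
# per-individual migration characteristics.

#' Default migratory-flight length threshold
#'
#' Twice the fitted migratory-state mean step length: a run of migratory
#' steps shorter than this in total is treated as a spurious flight
#' (e.g., a single missing fix) and folded back into the surrounding
#' stopover. With a migratory mean of 32.3 km/step the threshold is
#' 64.6 km.
#'
#' @param migratory_mean_km Migratory-state gamma mean (km/step), or a
#'   `mig_hmm` from which it is taken via [label_states()].
#' @return Threshold in km.
#' @export
#' @examples
#' flight_threshold(32.3) # 64.6
flight_threshold <- function(migratory_mean_km) {
  if (inherits(migratory_mean_km, "mig_hmm")) {
    model <- migratory_mean_km
    mig_state <- label_states(model)$state[label_states(model)$role == "flight"]
    migratory_mean_km <- model$gamma$mean[mig_state]
  }
  2 * migratory_mean_km
}

#' Merge decoded states into flight and stopover segments
#'
#' Consecutive migratory-state steps form candidate flight segments; any
#' candidate whose cumulative great-circle length falls below
#' `flight_min_km` is reclassified as stopover and absorbed into its
#' neighbours, after which the remaining alternation of roles defines
#' the segment list. Set `per_step = TRUE` to apply the threshold to
#' individual steps instead of segment totals (sensitivity analysis).
#'
#' @param steps Decoded step tibble for ONE individual (needs `state`;
#'   see [decode_states()]).
#' @param role_map Output of [label_states()].
#' @param flight_min_km Minimum cumulative flight length; default
#'   [flight_threshold()] of the supplied model mean. Must be given
#'   explicitly when `role_map` is a plain tibble.
#' @param per_step Apply the threshold per step rather than per segment.
#' @return A `mig_segments` object: list with `steps` (per-step tibble
#'   with `role`, `segment_id`) and `segments` (one row per segment:
#'   `segment_id`, `role`, `start`, `end`, `n_steps`, `cum_km`, `dlat`,
#'   `t_start`, `t_end`).
#' @export
merge_segments <- function(steps, role_map, flight_min_km, per_step = FALSE) {
  stopifnot("state" %in% names(steps))
  if (length(unique(steps$individual_id)) > 1) {
    abort("merge_segments: one individual at a time")
  }
  role <- role_map$role[match(steps$state, role_map$state)]
  if (per_step) {
    role[role == "flight" & steps$step_km < flight_min_km] <- "stopover"
  } else {
    r <- rle(role)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values == "flight")) {
      if (sum(steps$step_km[starts[i]:ends[i]]) < flight_min_km) {
        role[starts[i]:ends[i]] <- "stopover"
      }
    }
  }
  r <- rle(role)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segments <- tibble(
    segment_id = seq_along(r$values),
    role = r$values,
    start = starts, end = ends,
    n_steps = r$lengths,
    cum_km = map_dbl(seq_along(starts),
                     ~ sum(steps$step_km[starts[.x]:ends[.x]])),
    dlat = steps$lat_to[ends] - steps$lat_from[starts],
    t_start = steps$t_start[starts],
    t_end = steps$t_end[ends]
  )
  steps$role <- role
  steps$segment_id <- rep(segments$segment_id, segments$n_steps)
  structure(list(steps = steps, segments = segments,
                 flight_min_km = flight_min_km),
            class = "mig_segments")
}

#' Per-step rows of a segmentation (for CSV output)
#' @param segments A `mig_segments`.
#' @return Per-step tibble including state, role, segment id and
#'   within-segment cumulative length.
#' @export
segment_steps <- function(segments) {
  stopifnot(inherits(segments, "mig_segments"))
  segments$steps |>
    group_by(.data$segment_id) |>
    mutate(cum_km = cumsum(.data$step_km)) |>
    ungroup() |>
    select("individual_id", "t_start", "t_end", "step_km", "angle_rad",
           "interval_min", "speed_cov", "lon_from", "lat_from", "lon_to",
           "lat_to", "state", "role", "segment_id", "cum_km")
}

#' @export
print.mig_segments <- function(x, ...) {
  cat("Segmented track:", nrow(x$steps), "steps,",
      sum(x$segments$role == "flight"), "flight segment(s),",
      sum(x$segments$role == "stopover"), "stopover segment(s)\n")
  invisible(x)
}

#' Count stopovers and reverse migratory movements
#'
#' Stopovers are stopover-role segments excluding the final stopover
#' (the pre-nesting settlement near the breeding area). Reverse
#' migratory movements are flight segments with a net latitude decrease.
#'
#' @param segments A `mig_segments`.
#' @return One-row tibble `n_stopovers`, `n_reverse`.
#' @export
count_movements <- function(segments) {
  seg <- segments$segments
  n_stop <- sum(seg$role == "stopover")
  if (nrow(seg) > 0 && seg$role[nrow(seg)] == "stopover") {
    n_stop <- n_stop - 1
  }
  n_rev <- sum(seg$role == "flight" & seg$dlat < 0)
  tibble(n_stopovers = n_stop, n_reverse = n_rev)
}

#' Summarize migration characteristics for one individual
#'
#' Total distance is the sum of step lengths from migration onset
#' through the end of the final migratory flight (set
#' `flight_steps_only = TRUE` to sum flight-state steps only); duration
#' is the elapsed days over the same span; arrival is the ordinal date
#' of the final flight's end. The share of time in high-use areas is the
#' fraction of migration-period fixes falling inside the supplied 50%
#' isopleth mask; the wintering region is the region polygon containing
#' the last pre-onset fix (else `"Other"`).
#'
#' @param segments A `mig_segments`.
#' @param onset_time Migration onset (POSIXct) for this individual.
#' @param high_use Optional `mig_iso` isopleth set; its 0.5-level mask
#'   defines high use. Absent mask reports `prop_high_use = NA` (never
#'   zero).
#' @param regions Optional `mig_regions` for the winter-origin label.
#' @param fixes Optional fix tibble for this individual (needed for
#'   `prop_high_use` and `winter_region`).
#' @param flight_steps_only Sum only flight-state steps into the total
#'   distance (default sums every step in the migration span).
#' @return One-row tibble of migration characteristics.
#' @export
summarize_migration <- function(segments, onset_time, high_use = NULL,
                                regions = NULL, fixes = NULL,
                                flight_steps_only = FALSE) {
  steps <- segments$steps
  seg <- segments$segments
  flights <- seg[seg$role == "flight", , drop = FALSE]
  id <- steps$individual_id[1]
  if (nrow(flights) == 0) {
    return(tibble(individual_id = id, total_distance_km = NA_real_,
                  duration_days = NA_real_, n_stopovers = NA_integer_,
                  n_reverse = NA_integer_, arrival_ordinal = NA_integer_,
                  prop_high_use = NA_real_, winter_region = NA_character_))
  }
  mig_end <- flights$t_end[nrow(flights)]
  in_window <- steps$t_start >= onset_time & steps$t_end <= mig_end
  if (flight_steps_only) in_window <- in_window & steps$role == "flight"
  counts <- count_movements(segments)
  prop_hu <- NA_real_
  if (!is.null(high_use) && !is.null(fixes)) {
    mf <- fixes[fixes$timestamp >= onset_time & fixes$timestamp <= mig_end, ]
    if (nrow(mf) > 0) prop_hu <- mean(iso_contains(high_use, 0.5, mf$lon, mf$lat))
  }
  wr <- NA_character_
  if (!is.null(regions) && !is.null(fixes)) {
    pre <- fixes[fixes$timestamp < onset_time, ]
    wr <- if (nrow(pre) == 0) "Other" else
      region_of(regions, pre$lon[nrow(pre)], pre$lat[nrow(pre)])
  }
  tibble(
    individual_id = id,
    total_distance_km = sum(steps$step_km[in_window]),
    duration_days = as.numeric(difftime(mig_end, onset_time, units = "days")),
    n_stopovers = counts$n_stopovers,
    n_reverse = counts$n_reverse,
    arrival_ordinal = lubridate::yday(mig_end),
    prop_high_use = prop_hu,
    winter_region = wr
  )
}
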