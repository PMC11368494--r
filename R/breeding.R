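# Breeding attempt/deferral and success/failure classification from the
# incubation movement signature, plus phenology and the capital-income
# strategy class.

#' Breeding-classification configuration
#'
#' An individual that moves at most 2 km per day for at least 6
#' consecutive days while staying at a single site is classed as
#' attempting to nest; an attempt whose quiet run lasts at least 23 days
#' (the minimum published incubation period for midcontinent
#' white-fronted geese) is classed successful. Pre-nesting durations
#' under 10 days mark a capital-leaning strategy (too short to rebuild
#' reserves locally).
#'
#' @param window_start,window_end Month-day strings bounding the daily
#'   movement series (defaults 15 May - 30 July).
#' @param daily_max_km Daily total distance at or below which a day is
#'   "quiet".
#' @param min_attempt_days Minimum quiet-run length calling an attempt.
#' @param success_days Quiet-run length separating success from failure.
#' @param cluster_radius_km Site-fidelity radius around the run's median
#'   coordinate.
#' @param site_fidelity_prop Fraction of run fixes that must fall inside
#'   the radius.
#' @param capital_prenest_days Pre-nesting duration strictly below which
#'   the strategy is capital-leaning.
#' @param max_missing_days Consecutive missing days tolerated inside a
#'   quiet run.
#' @param day_offset_hours Shift applied before assigning fixes to
#'   calendar days (0 = UTC days; set to a longitude-based offset for
#'   local-solar sensitivity checks).
#' @return List of class `breeding_config`.
#' @export
breeding_config <- function(window_start = "05-15", window_end = "07-30",
                            daily_max_km = 2, min_attempt_days = 6,
                            success_days = 23, cluster_radius_km = 0.25,
                            site_fidelity_prop = 0.9,
                            capital_prenest_days = 10,
                            max_missing_days = 1, day_offset_hours = 0) {
  stopifnot(daily_max_km > 0, min_attempt_days > 0, success_days > 0,
            min_attempt_days < success_days, cluster_radius_km > 0)
  structure(list(window_start = window_start, window_end = window_end,
                 daily_max_km = daily_max_km,
                 min_attempt_days = min_attempt_days,
                 success_days = success_days,
                 cluster_radius_km = cluster_radius_km,
                 site_fidelity_prop = site_fidelity_prop,
                 capital_prenest_days = capital_prenest_days,
                 max_missing_days = max_missing_days,
                 day_offset_hours = day_offset_hours),
            class = "breeding_config")
}

breeding_window <- function(timestamps, cfg) {
  yr <- lubridate::year(timestamps[1])
  start <- lubridate::ymd(paste0(yr, "-", cfg$window_start), tz = "UTC")
  end <- lubridate::ymd(paste0(yr, "-", cfg$window_end), tz = "UTC")
  list(start = start, end = end)
}

#' Daily movement totals over the breeding window
#'
#' Per calendar day (UTC unless offset): the summed length of
#' within-day steps (an overnight relocation is caught by the
#' displacement diagnostic and the site-fidelity check, not the total),
#' the largest displacement of any fix from the previous day's last
#' fix, and the fix count. Days without fixes appear flagged `missing`
#' (not as zero distance).
#'
#' @param fixes Fix tibble for one individual.
#' @param cfg A [breeding_config()].
#' @return Tibble: `date`, `total_km`, `max_displacement_km`,
#'   `fix_count`, `missing`.
#' @export
daily_movement <- function(fixes, cfg = breeding_config()) {
  assert_fixes(fixes)
  if (length(unique(fixes$individual_id)) > 1) {
    abort("daily_movement: one individual at a time")
  }
  w <- breeding_window(fixes$timestamp, cfg)
  ts <- fixes$timestamp + cfg$day_offset_hours * 3600
  keep <- ts >= w$start & ts < w$end + 86400
  df <- fixes[keep, , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble(date = as.Date(character()), total_km = double(),
                  max_displacement_km = double(), fix_count = integer(),
                  missing = logical()))
  }
  day <- as.Date(ts[keep], tz = "UTC")
  n <- nrow(df)
  step <- c(NA_real_,
            haversine_km(df$lon[-n], df$lat[-n], df$lon[-1], df$lat[-1]))
  # only within-day steps count toward the daily total; overnight
  # relocations are instead caught by the displacement diagnostic and
  # the site-fidelity check in detect_attempt()
  step[c(TRUE, day[-1] != day[-n])] <- NA_real_
  daily <- tibble(day = day, step = step) |>
    group_by(date = day) |>
    summarise(total_km = sum(.data$step, na.rm = TRUE),
              fix_count = n(), .groups = "drop")
  anchors <- tibble(day = day, lon = df$lon, lat = df$lat) |>
    group_by(.data$day) |>
    summarise(last_lon = dplyr::last(.data$lon),
              last_lat = dplyr::last(.data$lat), .groups = "drop")
  disp <- tibble(day = day, lon = df$lon, lat = df$lat) |>
    left_join(anchors |> mutate(day = .data$day + 1),
              by = "day") |>
    group_by(date = .data$day) |>
    summarise(max_displacement_km = if (all(is.na(.data$last_lon))) NA_real_
              else max(haversine_km(.data$last_lon, .data$last_lat,
                                    .data$lon, .data$lat)),
              .groups = "drop")
  all_days <- tibble(date = seq(as.Date(w$start), as.Date(w$end), by = "day"))
  all_days |>
    left_join(daily, by = "date") |>
    left_join(disp, by = "date") |>
    mutate(missing = is.na(.data$fix_count),
           fix_count = coalesce(.data$fix_count, 0L))
}

# candidate quiet runs over the daily series, allowing short missing-day
# bridges flanked by qualifying days
quiet_runs <- function(daily, cfg) {
  quiet <- !daily$missing & daily$total_km <= cfg$daily_max_km
  n <- length(quiet)
  status <- ifelse(daily$missing, "m", ifelse(quiet, "q", "x"))
  runs <- list()
  i <- 1
  while (i <= n) {
    if (status[i] != "q") { i <- i + 1; next }
    j <- i
    last_q <- i
    gap <- 0
    while (j < n) {
      nxt <- status[j + 1]
      if (nxt == "q") { j <- j + 1; last_q <- j; gap <- 0 }
      else if (nxt == "m" && gap < cfg$max_missing_days) { j <- j + 1; gap <- gap + 1 }
      else break
    }
    runs[[length(runs) + 1]] <- c(start = i, end = last_q)
    i <- last_q + 1
  }
  runs
}

#' Detect a nesting attempt from daily movement
#'
#' Finds the longest run of consecutive quiet days (daily total at or
#' below `daily_max_km`) whose fixes also pass the site-fidelity check:
#' at least `site_fidelity_prop` of the run's fixes within
#' `cluster_radius_km` of the run's median coordinate. Up to
#' `max_missing_days` consecutive missing days inside a run neither
#' break nor extend it. An attempt is a qualifying run of at least
#' `min_attempt_days`.
#'
#' @param daily Output of [daily_movement()].
#' @param fixes The individual's fix tibble (site-fidelity check).
#' @param cfg A [breeding_config()].
#' @param longest_run Keep the longest qualifying run (default); `FALSE`
#'   selects the first qualifying run instead.
#' @return One-row tibble: `attempt`, `incubation_start` (Date),
#'   `incubation_start_ordinal`, `run_days`, `nest_lon`, `nest_lat`.
#' @export
detect_attempt <- function(daily, fixes, cfg = breeding_config(),
                           longest_run = TRUE) {
  none <- tibble(attempt = FALSE, incubation_start = as.Date(NA),
                 incubation_start_ordinal = NA_integer_,
                 run_days = 0L, nest_lon = NA_real_, nest_lat = NA_real_)
  if (nrow(daily) == 0) return(none)
  runs <- quiet_runs(daily, cfg)
  if (length(runs) == 0) return(none)
  ts_day <- as.Date(fixes$timestamp + cfg$day_offset_hours * 3600, tz = "UTC")
  qualify <- function(run) {
    d0 <- daily$date[run["start"]]; d1 <- daily$date[run["end"]]
    in_run <- ts_day >= d0 & ts_day <= d1
    if (sum(in_run) == 0) return(NULL)
    mlon <- median(fixes$lon[in_run]); mlat <- median(fixes$lat[in_run])
    r <- haversine_km(mlon, mlat, fixes$lon[in_run], fixes$lat[in_run])
    if (mean(r <= cfg$cluster_radius_km) < cfg$site_fidelity_prop) return(NULL)
    list(run = run, lon = mlon, lat = mlat,
         days = as.integer(d1 - d0 + 1))
  }
  cands <- Filter(Negate(is.null), lapply(runs, qualify))
  if (length(cands) == 0) return(none)
  lens <- vapply(cands, function(c) c$days, integer(1))
  best <- if (longest_run) cands[[which.max(lens)]] else {
    ok <- which(lens >= cfg$min_attempt_days)
    if (length(ok) == 0) cands[[which.max(lens)]] else cands[[ok[1]]]
  }
  if (best$days < cfg$min_attempt_days) return(none)
  start_date <- daily$date[best$run["start"]]
  tibble(attempt = TRUE, incubation_start = start_date,
         incubation_start_ordinal = lubridate::yday(start_date),
         run_days = best$days, nest_lon = best$lon, nest_lat = best$lat)
}

#' Classify a detected attempt as success or failure
#'
#' Success means the incubation quiet run lasted at least `success_days`
#' (default 23); monotone in the run length by construction. Failures
#' during egg laying are undetectable by design: classification starts
#' only once an incubation signature exists.
#'
#' @param run_days Quiet-run length in days.
#' @param cfg A [breeding_config()].
#' @return `"success"` or `"fail"`.
#' @export
classify_outcome <- function(run_days, cfg = breeding_config()) {
  if (any(is.na(run_days)) || any(run_days < cfg$min_attempt_days)) {
    abort("classify_outcome: only call on detected attempts")
  }
  ifelse(run_days >= cfg$success_days, "success", "fail")
}

#' Assemble breeding records with phenology and strategy class
#'
#' Joins attempt detections to arrival dates: pre-nesting duration is
#' incubation start minus arrival (days); strategy is capital-leaning
#' when pre-nesting is strictly under `capital_prenest_days`, else
#' income-leaning. Non-attempters get the cohort median incubation start
#' of attempters in the same year as their trajectory endpoint (lower
#' median on even counts).
#'
#' @param attempts Tibble with one row per individual: `individual_id`,
#'   `attempt`, `incubation_start_ordinal`, `run_days` (from
#'   [detect_attempt()]), plus a `year` column.
#' @param arrivals Tibble `individual_id`, `arrival_ordinal`.
#' @param cfg A [breeding_config()].
#' @return Breeding-record tibble: adds `outcome`, `pre_nesting_days`,
#'   `strategy`, `endpoint_ordinal`.
#' @export
phenology <- function(attempts, arrivals, cfg = breeding_config()) {
  rec <- attempts |>
    left_join(arrivals, by = "individual_id")
  bad <- rec$attempt & !is.na(rec$arrival_ordinal) &
    rec$incubation_start_ordinal < rec$arrival_ordinal
  if (any(bad, na.rm = TRUE)) {
    abort(paste0("incubation before arrival for individual(s): ",
                 paste(rec$individual_id[which(bad)], collapse = ", ")))
  }
  lower_median <- function(x) {
    x <- sort(x)
    if (length(x) == 0) return(NA_integer_)
    x[ceiling(length(x) / 2)]
  }
  med <- rec |>
    filter(.data$attempt) |>
    group_by(.data$year) |>
    summarise(median_start = lower_median(.data$incubation_start_ordinal),
              .groups = "drop")
  rec |>
    left_join(med, by = "year") |>
    mutate(
      outcome = ifelse(.data$attempt,
                       ifelse(.data$run_days >= cfg$success_days,
                              "success", "fail"),
                       "none"),
      pre_nesting_days = ifelse(.data$attempt,
                                .data$incubation_start_ordinal -
                                  .data$arrival_ordinal, NA_integer_),
      strategy = ifelse(.data$attempt,
                        ifelse(.data$pre_nesting_days <
                                 cfg$capital_prenest_days,
                               "capital-leaning", "income-leaning"),
                        NA_character_),
      endpoint_ordinal = ifelse(.data$attempt,
                                .data$incubation_start_ordinal,
                                .data$median_start)
    ) |>
    select(-"median_start")
}

#' Classify breeding for a set of individuals
#'
#' Convenience wrapper: runs [daily_movement()] and [detect_attempt()]
#' per individual and [phenology()] across the cohort.
#'
#' @param fixes Fix tibble (several individuals).
#' @param arrivals Tibble `individual_id`, `arrival_ordinal` (e.g. from
#'   [summarize_migration()]).
#' @param cfg A [breeding_config()].
#' @return Breeding-record tibble, one row per individual.
#' @export
classify_breeding <- function(fixes, arrivals, cfg = breeding_config()) {
  assert_fixes(fixes)
  attempts <- fixes |>
    group_by(.data$individual_id) |>
    group_modify(function(df, key) {
      df$individual_id <- key$individual_id
      daily <- daily_movement(df, cfg)
      det <- detect_attempt(daily, df, cfg)
      det$year <- lubridate::year(df$timestamp[1])
      det
    }) |>
    ungroup()
  phenology(attempts, arrivals, cfg)
}

#' Cohort attempt and success rates
#'
#' @param records Breeding-record tibble (needs `attempt` and `outcome`).
#' @return One-row tibble: `n`, `n_attempt`, `n_success`, `attempt_pct`,
#'   `success_pct` (success among attempters), on the percentage scale.
#' @export
breeding_rates <- function(records) {
  n <- nrow(records)
  na <- sum(records$attempt)
  ns <- sum(records$outcome == "success")
  tibble(n = n, n_attempt = na, n_success = ns,
         attempt_pct = 100 * na / n,
         success_pct = if (na > 0) 100 * ns / na else NA_real_)
}

#' Pool regional attempt rates into an overall percentage
#'
#' Reconstructs integer attempt counts from per-region percentages and
#' sample sizes (rounding to the nearest count) and pools them; useful
#' for aggregating published regional summaries.
#'
#' @param n Per-region sample sizes.
#' @param attempt_pct Per-region attempt percentages.
#' @return Pooled attempt percentage.
#' @export
pool_attempt_rates <- function(n, attempt_pct) {
  counts <- round(attempt_pct / 100 * n)
  100 * sum(counts) / sum(n)
}
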