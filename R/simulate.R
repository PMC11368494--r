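# Synthetic goose-track generator: multi-phase spring trajectories
# (winter residence, northward migration with stopovers and occasional
# reverse flights, pre-nesting, incubation/deferral) with
# state-dependent gamma step lengths and von Mises headings, GPS noise,
# and a ground-truth ledger for every planted quantity.

#' Simulation configuration
#'
#' The `"goose2019"` preset targets the movement magnitudes of
#' midcontinent greater white-fronted goose spring migration: ~93-day
#' migrations of ~5450 km with ~16 stopovers, migratory steps averaging
#' 32.3 km per 30-min fix, occasional latitude-reversing flights, and a
#' breeding cohort in which about 55% attempt nesting and about 71% of
#' attempters succeed (>= 23 incubation days).
#'
#' @param preset Currently `"goose2019"`.
#' @param ... Overrides for any preset field.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(preset = "goose2019", ...) {
  cfg <- list(
    year = 2019,
    fix_interval_min = 30,
    gps_noise_m = 8,
    start_date = "02-01",
    end_date = "08-01",
    onset_window = c("02-10", "02-28"),
    onset_hour = 10,
    # per-state gamma step (km per fix) and von Mises heading-change kappa
    states = list(
      roost = list(mean = 0.05, sd = 0.04, kappa = 0),
      forage = list(mean = 0.17, sd = 0.15, kappa = 0),
      localflight = list(mean = 3.0, sd = 2.2, kappa = 1),
      migratory = list(mean = 32.3, sd = 8.0, kappa = 50)
    ),
    localflight_prob = 0.02,   # per daytime fix during residence phases
    roost_hours = c(21, 5),    # local night: roost between these hours
    winter_regions = list(
      MAV = c(lon = -90.7, lat = 34.5),
      `Chenier Plain` = c(lon = -92.8, lat = 29.8),
      `Rolling/High Plains` = c(lon = -100.5, lat = 33.5),
      Other = c(lon = -97.0, lat = 36.0)
    ),
    winter_mix = c(MAV = 5, `Chenier Plain` = 24,
                   `Rolling/High Plains` = 8, Other = 19) / 56,
    destinations = list(
      western = c(lon = -152, lat = 68.5),
      eastern = c(lon = -96, lat = 66.5)
    ),
    eastern_prob = 29 / 56,
    n_stopovers_mean = 15.7, n_stopovers_min = 4,
    duration_days_mean = 93, duration_days_sd = 10,
    duration_days_range = c(70, 115),
    reverse_mean = 0.9, reverse_max = 4,
    reverse_length_km = c(80, 150),
    route_jitter_km = 40,
    attempt_prob = 31 / 56,      # 55.4% of the cohort attempts
    success_prob = 22 / 31,      # 71.0% of attempters succeeds
    fail_run_days = c(7, 22),
    success_run_days = c(23, 28),
    prenest_days_range = c(4, 28), prenest_days_mean = 15.6,
    nest_jitter_m = 5,
    dropout_rate = 0
  )
  if (!identical(preset, "goose2019")) abort("unknown preset")
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "sim_config")
}

# vectorized von Mises sampler (Best & Fisher rejection, batched)
rvm_vec <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  mu <- rep_len(mu, n); kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-6
  out[unif] <- runif(sum(unif), -pi, pi)
  todo <- which(!unif)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  while (length(todo) > 0) {
    m <- length(todo)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r[todo] * z) / (r[todo] + z)
    cc <- kappa[todo] * (r[todo] - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    idx <- todo[acc]
    out[idx] <- sign(u3[acc] - 0.5) * acos(pmax(pmin(f[acc], 1), -1))
    todo <- todo[!acc]
  }
  wrap_angle(out + mu)
}

rgamma_ms <- function(n, mean, sd) {
  rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

# residence-phase step block: roost at night, forage by day with
# occasional local flights; headings are a von Mises random walk
residence_block <- function(n, hours, cfg, label) {
  st <- cfg$states
  night <- hours >= cfg$roost_hours[1] | hours < cfg$roost_hours[2]
  state <- ifelse(night, "roost", "forage")
  day_idx <- which(!night)
  lf <- day_idx[runif(length(day_idx)) < cfg$localflight_prob]
  state[lf] <- "localflight"
  mean <- vapply(st[state], function(s) s$mean, double(1))
  sd <- vapply(st[state], function(s) s$sd, double(1))
  kap <- vapply(st[state], function(s) s$kappa, double(1))
  list(len = rgamma_ms(n, mean, sd),
       turn = rvm_vec(n, 0, kap),
       state = state, phase = rep(label, n))
}

#' Draw breeding scenarios for a cohort
#'
#' @param cfg A [sim_config()].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Tibble: `scenario` (defer/fail/success), `run_days` (0 for
#'   defer), `prenest_days`.
#' @export
sim_scenarios <- function(cfg, n, seed = 1) {
  set.seed(seed %% 2147483647)
  attempt <- runif(n) < cfg$attempt_prob
  success <- runif(n) < cfg$success_prob
  scenario <- ifelse(!attempt, "defer", ifelse(success, "success", "fail"))
  run_days <- integer(n)
  run_days[scenario == "fail"] <-
    sample(cfg$fail_run_days[1]:cfg$fail_run_days[2],
           sum(scenario == "fail"), replace = TRUE)
  run_days[scenario == "success"] <-
    sample(cfg$success_run_days[1]:cfg$success_run_days[2],
           sum(scenario == "success"), replace = TRUE)
  pn <- round(rgamma_ms(n, cfg$prenest_days_mean, 6))
  pn <- pmin(pmax(pn, cfg$prenest_days_range[1]), cfg$prenest_days_range[2])
  tibble(scenario = scenario, run_days = run_days, prenest_days = pn)
}

#' Simulate one individual's spring trajectory
#'
#' Phases are emitted in order: winter residence, alternating migratory
#' flights and stopovers northward (with any reverse flights), the
#' pre-nesting locale, then scenario-dependent incubation or continued
#' deferral movement through 1 August. Positions accumulate by local
#' dead reckoning (valid at step scales far below the Earth radius) and
#' isotropic Gaussian GPS noise is added last. Deterministic given the
#' seed.
#'
#' @param cfg A [sim_config()].
#' @param id Individual identifier.
#' @param seed Integer seed.
#' @param scenario Optional row from [sim_scenarios()] (drawn from `cfg`
#'   when `NULL`).
#' @return List: `track` (fix tibble with `true_state` and `phase`
#'   columns) and `truth` (one-row ledger tibble).
#' @export
simulate_individual <- function(cfg, id = "G001", seed = 1, scenario = NULL) {
  set.seed(seed %% 2147483647)
  if (is.null(scenario)) {
    sc <- sim_scenarios(cfg, 1, seed = seed + 1)
  } else {
    sc <- scenario
  }
  yr <- cfg$year
  dt_min <- cfg$fix_interval_min
  t_start <- lubridate::ymd(paste0(yr, "-", cfg$start_date), tz = "UTC")
  t_end <- lubridate::ymd(paste0(yr, "-", cfg$end_date), tz = "UTC") + 86400
  onset_lo <- lubridate::ymd(paste0(yr, "-", cfg$onset_window[1]), tz = "UTC")
  onset_hi <- lubridate::ymd(paste0(yr, "-", cfg$onset_window[2]), tz = "UTC")
  onset_day <- onset_lo + runif(1) * as.numeric(onset_hi - onset_lo) * 86400
  onset <- lubridate::floor_date(onset_day, "day") + cfg$onset_hour * 3600
  winter_label <- sample(names(cfg$winter_mix), 1, prob = cfg$winter_mix)
  origin <- cfg$winter_regions[[winter_label]]
  dest_side <- if (runif(1) < cfg$eastern_prob) "eastern" else "western"
  dest <- cfg$destinations[[dest_side]]

  # route waypoints: great-circle intermediate points with lateral jitter
  n_stop <- max(cfg$n_stopovers_min, rpois(1, cfg$n_stopovers_mean))
  n_legs <- n_stop + 1
  gc <- geosphere::gcIntermediate(origin[c("lon", "lat")],
                                  dest[c("lon", "lat")], n = n_legs - 1,
                                  addStartEnd = TRUE)
  jit <- rnorm(n_legs - 1, 0, cfg$route_jitter_km)
  gc[2:n_legs, 1] <- gc[2:n_legs, 1] +
    jit / (111.195 * cos(gc[2:n_legs, 2] * pi / 180))
  route_km <- haversine_km(gc[-nrow(gc), 1], gc[-nrow(gc), 2],
                           gc[-1, 1], gc[-1, 2])
  bearings <- bearing_rad(gc[-nrow(gc), 1], gc[-nrow(gc), 2],
                          gc[-1, 1], gc[-1, 2])

  dur_days <- min(max(rnorm(1, cfg$duration_days_mean, cfg$duration_days_sd),
                      cfg$duration_days_range[1]), cfg$duration_days_range[2])
  mig <- cfg$states$migratory
  flight_hours_est <- sum(route_km) / mig$mean * dt_min / 60
  n_rev <- min(rpois(1, cfg$reverse_mean), cfg$reverse_max, n_legs - 2)
  rev_after <- if (n_rev > 0) sort(sample(seq_len(n_legs - 1), n_rev)) else integer(0)
  stop_hours_total <- max(dur_days * 24 - flight_hours_est, (n_stop + n_rev) * 12)
  stop_w <- rgamma(n_stop + n_rev, shape = 2)
  stop_fix <- pmax(24, round(stop_hours_total * (stop_w / sum(stop_w)) * 60 /
                               dt_min))

  blocks <- list()
  push <- function(b) blocks[[length(blocks) + 1]] <<- b

  # winter residence from track start until onset
  n_winter <- round(as.numeric(difftime(onset, t_start, units = "mins")) / dt_min)
  hrs <- (as.numeric(t_start - lubridate::floor_date(t_start, "day")) / 3600 +
            (seq_len(n_winter) - 1) * dt_min / 60) %% 24
  push(residence_block(n_winter, hrs, cfg, "winter"))

  flight_block <- function(leg_km, brg) {
    n_est <- ceiling(leg_km / mig$mean * 1.6) + 4
    len <- rgamma_ms(n_est, mig$mean, mig$sd)
    n_fly <- which(cumsum(len) >= leg_km)[1]
    if (is.na(n_fly)) n_fly <- n_est
    len <- len[seq_len(n_fly)]
    wig <- rvm_vec(n_fly, 0, mig$kappa)
    list(len = len, turn = wig, state = rep("migratory", n_fly),
         phase = rep("flight", n_fly), heading = brg + wig)
  }

  stop_count <- 0
  for (leg in seq_len(n_legs)) {
    push(flight_block(route_km[leg], bearings[leg]))
    if (leg < n_legs) {
      stop_count <- stop_count + 1
      n_sf <- stop_fix[stop_count]
      push(residence_block(n_sf, rep(0:47, length.out = n_sf) / 2, cfg,
                           "stopover"))
      if (leg %in% rev_after) {
        rl <- runif(1, cfg$reverse_length_km[1], cfg$reverse_length_km[2])
        push(flight_block(rl, pi + rnorm(1, 0, 0.15)))
        stop_count <- stop_count + 1
        n_sf <- stop_fix[stop_count]
        push(residence_block(n_sf, rep(0:47, length.out = n_sf) / 2, cfg,
                             "stopover"))
        # recover the reverse distance on the next leg
        route_km[leg + 1] <- route_km[leg + 1] + rl
      }
    }
  }

  # ---- assemble steps, then positions ----
  len <- unlist(lapply(blocks, `[[`, "len"))
  state <- unlist(lapply(blocks, `[[`, "state"))
  phase <- unlist(lapply(blocks, `[[`, "phase"))
  heading <- numeric(length(len))
  at <- 0
  h_prev <- runif(1, -pi, pi)
  for (b in blocks) {
    nb <- length(b$len)
    if (!is.null(b$heading)) {
      heading[at + seq_len(nb)] <- b$heading
      h_prev <- b$heading[nb]
    } else {
      h <- h_prev + cumsum(b$turn)
      heading[at + seq_len(nb)] <- h
      h_prev <- h[nb]
    }
    at <- at + nb
  }

  n_mig_end <- length(len)  # last flown step index = arrival
  arrival <- t_start + n_mig_end * dt_min * 60
  arrival_date <- lubridate::floor_date(arrival, "day")

  # pre-nesting / deferral / incubation through the end date
  incub_start <- NA
  if (sc$scenario != "defer") {
    incub_start <- arrival_date + sc$prenest_days * 86400
    latest <- lubridate::ymd(paste0(yr, "-07-01"), tz = "UTC")
    if (incub_start > latest) incub_start <- latest
    n_pre <- round(as.numeric(difftime(incub_start, arrival,
                                       units = "mins")) / dt_min)
  } else {
    n_pre <- round(as.numeric(difftime(t_end, arrival, units = "mins")) / dt_min)
  }
  hrs0 <- (as.numeric(arrival - lubridate::floor_date(arrival, "day")) / 3600 +
             (seq_len(max(n_pre, 0)) - 1) * dt_min / 60) %% 24
  if (n_pre > 0) push(residence_block(
    n_pre, hrs0, cfg, if (sc$scenario == "defer") "defer" else "prenest"))
  n_inc <- 0
  if (sc$scenario != "defer") {
    n_inc <- sc$run_days * 24 * 60 / dt_min
    push(list(len = rep(0, n_inc), turn = rep(0, n_inc),
              state = rep("nest", n_inc), phase = rep("incubation", n_inc)))
    t_after <- incub_start + sc$run_days * 86400
    n_post <- round(as.numeric(difftime(t_end, t_after, units = "mins")) / dt_min)
    hrs1 <- ((seq_len(max(n_post, 0)) - 1) * dt_min / 60) %% 24
    if (n_post > 0) push(residence_block(n_post, hrs1, cfg, "post"))
  }

  # rebuild full vectors (blocks grew after the flight assembly)
  len <- unlist(lapply(blocks, `[[`, "len"))
  state <- unlist(lapply(blocks, `[[`, "state"))
  phase <- unlist(lapply(blocks, `[[`, "phase"))
  n_steps <- length(len)
  heading2 <- numeric(n_steps)
  heading2[seq_len(n_mig_end)] <- heading
  at <- n_mig_end
  h_prev <- heading[n_mig_end]
  for (b in blocks[-seq_len(which(cumsum(vapply(blocks, function(x)
    length(x$len), integer(1))) == n_mig_end)[1])]) {
    nb <- length(b$len)
    h <- h_prev + cumsum(b$turn)
    heading2[at + seq_len(nb)] <- h
    h_prev <- h[nb]
    at <- at + nb
  }

  # dead reckoning: km displacements, then lon/lat
  dx <- len * sin(heading2)
  dy <- len * cos(heading2)
  # pin incubation steps to the nest (zero step already ensures this)
  lat <- origin[["lat"]] + cumsum(c(0, dy)) / 111.195
  lon_scale <- 111.195 * cos(pmin(pmax(lat, -89), 89) * pi / 180)
  lon <- origin[["lon"]] + cumsum(c(0, dx) / lon_scale)
  n_fix <- n_steps + 1
  ts <- t_start + (seq_len(n_fix) - 1) * dt_min * 60

  # incubation jitter around the nest
  nest_lon <- NA_real_; nest_lat <- NA_real_
  if (n_inc > 0) {
    inc_fix <- which(phase == "incubation") + 1
    nest_lon <- lon[inc_fix[1]]; nest_lat <- lat[inc_fix[1]]
    jr <- cfg$nest_jitter_m / 1000
    lat[inc_fix] <- nest_lat + rnorm(n_inc, 0, jr) / 111.195
    lon[inc_fix] <- nest_lon + rnorm(n_inc, 0, jr) /
      (111.195 * cos(nest_lat * pi / 180))
  }

  # GPS noise
  if (cfg$gps_noise_m > 0) {
    nk <- cfg$gps_noise_m / 1000
    lat <- lat + rnorm(n_fix, 0, nk) / 111.195
    lon <- lon + rnorm(n_fix, 0, nk) / (111.195 * cos(lat * pi / 180))
  }

  speed <- c(len / (dt_min / 60), 0)
  track <- tibble(
    individual_id = id, timestamp = ts, lon = lon, lat = lat,
    hdop = NA_real_, ground_speed = speed,
    true_state = c(state[1], state), phase = c(phase[1], phase)
  )
  if (cfg$dropout_rate > 0) {
    keep <- runif(n_fix) > cfg$dropout_rate
    keep[1] <- TRUE
    track <- track[keep, , drop = FALSE]
  }
  truth <- tibble(
    individual_id = id,
    winter_region = winter_label,
    destination = dest_side,
    onset_time = onset,
    n_stopovers_mid = n_stop + n_rev,
    n_reverse = n_rev,
    arrival_time = arrival,
    arrival_ordinal = lubridate::yday(arrival),
    scenario = sc$scenario,
    attempt = sc$scenario != "defer",
    incubation_start = if (sc$scenario == "defer") as.Date(NA)
      else as.Date(incub_start),
    run_days = sc$run_days,
    outcome = switch(sc$scenario, defer = "none", fail = "fail",
                     success = "success"),
    prenest_days = if (sc$scenario == "defer") NA_real_ else
      as.numeric(as.Date(incub_start) - as.Date(arrival_date)),
    nest_lon = nest_lon, nest_lat = nest_lat
  )
  list(track = track, truth = truth)
}

#' Simulate a population of tracked individuals
#'
#' Each individual gets an independent substream derived from the seed,
#' so any subset reproduces bit-identically.
#'
#' @param cfg A [sim_config()].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return List: `tracks` (stacked fix tibble), `truth` (one row per
#'   individual).
#' @export
simulate_population <- function(cfg, n, seed = 1) {
  stopifnot(n >= 1)
  scen <- sim_scenarios(cfg, n, seed = seed)
  sims <- purrr::map(seq_len(n), function(i) {
    simulate_individual(cfg, id = sprintf("G%03d", i),
                        seed = substream_seed(seed, i),
                        scenario = scen[i, , drop = FALSE])
  })
  list(tracks = list_rbind(purrr::map(sims, "track")),
       truth = list_rbind(purrr::map(sims, "truth")))
}
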