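# daily-movement nesting signatures

# fixes for a sequence of daily behaviors: "quiet" days jitter within
# meters of a site; "move" days walk ~20 km; "gap" days have no fixes
behavior_track <- function(days, start_date = "2019-06-01", lon0 = -100,
                           lat0 = 66, site_step_m = 10, id = "hen") {
  ts <- c(); lon <- c(); lat <- c()
  cur_lon <- lon0; cur_lat <- lat0
  t0 <- ts_utc(paste(start_date, "00:00:00"))
  for (d in seq_along(days)) {
    if (days[d] == "gap") next
    tt <- t0 + (d - 1) * 86400 + (0:47) * 1800
    if (days[d] == "quiet") {
      lo <- cur_lon + rnorm(48, 0, site_step_m / 1000 / 111.195)
      la <- cur_lat + rnorm(48, 0, site_step_m / 1000 / 111.195)
    } else if (days[d] == "move") {
      la <- cur_lat + cumsum(rep(0.2 / 48, 48))
      lo <- cur_lon + rnorm(48, 0, 1e-5)
      cur_lat <- la[48]
    } else if (startsWith(days[d], "jump")) {
      # relocate by the stated km at the first step, then sit quiet
      km <- as.numeric(sub("jump", "", days[d]))
      cur_lon <- cur_lon + km / (111.195 * cos(cur_lat * pi / 180))
      lo <- cur_lon + rnorm(48, 0, site_step_m / 1000 / 111.195)
      la <- cur_lat + rnorm(48, 0, site_step_m / 1000 / 111.195)
    }
    ts <- c(ts, tt); lon <- c(lon, lo); lat <- c(lat, la)
  }
  tibble(individual_id = id, timestamp = lubridate::as_datetime(ts, tz = "UTC"),
         lon = lon, lat = lat, hdop = NA_real_, ground_speed = NA_real_)
}

test_that("daily movement totals distinguish quiet, moving and missing days", {
  set.seed(1)
  tr <- behavior_track(c("quiet", "move", "gap", "quiet"))
  d <- daily_movement(tr)
  jun <- d[d$date >= as.Date("2019-06-01") & d$date <= as.Date("2019-06-04"), ]
  expect_lt(jun$total_km[1], 2)
  expect_gte(jun$total_km[2], 20)
  expect_true(jun$missing[3])
  expect_false(jun$missing[4])
  # days before the track are flagged missing, not zero
  expect_true(all(d$missing[d$date < as.Date("2019-06-01")]))
})

test_that("attempts need six quiet days at a single site", {
  set.seed(2)
  cfg <- breeding_config()
  # a planted 27-day signature is found exactly
  tr <- behavior_track(c("move", rep("quiet", 27), "move"))
  det <- detect_attempt(daily_movement(tr, cfg), tr, cfg)
  expect_true(det$attempt)
  expect_equal(det$incubation_start, as.Date("2019-06-02"))
  expect_equal(det$run_days, 27)
  # the moving first day ends 0.2 degrees north of the start point
  expect_lt(haversine_km(det$nest_lon, det$nest_lat, -100, 66.2), 0.05)

  # five quiet days then departure: no attempt
  tr2 <- behavior_track(c("move", rep("quiet", 5), "move", "move"))
  det2 <- detect_attempt(daily_movement(tr2, cfg), tr2, cfg)
  expect_false(det2$attempt)

  # eight quiet days split across two sites 5 km apart: site fidelity fails
  set.seed(3)
  tr3 <- behavior_track(c("move", rep("quiet", 4), "gap", "jump5",
                          rep("quiet", 3), "move"))
  det3 <- detect_attempt(daily_movement(tr3, cfg), tr3, cfg)
  expect_false(det3$attempt)

  # one missing day inside a run neither breaks nor extends it
  set.seed(4)
  tr4 <- behavior_track(c("move", rep("quiet", 4), "gap", rep("quiet", 4),
                          "move"))
  det4 <- detect_attempt(daily_movement(tr4, cfg), tr4, cfg)
  expect_true(det4$attempt)
  expect_equal(det4$run_days, 9)
})

test_that("outcome classification is the 23-day rule and is monotone", {
  cfg <- breeding_config()
  expect_equal(classify_outcome(23, cfg), "success")
  expect_equal(classify_outcome(14, cfg), "fail")
  expect_equal(classify_outcome(6, cfg), "fail")
  runs <- 6:30
  out <- classify_outcome(runs, cfg)
  expect_true(all(diff(out == "success") >= 0))  # monotone in run length
  expect_error(classify_outcome(3, cfg), "attempts")
})

test_that("phenology derives pre-nesting duration and strategy class", {
  attempts <- tibble(
    individual_id = c("a", "b", "c", "d"),
    attempt = c(TRUE, TRUE, TRUE, FALSE),
    incubation_start_ordinal = c(158L, 150L, 160L, NA),
    run_days = c(24L, 10L, 25L, 0L),
    year = 2019)
  arrivals <- tibble(individual_id = c("a", "b", "c", "d"),
                     arrival_ordinal = c(134L, 141L, 150L, 140L))
  rec <- phenology(attempts, arrivals)
  a <- rec[rec$individual_id == "a", ]
  expect_equal(a$pre_nesting_days, 24)
  expect_equal(a$strategy, "income-leaning")
  b <- rec[rec$individual_id == "b", ]
  expect_equal(b$pre_nesting_days, 9)
  expect_equal(b$strategy, "capital-leaning")
  c_ <- rec[rec$individual_id == "c", ]
  expect_equal(c_$pre_nesting_days, 10)
  expect_equal(c_$strategy, "income-leaning")  # boundary: strict <
  # non-attempter endpoint: lower median of {158, 150, 160} = 158
  d_ <- rec[rec$individual_id == "d", ]
  expect_equal(d_$endpoint_ordinal, 158)
  expect_equal(d_$outcome, "none")

  bad <- attempts
  bad$incubation_start_ordinal[1] <- 120L
  expect_error(phenology(bad, arrivals), "incubation before arrival")
})

test_that("cohort and pooled rate arithmetic", {
  rec <- tibble(attempt = c(rep(TRUE, 31), rep(FALSE, 25)),
                outcome = c(rep("success", 22), rep("fail", 9),
                            rep("none", 25)))
  rates <- breeding_rates(rec)
  expect_equal(rates$attempt_pct, 100 * 31 / 56)
  expect_equal(rates$success_pct, 100 * 22 / 31)
  # pooling regional rates recovers the overall percentage
  expect_equal(pool_attempt_rates(c(10, 20), c(50, 50)), 50)
})
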