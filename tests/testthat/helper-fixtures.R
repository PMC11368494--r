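# Fixtures and independent oracles used across the suite. Everything is
# generated in code; nothing is read from disk except temp files the
# tests themselves write.

suppressMessages({
  library(dplyr)
  library(tibble)
})

ts_utc <- function(x) lubridate::ymd_hms(x, tz = "UTC")

# minimal fix tibble from coordinate vectors
make_fixes <- function(lon, lat, start = "2019-03-01 00:00:00",
                       interval_min = 30, id = "bird1", hdop = NA_real_,
                       speed = NA_real_) {
  n <- length(lon)
  tibble(individual_id = id,
         timestamp = ts_utc(start) + (seq_len(n) - 1) * interval_min * 60,
         lon = lon, lat = lat,
         hdop = rep_len(hdop, n), ground_speed = rep_len(speed, n))
}

# the four-state structure used for parameter-recovery checks: slow and
# tortuous residence states against a fast, straight migratory state
four_state_truth <- function() {
  as_mig_hmm(
    gamma = tibble(state = 1:4, mean = c(0.05, 0.35, 3, 32.3),
                   sd = c(0.04, 0.3, 2.2, 8)),
    vonmises = tibble(state = 1:4, mean = 0, kappa = c(0.2, 0.5, 1, 15)),
    trans_a = matrix(c(0, -2.2, -3, -4,
                       -2.2, 0, -2.5, -3.5,
                       -3, -2.5, 0, -2.2,
                       -4, -3.5, -2.2, 0), 4, 4, byrow = TRUE),
    delta = c(0.4, 0.4, 0.15, 0.05))
}

two_state_truth <- function(kappa = c(0.3, 8)) {
  as_mig_hmm(
    gamma = tibble(state = 1:2, mean = c(0.2, 30), sd = c(0.15, 9)),
    vonmises = tibble(state = 1:2, mean = 0, kappa = kappa),
    trans_a = matrix(c(0, -2.5, -2.5, 0), 2, 2, byrow = TRUE),
    delta = c(0.8, 0.2))
}

# random small HMM for exhaustive Viterbi checks
random_hmm <- function(k, seed) {
  set.seed(seed)
  as_mig_hmm(
    gamma = tibble(state = seq_len(k),
                   mean = sort(exp(runif(k, -2, 3))),
                   sd = exp(runif(k, -2, 1))),
    vonmises = tibble(state = seq_len(k), mean = runif(k, -pi, pi),
                      kappa = exp(runif(k, -2, 1.5))),
    trans_a = matrix(rnorm(k * k, -1.5, 0.8), k, k) * (1 - diag(k)),
    delta = { d <- runif(k) + 0.1; d / sum(d) })
}

# ---- independent oracles --------------------------------------------------

# exhaustive-path Viterbi: joint log-probability of every state path,
# computed from first principles (gamma + von Mises densities, softmax
# transitions), independent of the package's recursions
brute_viterbi <- function(model, steps) {
  k <- model$n_states
  n <- nrow(steps)
  dens <- function(j, x, ang) {
    mu <- model$gamma$mean[j]; sdv <- model$gamma$sd[j]
    shape <- (mu / sdv)^2; rate <- mu / sdv^2
    ld <- dgamma(x, shape = shape, rate = rate, log = TRUE)
    if (!is.na(ang)) {
      kap <- model$vonmises$kappa[j]
      ld <- ld + kap * cos(ang - model$vonmises$mean[j]) -
        log(2 * pi * besselI(kap, 0))
    }
    ld
  }
  tm <- function() {
    e <- exp(model$trans_a - apply(model$trans_a, 1, max))
    log(e / rowSums(e))
  }
  lt <- tm()
  lobs <- sapply(seq_len(k), function(j)
    vapply(seq_len(n), function(t) dens(j, steps$step_km[t],
                                        steps$angle_rad[t]), double(1)))
  lobs <- matrix(lobs, n, k)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  lp <- log(model$delta)[paths[, 1]] + lobs[cbind(1, paths[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      lp <- lp + lt[cbind(paths[, t - 1], paths[, t])] +
        lobs[cbind(t, paths[, t])]
    }
  }
  best <- max(lp)
  cand <- which(lp > best - 1e-12)
  # lexicographically smallest maximizer mirrors lowest-index tie-breaks
  paths[cand[order(apply(paths[cand, , drop = FALSE], 1, paste,
                         collapse = ""))[1]], ]
}

# Newton-Raphson logistic MLE, independent of glm
newton_logit <- function(y, X, tol = 1e-12, maxit = 200) {
  X <- cbind(1, X)
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    g <- crossprod(X, y - p)
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  drop(b)
}

# temp GeoJSON FeatureCollection of lon/lat boxes
write_region_geojson <- function(boxes, path = tempfile(fileext = ".geojson")) {
  feats <- lapply(names(boxes), function(nm) {
    b <- boxes[[nm]]  # c(lon_min, lat_min, lon_max, lat_max)
    ring <- list(c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]),
                 c(b[1], b[4]), c(b[1], b[2]))
    list(type = "Feature", properties = list(region = nm),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# hand-built UD on an explicit grid (values given south-up)
make_ud <- function(values, xmin = 0, ymin = 0, cell_km = sqrt(10),
                    proj = albers_proj()) {
  grid <- list(xmin = xmin, ymin = ymin, ncol = ncol(values),
               nrow = nrow(values), cell_km = cell_km, proj = proj,
               projection = proj$label)
  migtrack:::new_mig_ud(values / sum(values), grid)
}

# Brownian track with known motion variance (km^2/h) around a lon/lat
# anchor, with GPS noise err (km)
make_brownian_track <- function(n, sigma2, dt_h = 0.5, err = 0.008,
                                seed = 1, lon0 = -95, lat0 = 45,
                                id = "bb") {
  set.seed(seed)
  dx <- rnorm(n - 1, 0, sqrt(sigma2 * dt_h))
  dy <- rnorm(n - 1, 0, sqrt(sigma2 * dt_h))
  x <- cumsum(c(0, dx)) + rnorm(n, 0, err)
  y <- cumsum(c(0, dy)) + rnorm(n, 0, err)
  make_fixes(lon = lon0 + x / (111.195 * cos(lat0 * pi / 180)),
             lat = lat0 + y / 111.195, interval_min = dt_h * 60, id = id)
}

# cached simulated cohorts shared across test files (built once per run)
.pop_cache <- new.env(parent = emptyenv())
cached_population <- function(n, seed, noiseless = FALSE) {
  key <- paste0("p", n, "_", seed, "_", noiseless)
  if (is.null(.pop_cache[[key]])) {
    cfg <- if (noiseless) sim_config(gps_noise_m = 0) else sim_config()
    .pop_cache[[key]] <- simulate_population(cfg, n, seed = seed)
  }
  .pop_cache[[key]]
}
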