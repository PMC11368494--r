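# Dynamic Brownian bridge movement model: sliding-window motion-variance
# estimation, bridge-integrated utilization distributions on an
# equal-area grid, day weighting, composites, isopleths, and regional
# area accounting.

new_mig_ud <- function(values, grid) {
  structure(list(values = values, grid = grid), class = "mig_ud")
}

#' @export
print.mig_ud <- function(x, ...) {
  cat("Utilization distribution:", x$grid$nrow, "x", x$grid$ncol,
      "cells of", format(x$grid$cell_km^2, digits = 4), "km^2, mass",
      format(sum(x$values), digits = 10), "\n")
  invisible(x)
}

#' Build a UD grid specification over a set of fixes
#'
#' Equal-area grid with 10 km^2 cells by default; the origin is snapped
#' to multiples of the cell size in projected coordinates so repeated
#' runs land on identical grids.
#'
#' @param fixes Fix tibble (any number of individuals).
#' @param proj An [albers_proj()].
#' @param cell_km Cell edge, km (default `sqrt(10)` for 10 km^2 cells).
#' @param buffer_km Margin added around the fix extent.
#' @return Grid list used by [compute_ud()].
#' @export
ud_grid_spec <- function(fixes, proj = albers_proj(), cell_km = sqrt(10),
                         buffer_km = 30) {
  xy <- project_xy(proj, fixes$lon, fixes$lat)
  xmin <- floor((min(xy[, 1]) - buffer_km) / cell_km) * cell_km
  ymin <- floor((min(xy[, 2]) - buffer_km) / cell_km) * cell_km
  ncol <- ceiling((max(xy[, 1]) + buffer_km - xmin) / cell_km)
  nrow <- ceiling((max(xy[, 2]) + buffer_km - ymin) / cell_km)
  list(xmin = xmin, ymin = ymin, ncol = ncol, nrow = nrow,
       cell_km = cell_km, proj = proj, projection = proj$label)
}

grid_cell_index <- function(grid, x, y) {
  ix <- floor((x - grid$xmin) / grid$cell_km) + 1
  iy <- floor((y - grid$ymin) / grid$cell_km) + 1
  ok <- ix >= 1 & ix <= grid$ncol & iy >= 1 & iy <= grid$nrow
  cbind(ix = ifelse(ok, ix, NA_integer_), iy = ifelse(ok, iy, NA_integer_))
}

# Per-fix leave-one-out bridge statistics: for each interior fix j,
# predicting j from the bridge between j-1 and j+1 gives a Gaussian with
# variance sigma2 * w_j + c_j and squared planar residual d2_j. These
# triplet statistics do not depend on the window, so they are computed
# once per track.
bb_triplet_stats <- function(tt, xy, err_km) {
  n <- length(tt)
  j <- seq(2, n - 1)
  Tj <- tt[j + 1] - tt[j - 1]
  a <- (tt[j] - tt[j - 1]) / Tj
  mx <- xy[j - 1, 1] + a * (xy[j + 1, 1] - xy[j - 1, 1])
  my <- xy[j - 1, 2] + a * (xy[j + 1, 2] - xy[j - 1, 2])
  list(idx = j,
       w = Tj * a * (1 - a),
       c = ((1 - a)^2 + a^2) * err_km^2,
       d2 = (xy[j, 1] - mx)^2 + (xy[j, 2] - my)^2)
}

# isotropic bivariate normal LOO log-likelihood at motion variance s2
bb_loo_loglik <- function(s2, w, cc, d2) {
  v <- s2 * w + cc
  sum(-log(2 * pi * v) - d2 / (2 * v))
}

bb_mle_sigma2 <- function(stats, sel) {
  if (length(sel) == 0) return(list(sigma2 = NA_real_, nll = NA_real_))
  w <- stats$w[sel]; cc <- stats$c[sel]; d2 <- stats$d2[sel]
  opt <- optimize(function(ls) -bb_loo_loglik(exp(ls), w, cc, d2),
                  interval = c(log(1e-10), log(1e5)), tol = 1e-4)
  list(sigma2 = exp(opt$minimum), nll = opt$objective)
}

#' Estimate the dynamic Brownian motion variance along a track
#'
#' Sliding-window estimation: within each window of `window` fixes,
#' candidate single breakpoints outside the margins are compared against
#' a no-break model by BIC on the leave-one-out likelihood of
#' odd-indexed fixes, and the Brownian motion variance is the
#' maximum-likelihood estimate for the selected piece(s). Each
#' between-fix interval inherits the mean of the estimates from windows
#' whose interior covers it. Tracks shorter than one window fall back to
#' a single global estimate (with a warning).
#'
#' @param fixes Fix tibble for one individual, time-ordered.
#' @param window Window size in fixes (odd; default 25).
#' @param margin Margin in fixes (default 9).
#' @param location_error_m Telemetry error standard deviation (default
#'   8 m).
#' @param proj Projection used for the planar bridge likelihood.
#' @return A tibble with one row per interval: `interval`,
#'   `sigma2_km2h` (km^2 per hour).
#' @export
estimate_dynamic_variance <- function(fixes, window = 25, margin = 9,
                                      location_error_m = 8,
                                      proj = albers_proj()) {
  stopifnot(window %% 2 == 1, window > 2 * margin)
  n <- nrow(fixes)
  err_km <- location_error_m / 1000
  xy <- project_xy(proj, fixes$lon, fixes$lat)
  tt <- as.numeric(difftime(fixes$timestamp, fixes$timestamp[1],
                            units = "hours"))
  n_int <- n - 1
  tri <- bb_triplet_stats(tt, xy, err_km)
  if (n < window) {
    warn("estimate_dynamic_variance: track shorter than one window; using a global estimate")
    sel <- which(tri$idx %% 2 == 0)
    s2 <- bb_mle_sigma2(tri, sel)$sigma2
    return(tibble(interval = seq_len(n_int), sigma2_km2h = s2))
  }
  acc <- numeric(n_int)
  cnt <- numeric(n_int)
  loo_local <- seq(2, window - 1, by = 2)  # odd-indexed interior fixes
  for (i in seq_len(n - window + 1)) {
    # global fix index of local position p is i + p - 1; triplet row is
    # that global index minus 1
    sel_all <- i + loo_local - 2
    no_break <- bb_mle_sigma2(tri, sel_all)
    n_obs <- length(sel_all)
    best <- list(bic = 2 * no_break$nll + 1 * log(n_obs), breaks = NULL,
                 s2 = c(no_break$sigma2, no_break$sigma2))
    for (b in (margin + 1):(window - margin)) {
      left <- sel_all[loo_local < b]
      right <- sel_all[loo_local > b]
      if (length(left) == 0 || length(right) == 0) next
      fl <- bb_mle_sigma2(tri, left)
      fr <- bb_mle_sigma2(tri, right)
      bic <- 2 * (fl$nll + fr$nll) + 2 * log(n_obs)
      if (bic < best$bic) best <- list(bic = bic, breaks = b,
                                       s2 = c(fl$sigma2, fr$sigma2))
    }
    interior <- (i + margin - 1):(i + window - margin - 1)  # interval indices
    if (is.null(best$breaks)) {
      acc[interior] <- acc[interior] + best$s2[1]
    } else {
      g <- i + best$breaks - 1  # global fix index of the break
      lo <- interior[interior < g]
      hi <- interior[interior >= g]
      acc[lo] <- acc[lo] + best$s2[1]
      acc[hi] <- acc[hi] + best$s2[2]
    }
    cnt[interior] <- cnt[interior] + 1
  }
  s2 <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  # track edges outside any window interior take the nearest estimate
  if (anyNA(s2)) {
    filled <- which(!is.na(s2))
    s2[is.na(s2)] <- s2[filled[pmax(1, findInterval(which(is.na(s2)), filled))]]
    s2 <- zoo_fill(s2)
  }
  tibble(interval = seq_len(n_int), sigma2_km2h = s2)
}

# nearest-neighbour NA fill (both directions)
zoo_fill <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  for (i in which(is.na(x))) {
    x[i] <- x[idx[which.min(abs(idx - i))]]
  }
  x
}

#' Compute a dynamic Brownian bridge utilization distribution
#'
#' The UD is the duration-weighted average over between-fix intervals of
#' the Brownian-bridge position density (isotropic Gaussian with
#' variance `sigma2 * T * a * (1 - a)` plus telemetry-error terms),
#' integrated along each bridge with `quadrature` midpoint nodes. Cell
#' masses use exact separable Gaussian cell integrals. The result is
#' normalized to total mass 1.
#'
#' @param fixes Fix tibble (one individual).
#' @param variances Output of [estimate_dynamic_variance()].
#' @param grid Grid from [ud_grid_spec()] (built from the fixes when
#'   `NULL`).
#' @param quadrature Midpoint nodes per bridge (at least 10; the
#'   default 50 keeps the along-track discretization error below 1e-4
#'   of total mass per cell).
#' @param location_error_m Telemetry error sd (m).
#' @param sigma_cutoff Gaussian support truncation, in standard
#'   deviations.
#' @return A `mig_ud`.
#' @export
compute_ud <- function(fixes, variances, grid = NULL, quadrature = 50,
                       location_error_m = 8, sigma_cutoff = 5) {
  if (is.null(grid)) grid <- ud_grid_spec(fixes)
  err_km <- location_error_m / 1000
  xy <- project_xy(grid$proj, fixes$lon, fixes$lat)
  tt <- as.numeric(difftime(fixes$timestamp, fixes$timestamp[1],
                            units = "hours"))
  vals <- matrix(0, grid$nrow, grid$ncol)
  xcent <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cell_km
  ycent <- grid$ymin + (seq_len(grid$nrow) - 0.5) * grid$cell_km
  n <- nrow(fixes)
  for (i in seq_len(n - 1)) {
    Tt <- tt[i + 1] - tt[i]
    if (Tt <= 0) next
    s2 <- variances$sigma2_km2h[i]
    w <- Tt / quadrature
    for (q in seq_len(quadrature)) {
      a <- (q - 0.5) / quadrature
      mx <- xy[i, 1] + a * (xy[i + 1, 1] - xy[i, 1])
      my <- xy[i, 2] + a * (xy[i + 1, 2] - xy[i, 2])
      v <- s2 * Tt * a * (1 - a) + ((1 - a)^2 + a^2) * err_km^2
      sdv <- sqrt(v)
      r <- sigma_cutoff * sdv + grid$cell_km
      ix <- which(abs(xcent - mx) <= r)
      iy <- which(abs(ycent - my) <= r)
      if (length(ix) == 0 || length(iy) == 0) next
      px <- stats::pnorm(grid$xmin + ix * grid$cell_km, mx, sdv) -
        stats::pnorm(grid$xmin + (ix - 1) * grid$cell_km, mx, sdv)
      py <- stats::pnorm(grid$ymin + iy * grid$cell_km, my, sdv) -
        stats::pnorm(grid$ymin + (iy - 1) * grid$cell_km, my, sdv)
      vals[iy, ix] <- vals[iy, ix] + w * outer(py, px)
    }
  }
  total <- sum(vals)
  if (total <= 0) abort("compute_ud: degenerate track, UD has zero mass")
  new_mig_ud(vals / total, grid)
}

#' Weight a UD by days of use per cell
#'
#' Each cell's mass is multiplied by the number of distinct calendar
#' days (UTC) on which the individual had at least one fix in the cell;
#' cells carrying bridge mass but no fixes instead get a time-share
#' weight (total tracking days times the cell's share of UD mass, i.e.
#' the model's own estimate of residence time there). The result is
#' renormalized.
#'
#' @param ud A `mig_ud` for the individual.
#' @param fixes The individual's fix tibble (same period as the UD).
#' @return A reweighted, renormalized `mig_ud`.
#' @export
weight_by_days <- function(ud, fixes) {
  grid <- ud$grid
  xy <- project_xy(grid$proj, fixes$lon, fixes$lat)
  ci <- grid_cell_index(grid, xy[, 1], xy[, 2])
  day <- as.Date(fixes$timestamp, tz = "UTC")
  ok <- !is.na(ci[, 1])
  dd <- tibble(ix = ci[ok, 1], iy = ci[ok, 2], day = day[ok]) |>
    distinct() |>
    count(.data$ix, .data$iy, name = "days")
  wts <- matrix(0, grid$nrow, grid$ncol)
  total_days <- length(unique(day))
  has_mass <- ud$values > 0
  wts[has_mass] <- total_days * ud$values[has_mass] / sum(ud$values)
  wts[cbind(dd$iy, dd$ix)] <- dd$days
  vals <- ud$values * wts
  total <- sum(vals)
  if (total <= 0) abort("weight_by_days: all mass removed by weighting")
  new_mig_ud(vals / total, grid)
}

#' Composite several UDs on a shared grid
#'
#' Cellwise sum of the individual (already normalized, day-weighted)
#' UDs, renormalized so the composite sums to 1.
#'
#' @param uds List of `mig_ud` on identical grids.
#' @return A `mig_ud`.
#' @export
composite_ud <- function(uds) {
  stopifnot(length(uds) >= 1)
  g0 <- uds[[1]]$grid
  for (u in uds[-1]) {
    g <- u$grid
    if (g$ncol != g0$ncol || g$nrow != g0$nrow ||
        abs(g$xmin - g0$xmin) > 1e-9 || abs(g$ymin - g0$ymin) > 1e-9 ||
        abs(g$cell_km - g0$cell_km) > 1e-12) {
      abort("composite_ud: grids are not aligned")
    }
  }
  vals <- Reduce(`+`, lapply(uds, function(u) u$values))
  new_mig_ud(vals / sum(vals), g0)
}

#' Extract probability-level isopleth cell sets
#'
#' For each level the mask is the smallest cell set whose probability
#' mass reaches the level: cells are taken in decreasing order of mass
#' until the cumulative probability first reaches the level. Ties at
#' the cut are broken deterministically by cell index, so masks are
#' exactly minimal and nested by construction.
#'
#' @param ud A normalized `mig_ud`.
#' @param levels Probability levels (defaults 0.50-0.99 as used for
#'   high/moderate-use mapping).
#' @return A `mig_iso`: list with `levels`, `masks` (logical matrices)
#'   and the grid.
#' @export
isopleths <- function(ud, levels = c(0.50, 0.60, 0.70, 0.80, 0.90, 0.99)) {
  v <- as.vector(ud$values)
  ord <- order(v, decreasing = TRUE)  # stable: ties fall to lower index
  cum <- cumsum(v[ord])
  n_pos <- sum(v > 0)
  masks <- lapply(levels, function(lv) {
    m <- which(cum >= lv - 1e-12)[1]
    if (is.na(m)) m <- n_pos
    m <- min(m, n_pos)
    mask <- rep(FALSE, length(v))
    mask[ord[seq_len(m)]] <- TRUE
    matrix(mask, nrow(ud$values), ncol(ud$values))
  })
  structure(list(levels = levels, masks = setNames(masks, format(levels)),
                 grid = ud$grid), class = "mig_iso")
}

#' Extract one level's mask from an isopleth set
#' @param iso A `mig_iso`.
#' @param level A probability level present in `iso$levels`.
#' @return Logical matrix over the grid.
#' @export
iso_mask <- function(iso, level) {
  i <- which(abs(iso$levels - level) < 1e-9)
  if (length(i) == 0) abort(paste0("isopleth level ", level, " not available"))
  iso$masks[[i]]
}

#' Test whether points fall in an isopleth mask
#' @param iso A `mig_iso`.
#' @param level Probability level present in `iso`.
#' @param lon,lat Point coordinates (degrees).
#' @return Logical vector.
#' @export
iso_contains <- function(iso, level, lon, lat) {
  mask <- iso_mask(iso, level)
  xy <- project_xy(iso$grid$proj, lon, lat)
  ci <- grid_cell_index(iso$grid, xy[, 1], xy[, 2])
  out <- rep(FALSE, length(lon))
  ok <- !is.na(ci[, 1])
  out[ok] <- mask[cbind(ci[ok, 2], ci[ok, 1])]
  out
}

#' Regional accounting of high- and moderate-use areas
#'
#' High use is the 50% isopleth; moderate use is the 60%-80% band,
#' interpreted as the 80% mask minus the high-use mask (so high plus
#' moderate equals the 80% mask; set `moderate_base = 0.6` for the
#' narrower 80%-minus-60% alternative). Cells with centroids at or above
#' `lat_cutoff_deg` are excluded (breeding-area movements, not
#' migration). Areas are cell counts times the cell area; cells in no
#' region polygon go to an `Unassigned` row which counts toward totals
#' and percentages but is not ranked.
#'
#' @param iso A `mig_iso` containing the 0.5 and 0.8 (and, if used, 0.6)
#'   levels.
#' @param regions A `mig_regions` (may be empty).
#' @param lat_cutoff_deg Northern latitude cutoff (default 60).
#' @param moderate_base Lower mask subtracted from the 80% mask.
#' @return A `region_use_table` tibble; see [region_use_table()].
#' @export
region_areas <- function(iso, regions, lat_cutoff_deg = 60,
                         moderate_base = 0.5) {
  grid <- iso$grid
  cell_area <- grid$cell_km^2
  high <- iso_mask(iso, 0.5)
  mod <- iso_mask(iso, 0.8) & !iso_mask(iso, moderate_base)
  cell_regions <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(character(0))
    x <- grid$xmin + (idx[, 2] - 0.5) * grid$cell_km
    y <- grid$ymin + (idx[, 1] - 0.5) * grid$cell_km
    ll <- unproject_xy(grid$proj, x, y)
    keep <- ll[, 2] < lat_cutoff_deg
    if (sum(keep) == 0) return(character(0))
    if (length(regions) == 0) return(rep("Unassigned", sum(keep)))
    region_of(regions, ll[keep, 1], ll[keep, 2], other = "Unassigned")
  }
  hi <- table(cell_regions(high))
  mo <- table(cell_regions(mod))
  all_regions <- union(names(regions), union(names(hi), names(mo)))
  if (length(all_regions) == 0) all_regions <- "Unassigned"
  count_for <- function(tab, nms) {
    v <- as.numeric(tab[nms])
    v[is.na(v)] <- 0
    v
  }
  df <- tibble(
    region = all_regions,
    high_km2 = count_for(hi, all_regions) * cell_area,
    moderate_km2 = count_for(mo, all_regions) * cell_area
  )
  region_use_table(df)
}

#' Percent-of-total and ranking logic for regional use areas
#'
#' Adds combined areas, percentages of the respective category totals,
#' and dense descending ranks to a per-region area table. Percentages
#' are relative to the full total including any `Unassigned` row;
#' `Unassigned` itself is never ranked.
#'
#' @param df Tibble with `region`, `high_km2`, `moderate_km2` (an
#'   `Unassigned` row may carry area outside named regions).
#' @return Tibble of class `region_use_table` with `combined_km2`,
#'   `*_pct` and `*_rank` columns; totals available via [glance()].
#' @export
region_use_table <- function(df) {
  stopifnot(all(c("region", "high_km2", "moderate_km2") %in% names(df)))
  df <- df |>
    mutate(combined_km2 = .data$high_km2 + .data$moderate_km2)
  tot_h <- sum(df$high_km2); tot_m <- sum(df$moderate_km2)
  tot_c <- sum(df$combined_km2)
  dense_rank_desc <- function(x, rankable) {
    r <- rep(NA_integer_, length(x))
    vals <- sort(unique(x[rankable & x > 0]), decreasing = TRUE)
    r[rankable & x > 0] <- match(x[rankable & x > 0], vals)
    r
  }
  rankable <- df$region != "Unassigned"
  out <- df |>
    mutate(
      high_pct = if (tot_h > 0) 100 * .data$high_km2 / tot_h else 0,
      moderate_pct = if (tot_m > 0) 100 * .data$moderate_km2 / tot_m else 0,
      combined_pct = if (tot_c > 0) 100 * .data$combined_km2 / tot_c else 0,
      high_rank = dense_rank_desc(.data$high_km2, rankable),
      moderate_rank = dense_rank_desc(.data$moderate_km2, rankable),
      combined_rank = dense_rank_desc(.data$combined_km2, rankable)
    ) |>
    arrange(desc(.data$combined_km2))
  attr(out, "totals") <- tibble(high_km2 = tot_h, moderate_km2 = tot_m,
                                combined_km2 = tot_c)
  class(out) <- c("region_use_table", class(out))
  out
}

#' @export
glance.region_use_table <- function(x, ...) {
  attr(x, "totals")
}
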