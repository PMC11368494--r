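test_that("motion variance is recovered on pure Brownian tracks", {
  est <- vapply(1:20, function(s) {
    tr <- make_brownian_track(200, sigma2 = 4, seed = s)
    median(estimate_dynamic_variance(tr)$sigma2_km2h)
  }, double(1))
  expect_lt(abs(median(est) - 4) / 4, 0.25)
})

test_that("a stationary jittered track estimates variance near zero", {
  set.seed(2)
  tr <- make_fixes(lon = -95 + rnorm(120, 0, 0.008 / 88.8),
                   lat = 45 + rnorm(120, 0, 0.008 / 111.195))
  v <- estimate_dynamic_variance(tr)
  expect_lt(median(v$sigma2_km2h), 0.01)
})

test_that("a planted variance change shows up in the profile", {
  set.seed(6)
  lo <- make_brownian_track(150, sigma2 = 0.3, seed = 10)
  hi <- make_brownian_track(151, sigma2 = 12, seed = 11)
  hi$lon <- hi$lon - hi$lon[1] + lo$lon[150]
  hi$lat <- hi$lat - hi$lat[1] + lo$lat[150]
  hi$timestamp <- lo$timestamp[150] + seq_len(151) * 1800
  tr <- bind_rows(lo, hi[-1, ])
  v <- estimate_dynamic_variance(tr)$sigma2_km2h
  expect_lt(mean(v[1:120]), mean(v[180:299]))
  expect_gt(mean(v[180:299]) / mean(v[1:120]), 5)
})

test_that("short tracks fall back to a global estimate with a warning", {
  tr <- make_brownian_track(12, sigma2 = 2, seed = 4)
  expect_warning(v <- estimate_dynamic_variance(tr), "global")
  expect_equal(length(unique(v$sigma2_km2h)), 1)
})

test_that("bridge UDs conserve mass and concentrate appropriately", {
  # two coincident fixes: nearly all mass in the containing cell
  proj <- albers_proj()
  xy <- project_xy(proj, -95, 45)
  cell <- sqrt(10)
  grid <- list(xmin = xy[1] - cell / 2, ymin = xy[2] - cell / 2,
               ncol = 5, nrow = 5, cell_km = cell, proj = proj,
               projection = proj$label)
  grid$xmin <- grid$xmin - 2 * cell
  grid$ymin <- grid$ymin - 2 * cell
  tr <- make_fixes(lon = c(-95, -95), lat = c(45, 45))
  v <- tibble(interval = 1, sigma2_km2h = 0)
  ud <- compute_ud(tr, v, grid = grid)
  expect_equal(sum(ud$values), 1, tolerance = 1e-9)
  expect_gt(ud$values[3, 3], 0.99)

  # straight two-fix bridge: mass stays in a 3-cell-wide corridor
  tr2 <- make_fixes(lon = c(-95, -95), lat = c(45, 45 + 20 / 111.195))
  n_across <- 9
  xy2 <- project_xy(proj, tr2$lon, tr2$lat)
  grid2 <- list(xmin = mean(xy2[, 1]) - n_across / 2 * cell,
                ymin = min(xy2[, 2]) - 3 * cell,
                ncol = n_across, nrow = ceiling(20 / cell) + 6,
                cell_km = cell, proj = proj, projection = proj$label)
  ud2 <- compute_ud(tr2, tibble(interval = 1, sigma2_km2h = 0.5),
                    grid = grid2)
  mid <- ceiling(n_across / 2)
  corridor <- ud2$values[, (mid - 1):(mid + 1)]
  expect_lt(1 - sum(corridor), 0.01)

  # doubling the default quadrature barely moves any cell
  tr3 <- make_brownian_track(40, sigma2 = 3, seed = 9)
  v3 <- estimate_dynamic_variance(tr3)
  u50 <- compute_ud(tr3, v3)
  u100 <- compute_ud(tr3, v3, quadrature = 100)
  expect_lt(max(abs(u50$values - u100$values)), 1e-4)
})

test_that("day weighting is monotone and proportional to fix-days", {
  proj <- albers_proj()
  # two cells of equal prior mass; 10 fix-days in one, 1 in the other
  vals <- matrix(0, 3, 3)
  vals[2, 1] <- 0.5; vals[2, 3] <- 0.5
  ud <- make_ud(vals, xmin = 0, ymin = 0, proj = proj)
  cell <- ud$grid$cell_km
  c1 <- unproject_xy(proj, 0.5 * cell, 1.5 * cell)
  c2 <- unproject_xy(proj, 2.5 * cell, 1.5 * cell)
  fixes <- bind_rows(
    make_fixes(lon = rep(c1[1], 10), lat = rep(c1[2], 10),
               start = "2019-05-01 06:00:00", interval_min = 1440),
    make_fixes(lon = c2[1], lat = c2[2], start = "2019-05-11 06:00:00"))
  w <- weight_by_days(ud, fixes)
  expect_equal(sum(w$values), 1, tolerance = 1e-12)
  expect_equal(w$values[2, 1] / w$values[2, 3], 10, tolerance = 1e-9)

  # all days in one cell: that cell's relative mass strictly increases
  ud2 <- make_ud(matrix(c(0.6, 0.4), 1, 2), proj = proj)
  f2 <- make_fixes(lon = unproject_xy(proj, 0.5 * cell, 0.5 * cell)[1],
                   lat = unproject_xy(proj, 0.5 * cell, 0.5 * cell)[2])
  w2 <- weight_by_days(ud2, f2)
  expect_gt(w2$values[1, 1], 0.6)
})

test_that("composites sum aligned grids and renormalize", {
  a <- make_ud(matrix(c(1, 0, 0, 0), 2, 2))
  b <- make_ud(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(composite_ud(list(a))$values, a$values)
  comp <- composite_ud(list(a, b))
  expect_equal(sum(comp$values[a$values > 0]), 0.5)
  expect_equal(sum(comp$values), 1, tolerance = 1e-12)
  # N identical inputs change nothing
  expect_equal(composite_ud(list(a, a, a))$values, a$values)
  off <- make_ud(matrix(1, 2, 2), xmin = 100)
  expect_error(composite_ud(list(a, off)), "aligned")
})

test_that("isopleths take the smallest cell sets at each level and nest", {
  u <- make_ud(matrix(0.25, 2, 2))
  iso <- isopleths(u, levels = 0.5)
  expect_equal(sum(iso_mask(iso, 0.5)), 2)

  single <- make_ud(matrix(c(1, 0, 0, 0), 2, 2))
  iso1 <- isopleths(single)
  for (lv in iso1$levels) expect_equal(sum(iso_mask(iso1, lv)), 1)

  set.seed(12)
  for (r in 1:20) {
    u2 <- make_ud(matrix(runif(100), 10, 10))
    iso2 <- isopleths(u2, levels = c(0.5, 0.9))
    m <- iso_mask(iso2, 0.9)
    expect_gte(sum(u2$values[m]), 0.9)
    # minimality: dropping the smallest included cell dips below level
    vals <- sort(u2$values[m])
    expect_lt(sum(u2$values[m]) - vals[1], 0.9)
    expect_true(all(m[iso_mask(iso2, 0.5)]))
  }
})

test_that("regional accounting splits, ranks and respects the 60 N cutoff", {
  proj <- albers_proj()
  # high-use (50%) mask of exactly 4 cells in row 1, split 3:1 between
  # two regions; the remaining mass is spread thinly so no other cell
  # enters the mask
  vals <- matrix(0.049, 2, 7)
  vals[1, 1:4] <- c(0.2, 0.15, 0.1, 0.06)
  ud <- make_ud(vals, xmin = 0, ymin = 0, proj = proj)
  iso <- isopleths(ud, levels = c(0.5, 0.6, 0.8))
  expect_equal(sum(iso_mask(iso, 0.5)), 4)
  cell <- ud$grid$cell_km
  cen <- unproject_xy(proj, (seq_len(4) - 0.5) * cell, rep(0.5 * cell, 4))
  west <- c(min(cen[1:3, 1]) - 0.01, min(cen[1:3, 2]) - 0.01,
            max(cen[1:3, 1]) + 0.01, max(cen[1:3, 2]) + 0.01)
  east <- c(cen[4, 1] - 0.01, cen[4, 2] - 0.01,
            cen[4, 1] + 0.01, cen[4, 2] + 0.01)
  regions <- read_regions(write_region_geojson(list(W = west, E = east)))
  tab <- region_areas(iso, regions)
  w <- tab[tab$region == "W", ]; e <- tab[tab$region == "E", ]
  expect_equal(w$high_pct, 75)
  expect_equal(e$high_pct, 25)
  expect_equal(w$high_rank, 1)
  expect_equal(e$high_rank, 2)
  expect_equal(w$high_km2, 3 * cell^2)

  # a single region holding the whole mask: 100%, rank 1
  all_box <- read_regions(write_region_geojson(list(
    All = c(-180, 0, 0, 80))))
  tab2 <- region_areas(iso, all_box)
  expect_equal(tab2$high_pct[tab2$region == "All"], 100)
  expect_equal(tab2$high_rank[tab2$region == "All"], 1)

  # cells with centroids at or beyond 60 N are excluded
  far_north <- make_fixes(lon = rep(-95, 2), lat = c(61, 61.01))
  xy <- project_xy(proj, far_north$lon, far_north$lat)
  gridN <- list(xmin = xy[1, 1] - cell / 2, ymin = xy[1, 2] - cell / 2,
                ncol = 3, nrow = 3, cell_km = cell, proj = proj,
                projection = proj$label)
  udN <- compute_ud(far_north, tibble(interval = 1, sigma2_km2h = 0),
                    grid = gridN)
  isoN <- isopleths(udN, levels = c(0.5, 0.8))
  tabN <- region_areas(isoN, all_box)
  expect_equal(sum(tabN$high_km2), 0)

  # empty region set still accounts areas under Unassigned
  tab3 <- region_areas(iso, structure(list(), class = "mig_regions"))
  expect_equal(tab3$region, "Unassigned")
  expect_equal(tab3$high_km2, 4 * cell^2)
  expect_equal(tab3$high_pct, 100)
})
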