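# Albers equal-area conic projection on the sphere. Equal-area mapping
# is required by the fixed 10 km^2 grid cells and the regional area
# accounting; the default parameters suit midcontinent North America.

#' Albers equal-area projection definition
#'
#' @param lat1,lat2 Standard parallels (degrees; defaults 20 and 60).
#' @param lon0 Central meridian (degrees).
#' @param lat0 Latitude of origin (degrees).
#' @return A list of class `mig_proj` with a `label` string recorded in
#'   raster output.
#' @export
albers_proj <- function(lat1 = 20, lat2 = 60, lon0 = -96, lat0 = 40) {
  d2r <- pi / 180
  n <- (sin(lat1 * d2r) + sin(lat2 * d2r)) / 2
  C <- cos(lat1 * d2r)^2 + 2 * n * sin(lat1 * d2r)
  rho0 <- EARTH_RADIUS_KM * sqrt(C - 2 * n * sin(lat0 * d2r)) / n
  structure(list(n = n, C = C, rho0 = rho0, lon0 = lon0,
                 label = sprintf(
                   "albers_sphere +lat_1=%g +lat_2=%g +lat_0=%g +lon_0=%g +R=%.4f km",
                   lat1, lat2, lat0, lon0, EARTH_RADIUS_KM)),
            class = "mig_proj")
}

#' Project lon/lat to equal-area x/y (km)
#' @param proj A [albers_proj()].
#' @param lon,lat Degrees.
#' @return Two-column matrix `x`, `y` in km.
#' @export
project_xy <- function(proj, lon, lat) {
  d2r <- pi / 180
  rho <- EARTH_RADIUS_KM * sqrt(proj$C - 2 * proj$n * sin(lat * d2r)) / proj$n
  theta <- proj$n * (lon - proj$lon0) * d2r
  cbind(x = rho * sin(theta), y = proj$rho0 - rho * cos(theta))
}

#' Inverse projection: x/y (km) to lon/lat (degrees)
#' @param proj A [albers_proj()].
#' @param x,y Projected coordinates in km.
#' @return Two-column matrix `lon`, `lat`.
#' @export
unproject_xy <- function(proj, x, y) {
  rho <- sqrt(x^2 + (proj$rho0 - y)^2)
  theta <- atan2(x, proj$rho0 - y)
  s <- (proj$C - (rho * proj$n / EARTH_RADIUS_KM)^2) / (2 * proj$n)
  lat <- asin(pmin(pmax(s, -1), 1)) * 180 / pi
  lon <- proj$lon0 + (theta / proj$n) * 180 / pi
  cbind(lon = lon, lat = lat)
}
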