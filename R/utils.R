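# Internal geometry and validation helpers shared across the pipeline.

#' Great-circle distance between fixes (km)
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Device error
#' (~8 m) dwarfs spheroid corrections at migration scales, so no
#' ellipsoidal correction is applied anywhere in the package.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial bearing between fixes (radians)
#' @noRd
bearing_rad <- function(lon1, lat1, lon2, lat2) {
  geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)) * pi / 180
}

# wrap angle to (-pi, pi]
wrap_angle <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

assert_fixes <- function(fixes, call = rlang::caller_env()) {
  needed <- c("individual_id", "timestamp", "lon", "lat")
  missing <- setdiff(needed, names(fixes))
  if (length(missing) > 0) {
    abort(paste0("fix table is missing column(s): ",
                 paste(missing, collapse = ", ")), call = call)
  }
  invisible(fixes)
}

# von Mises density; kappa = 0 reduces to the circular uniform
dvonmises <- function(x, mu, kappa) {
  if (kappa > 700) kappa <- 700  # besselI overflow guard
  exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0))
}

# log version, stable for large kappa
ldvonmises <- function(x, mu, kappa) {
  kappa * cos(x - mu) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
}

# deterministic per-individual substream seed, kept below 2^31
substream_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483399 + 1
}
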