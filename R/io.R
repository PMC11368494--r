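# Readers and writers for every external representation the pipeline
# touches: Movebank-style fix CSVs, per-step segment CSVs, utilization
# distributions as ESRI ASCII grids, and GeoJSON region polygons.

#' Default Movebank column mapping
#'
#' Maps the pipeline's canonical fix fields to Movebank export column
#' names. Override entries to load bespoke CSVs without code edits.
#'
#' @param individual_id,timestamp,lon,lat,hdop,ground_speed Column names
#'   in the source file. `hdop` and `ground_speed` may be `NA` when the
#'   file lacks them.
#' @return Named character vector used by [read_tracks()].
#' @export
#' @examples
#' movebank_columns(individual_id = "bird", timestamp = "time")
movebank_columns <- function(individual_id = "individual-local-identifier",
                             timestamp = "timestamp",
                             lon = "location-long",
                             lat = "location-lat",
                             hdop = "gps:hdop",
                             ground_speed = "ground-speed") {
  c(individual_id = individual_id, timestamp = timestamp, lon = lon,
    lat = lat, hdop = hdop, ground_speed = ground_speed)
}

#' Read GPS tracks from CSV
#'
#' Loads a fix table, normalizes timestamps to UTC (input offsets are
#' honored when present; offset-free stamps are assumed UTC), sorts each
#' individual by time, and collapses duplicate timestamps within an
#' individual to the first occurrence. The file order of individuals is
#' irrelevant: per-individual order is always by timestamp.
#'
#' @param path CSV file path.
#' @param column_map Named vector from [movebank_columns()].
#' @param nominal_interval Nominal fix interval in minutes (metadata only).
#' @return A tibble of fixes with columns `individual_id`, `timestamp`
#'   (POSIXct UTC), `lon`, `lat`, `hdop`, `ground_speed`, ordered by
#'   individual then time, with attribute `nominal_interval`.
#' @export
read_tracks <- function(path, column_map = movebank_columns(),
                        nominal_interval = 30) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  mandatory <- c("individual_id", "timestamp", "lon", "lat")
  for (field in mandatory) {
    if (!column_map[[field]] %in% names(raw)) {
      abort(paste0("mandatory column '", column_map[[field]],
                   "' (", field, ") not found in ", path))
    }
  }
  out <- tibble(
    individual_id = raw[[column_map[["individual_id"]]]],
    timestamp_raw = raw[[column_map[["timestamp"]]]],
    lon = as.numeric(raw[[column_map[["lon"]]]]),
    lat = as.numeric(raw[[column_map[["lat"]]]])
  )
  for (opt in c("hdop", "ground_speed")) {
    col <- column_map[[opt]]
    out[[opt]] <- if (!is.na(col) && col %in% names(raw)) {
      as.numeric(raw[[col]])
    } else {
      NA_real_
    }
  }
  # ISO-8601 (offsets honored, converted to UTC) with a fallback for
  # offset-free "Y-m-d H:M[:S]" stamps, which are taken as UTC
  ts <- suppressWarnings(readr::parse_datetime(out$timestamp_raw))
  retry <- which(is.na(ts))
  if (length(retry) > 0) {
    ts[retry] <- lubridate::parse_date_time(
      out$timestamp_raw[retry], orders = c("Ymd HMS", "Ymd HM"),
      tz = "UTC", quiet = TRUE)
  }
  attr(ts, "tzone") <- "UTC"
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    abort(paste0("unparseable timestamp at data row(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else ""))
  }
  out$timestamp <- ts
  bad_lat <- which(out$lat < -90 | out$lat > 90)
  bad_lon <- which(out$lon < -180 | out$lon > 180)
  if (length(c(bad_lat, bad_lon)) > 0) {
    abort(paste0("coordinate out of range at data row(s): ",
                 paste(head(sort(c(bad_lat, bad_lon)), 5), collapse = ", ")))
  }
  neg <- which(out$hdop < 0 | out$ground_speed < 0)
  if (length(neg) > 0) {
    abort(paste0("negative hdop/speed at data row(s): ",
                 paste(head(neg, 5), collapse = ", ")))
  }
  n_in <- nrow(out)
  out <- out |>
    select(-"timestamp_raw") |>
    arrange(.data$individual_id, .data$timestamp) |>
    distinct(.data$individual_id, .data$timestamp, .keep_all = TRUE) |>
    select("individual_id", "timestamp", "lon", "lat", "hdop", "ground_speed")
  dropped <- n_in - nrow(out)
  if (dropped > 0) {
    inform(paste0("read_tracks: collapsed ", dropped,
                  " duplicate-timestamp fix(es) to first occurrence"))
  }
  attr(out, "nominal_interval") <- nominal_interval
  out
}

#' Write per-step segment labels to CSV
#'
#' One row per step with the Viterbi state, flight/stopover role, segment
#' id and cumulative within-segment length; round-trips losslessly via
#' [read_segments()].
#'
#' @param segments A `mig_segments` object from [merge_segments()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  steps <- segment_steps(segments)
  readr::write_csv(steps, path, progress = FALSE)
  invisible(path)
}

#' Read a per-step segment CSV written by [write_segments()]
#' @param path CSV path.
#' @return Tibble of per-step rows.
#' @export
read_segments <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    individual_id = readr::col_character(),
                    role = readr::col_character(),
                    t_start = readr::col_datetime(),
                    t_end = readr::col_datetime(),
                    .default = readr::col_double())) |>
    mutate(t_start = lubridate::with_tz(.data$t_start, "UTC"),
           t_end = lubridate::with_tz(.data$t_end, "UTC"))
}

#' Write a utilization distribution as an ESRI ASCII grid
#'
#' Plain-text raster with the grid origin, cell size and projection
#' recorded; values are written with enough digits to round-trip to at
#' least six significant figures. The projection string is stored in a
#' sidecar `.prj`-style comment line accepted by [read_ud()].
#'
#' @param ud A `mig_ud` object (see [compute_ud()]).
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ud <- function(ud, path) {
  stopifnot(inherits(ud, "mig_ud"))
  if (any(!is.finite(ud$values))) abort("UD contains non-finite cell values")
  if (any(ud$values < 0)) abort("UD contains negative cell values")
  g <- ud$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$ncol),
    paste("nrows", g$nrow),
    paste("xllcorner", format(g$xmin, digits = 15)),
    paste("yllcorner", format(g$ymin, digits = 15)),
    paste("cellsize", format(g$cell_km, digits = 15)),
    "NODATA_value -9999"), con)
  # rows written north to south, per the ASCII grid convention
  for (r in g$nrow:1) {
    writeLines(paste(format(ud$values[r, ], digits = 9, scientific = TRUE,
                            trim = TRUE), collapse = " "), con)
  }
  writeLines(paste("# projection:", g$projection), con)
  invisible(path)
}

#' Read a utilization distribution from an ESRI ASCII grid
#' @param path Path written by [write_ud()].
#' @return A `mig_ud` object.
#' @export
read_ud <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  hv <- vapply(hdr, function(x) x[2], character(1))
  names(hv) <- tolower(vapply(hdr, function(x) x[1], character(1)))
  ncol <- as.integer(hv["ncols"]); nrow <- as.integer(hv["nrows"])
  proj_line <- grep("^# projection:", lines, value = TRUE)
  body <- lines[7:(6 + nrow)]
  vals <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  values <- vals[nrow:1, , drop = FALSE]  # back to south-up storage
  grid <- list(
    xmin = as.numeric(hv["xllcorner"]), ymin = as.numeric(hv["yllcorner"]),
    cell_km = as.numeric(hv["cellsize"]), ncol = ncol, nrow = nrow,
    projection = if (length(proj_line) > 0)
      sub("^# projection: ", "", proj_line[1]) else "unknown")
  new_mig_ud(values, grid)
}

#' Read region polygons from GeoJSON
#'
#' Parses a FeatureCollection of (Multi)Polygons in WGS84 into a named
#' list of boundary matrices suitable for point-in-region tests.
#'
#' @param path GeoJSON file path.
#' @param label_property Feature property holding the region label.
#' @return A `mig_regions` object: named list, one element per region,
#'   each a two-column lon/lat matrix with `NA` rows separating rings.
#' @export
read_regions <- function(path, label_property = "region") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) abort("GeoJSON is not a FeatureCollection")
  out <- list()
  for (f in gj$features) {
    label <- f$properties[[label_property]]
    if (is.null(label)) abort(paste0("feature lacks property '", label_property, "'"))
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      abort(paste0("unsupported geometry type: ", geom$type)))
    rings <- list()
    for (p in polys) for (ring in p) {
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      rings <- c(rings, list(m))
    }
    bnd <- do.call(rbind, lapply(seq_along(rings), function(i) {
      if (i == 1) rings[[i]] else rbind(c(NA, NA), rings[[i]])
    }))
    if (label %in% names(out)) abort(paste0("duplicate region label: ", label))
    out[[label]] <- bnd
  }
  structure(out, class = "mig_regions")
}

#' Locate points in regions
#'
#' @param regions A `mig_regions` object.
#' @param lon,lat Point coordinates (degrees).
#' @param other Label used for points in no region.
#' @return Character vector of region labels.
#' @export
region_of <- function(regions, lon, lat, other = "Other") {
  pts <- cbind(lon, lat)
  labels <- rep(other, nrow(pts))
  for (nm in names(regions)) {
    inside <- mgcv::in.out(regions[[nm]], pts)
    labels[inside & labels == other] <- nm
  }
  labels
}
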