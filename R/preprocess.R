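# Mean Earth radius, km.  All great-circle arithmetic in the package uses
# the spherical model; at the 10 km coastal-exclusion scale the sphere vs
# ellipsoid discrepancy (< 0.6 %) is immaterial.
EARTH_RADIUS_KM <- 6371.0

KM_PER_NM <- 1.852

#' Haversine great-circle distance
#'
#' Distance in km between two points on a sphere of radius 6371.0 km.
#' Vectorized over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees WGS84.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("coordinates out of bounds")
  p <- pi / 180
  dlat <- (lat2 - lat1) * p
  dlon <- (lon2 - lon1) * p
  a <- sin(dlat / 2)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Construct a shoreline object
#'
#' A shoreline is a set of coastal vertices used for minimum
#' distance-to-shore computation.  Unit 3-D vectors are precomputed so the
#' nearest vertex can be found by a chord-length scan (a monotone
#' transform of great-circle distance) instead of evaluating the haversine
#' at every vertex.
#'
#' @param lat,lon vertex coordinates, decimal degrees.
#' @return Object of class `shoreline`.
#' @export
as_shoreline <- function(lat, lon) {
  if (length(lat) == 0L) stop("shoreline must have at least one vertex")
  if (length(lat) != length(lon)) stop("lat and lon lengths differ")
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("shoreline vertex out of bounds")
  p <- pi / 180
  xyz <- cbind(cos(lat * p) * cos(lon * p),
               cos(lat * p) * sin(lon * p),
               sin(lat * p))
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon), xyz = xyz),
            class = "shoreline")
}

#' Load a shoreline vertex file
#'
#' Accepts (a) two-column delimited text with `lat`/`lon` columns (header
#' required) or (b) a GeoJSON FeatureCollection / geometry whose
#' Point, MultiPoint, LineString or MultiLineString vertices are extracted.
#'
#' @param path input file; format detected from content.
#' @return A [as_shoreline()] object.
#' @export
read_shoreline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*\\{", first)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    coords <- .geojson_vertices(gj)
    if (nrow(coords) == 0L) stop("no vertices found in GeoJSON: ", path)
    return(as_shoreline(coords[, 2], coords[, 1]))
  }
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  if (!all(c("lat", "lon") %in% names(df)))
    stop("shoreline table needs 'lat' and 'lon' columns")
  as_shoreline(df$lat, df$lon)
}

# Recursively pull (lon, lat) vertex pairs out of parsed GeoJSON.
.geojson_vertices <- function(node) {
  if (is.list(node) && !is.null(node$type)) {
    ty <- node$type
    if (ty == "FeatureCollection")
      return(do.call(rbind, lapply(node$features, .geojson_vertices)))
    if (ty == "Feature") return(.geojson_vertices(node$geometry))
    if (ty == "Point")
      return(matrix(unlist(node$coordinates)[1:2], ncol = 2))
    if (ty %in% c("MultiPoint", "LineString"))
      return(do.call(rbind, lapply(node$coordinates,
                                   function(c) unlist(c)[1:2])))
    if (ty == "MultiLineString")
      return(do.call(rbind, lapply(node$coordinates, function(line)
        do.call(rbind, lapply(line, function(c) unlist(c)[1:2])))))
  }
  matrix(numeric(0), ncol = 2)
}

#' Minimum distance from a point to the shoreline
#'
#' Vertex-based: the minimum over shoreline vertices of the haversine
#' distance.  The default indexed path locates the nearest vertex by
#' squared chord length in 3-D (monotone in central angle, hence the same
#' argmin) and returns the haversine distance to it; `method =
#' "exhaustive"` scans every vertex with the haversine directly.  Both
#' paths return the identical value.
#'
#' @param lat,lon query point, decimal degrees (vectorized).
#' @param shoreline a [as_shoreline()] object.
#' @param method `"indexed"` (chord-length scan) or `"exhaustive"`.
#' @return Distance(s) to the nearest shoreline vertex, km.
#' @export
distance_to_shore <- function(lat, lon, shoreline,
                              method = c("indexed", "exhaustive")) {
  method <- match.arg(method)
  if (!inherits(shoreline, "shoreline"))
    stop("shoreline must be built with as_shoreline()/read_shoreline()")
  if (method == "exhaustive") {
    return(vapply(seq_along(lat), function(i)
      min(haversine_km(lat[i], lon[i], shoreline$lat, shoreline$lon)),
      numeric(1)))
  }
  p <- pi / 180
  q <- cbind(cos(lat * p) * cos(lon * p),
             cos(lat * p) * sin(lon * p),
             sin(lat * p))
  dots <- q %*% t(shoreline$xyz)          # cos(central angle), n x m
  idx <- max.col(dots, ties.method = "first")
  haversine_km(lat, lon, shoreline$lat[idx], shoreline$lon[idx])
}

#' Solar elevation angle
#'
#' Low-precision solar position (fractional-year Fourier series for
#' declination and the equation of time, plus the local hour angle),
#' accurate to within a few minutes of sunrise/sunset timing at
#' non-polar latitudes.  No atmospheric refraction by default.
#'
#' @param lat,lon position, decimal degrees.
#' @param t POSIXct instant (UTC) or anything [as_track()] accepts.
#' @return Solar elevation above the horizon, degrees (vectorized).
#' @export
solar_elevation <- function(lat, lon, t) {
  t <- .parse_utc(t)
  lt <- as.POSIXlt(t, tz = "UTC")
  doy <- lt$yday
  hour_frac <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (doy + (hour_frac - 12) / 24)   # fractional year, rad
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour_frac * 60 + eqtime + 4 * lon            # true solar time, min
  ha <- (tst / 4 - 180) * pi / 180                    # hour angle, rad
  p <- pi / 180
  sin_el <- sin(lat * p) * sin(decl) + cos(lat * p) * cos(decl) * cos(ha)
  asin(pmin(1, pmax(-1, sin_el))) / p
}

#' Day/night flag
#'
#' `TRUE` iff the solar elevation at the position and instant is above the
#' horizon; the binary daylight indicator used to gate purse-seine
#' detection.  Twilight counts as night.
#'
#' @inheritParams solar_elevation
#' @param refraction add the standard -0.833 degree sunrise depression
#'   (refraction + solar radius) to the day test; default `FALSE`
#'   (geometric horizon).
#' @return Logical vector.
#' @export
is_day <- function(lat, lon, t, refraction = FALSE) {
  thr <- if (refraction) -0.833 else 0
  solar_elevation(lat, lon, t) > thr
}

#' Annotate a track with daylight and distance-to-shore
#'
#' Adds `is_day` and `shore_km` columns; downstream detectors treat points
#' with `shore_km` below the offshore threshold as out-of-domain (forced
#' non-fishing).  Idempotent.
#'
#' @param track a track object.
#' @param shoreline a [as_shoreline()] object.
#' @param offshore_km coastal exclusion radius, km (default 10).
#' @return The track with `is_day` and `shore_km` columns and an
#'   `offshore_km` attribute.
#' @export
annotate_track <- function(track, shoreline, offshore_km = 10) {
  v <- validate_track(track)
  if (length(v)) stop("invalid track: ", v[1])
  track$is_day <- is_day(track$lat, track$lon, track$t)
  track$shore_km <- distance_to_shore(track$lat, track$lon, shoreline)
  attr(track, "offshore_km") <- offshore_km
  track
}

#' Regularize a track onto a fixed time grid
#'
#' Resamples the track at exactly `step_hours` spacing by linear
#' interpolation of latitude and longitude between the bracketing original
#' fixes.  Wherever consecutive fixes are more than `max_gap_hours` apart
#' the track is split and no interpolation bridges the gap.  Grid speed is
#' the great-circle displacement over one step, in knots.
#'
#' @param track a track object with at least 2 points.
#' @param step_hours grid spacing, hours (default 7, the longline
#'   regularization scale).
#' @param max_gap_hours largest original-fix gap to interpolate across
#'   (default 24).
#' @param mode `"interpolate"` (default) resamples positions on the grid;
#'   `"subsample"` instead keeps, for each grid instant, the nearest
#'   original fix (each fix used at most once).
#' @return List of regular-track objects (class
#'   `c("regular_track", "track", "data.frame")`), each with attributes
#'   `step_hours` and `origin`.  Bursts shorter than one step are dropped
#'   with a message.
#' @export
regularize_track <- function(track, step_hours = 7, max_gap_hours = 24,
                             mode = c("interpolate", "subsample")) {
  mode <- match.arg(mode)
  if (nrow(track) < 2L) stop("regularize_track needs at least 2 points")
  tt <- as.numeric(track$t)
  gaps <- which(diff(tt) > max_gap_hours * 3600)
  burst_id <- c(0, cumsum(seq_len(nrow(track) - 1L) %in% gaps))
  out <- list()
  for (b in split(seq_len(nrow(track)), burst_id)) {
    d <- track[b, , drop = FALSE]
    span_h <- (as.numeric(d$t[nrow(d)]) - as.numeric(d$t[1])) / 3600
    if (span_h < step_hours) {
      message("regularize_track: dropped burst shorter than one step (",
              round(span_h, 2), " h)")
      next
    }
    grid <- seq(as.numeric(d$t[1]), as.numeric(d$t[nrow(d)]),
                by = step_hours * 3600)
    if (mode == "interpolate") {
      glat <- stats::approx(as.numeric(d$t), d$lat, xout = grid)$y
      glon <- stats::approx(as.numeric(d$t), d$lon, xout = grid)$y
    } else {
      idx <- vapply(grid, function(g) which.min(abs(as.numeric(d$t) - g)),
                    integer(1))
      glat <- d$lat[idx]
      glon <- d$lon[idx]
    }
    n <- length(grid)
    disp <- haversine_km(glat[-n], glon[-n], glat[-1], glon[-1])
    sog <- c(NA_real_, disp / KM_PER_NM / step_hours)
    if (n >= 2) sog[1] <- sog[2]
    rt <- data.frame(vessel_id = d$vessel_id[1],
                     t = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
                     lat = glat, lon = glon, sog = sog,
                     label = NA_character_, stringsAsFactors = FALSE)
    rt <- as_track(rt, sort = FALSE)
    class(rt) <- c("regular_track", class(rt))
    attr(rt, "step_hours") <- step_hours
    attr(rt, "origin") <- rt$t[1]
    out[[length(out) + 1L]] <- rt
  }
  out
}
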