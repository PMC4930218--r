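#' @keywords internal
"_PACKAGE"

# Default mapping from logical column roles to file column names.
.default_column_map <- c(id = "mmsi", time = "timestamp", lat = "lat",
                         lon = "lon", sog = "sog", label = "label")

#' Construct a track object
#'
#' A track is an ordered sequence of timestamped position reports for a
#' single vessel, stored as a data frame with columns `vessel_id`, `t`
#' (POSIXct, UTC), `lat`, `lon` (decimal degrees WGS84), `sog` (speed over
#' ground, knots) and optionally `label` (`"F"` fishing / `"NF"`
#' non-fishing), `is_day`, `shore_km` and `phase`.
#'
#' @param df data frame holding at least `vessel_id`, `t`, `lat`, `lon`,
#'   `sog`. `t` may be POSIXct, numeric epoch seconds or ISO-8601 strings.
#' @param sort sort rows by time (default `TRUE`).
#' @return An object of class `c("track", "data.frame")`.
#' @export
as_track <- function(df, sort = TRUE) {
  stopifnot(is.data.frame(df))
  need <- c("vessel_id", "t", "lat", "lon", "sog")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track is missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$vessel_id <- as.character(df$vessel_id)
  df$t <- .parse_utc(df$t)
  for (col in c("lat", "lon", "sog")) df[[col]] <- as.numeric(df[[col]])
  if (!"label" %in% names(df)) df$label <- NA_character_
  if (sort && nrow(df) > 1) df <- df[order(df$t), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("track", "data.frame")
  df
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> vessel %s: %d points, %s .. %s\n",
              x$vessel_id[1], nrow(x),
              format(min(x$t), "%Y-%m-%d %H:%M UTC"),
              format(max(x$t), "%Y-%m-%d %H:%M UTC")))
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

# Parse timestamps given as POSIXct, epoch seconds or ISO-8601 text.
# Unparseable entries become NA (callers decide whether to drop or error).
.parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x),
                                               origin = "1970-01-01", tz = "UTC"))
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num[!is.na(x)]))
    return(as.POSIXct(num, origin = "1970-01-01", tz = "UTC"))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
  }
  out
}

#' Read vessel tracks from a delimited text file
#'
#' Reads one row per AIS position report and partitions rows into one track
#' per vessel id, sorted by time.  Duplicate (vessel, timestamp) rows keep
#' the first occurrence; rows whose timestamp or coordinates cannot be
#' parsed are rejected with their row numbers reported in a message.
#'
#' @param path delimited text file with a header row.
#' @param column_map named character vector mapping the roles
#'   `id`, `time`, `lat`, `lon`, `sog` and optionally `label` to the file's
#'   column names.  Defaults to `mmsi`, `timestamp`, `lat`, `lon`, `sog`,
#'   `label`.
#' @param sep field separator (default comma).
#' @return Named list of [as_track()] objects, one per vessel id.
#' @export
read_tracks <- function(path, column_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  cmap <- .default_column_map
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  need <- cmap[c("id", "time", "lat", "lon", "sog")]
  miss <- setdiff(unname(need), names(raw))
  if (length(miss))
    stop("required column(s) not found in ", path, ": ",
         paste(miss, collapse = ", "))
  df <- data.frame(vessel_id = as.character(raw[[cmap[["id"]]]]),
                   t = .parse_utc(raw[[cmap[["time"]]]]),
                   lat = suppressWarnings(as.numeric(raw[[cmap[["lat"]]]])),
                   lon = suppressWarnings(as.numeric(raw[[cmap[["lon"]]]])),
                   sog = suppressWarnings(as.numeric(raw[[cmap[["sog"]]]])),
                   stringsAsFactors = FALSE)
  if (cmap[["label"]] %in% names(raw)) {
    lab <- as.character(raw[[cmap[["label"]]]])
    bad <- !is.na(lab) & lab != "" & !lab %in% c("F", "NF")
    if (any(bad)) {
      warning(sum(bad), " label value(s) outside {F, NF} treated as unlabeled")
      lab[bad] <- NA_character_
    }
    lab[!is.na(lab) & lab == ""] <- NA_character_
    df$label <- lab
  } else df$label <- NA_character_
  for (extra in c("is_day", "shore_km", "phase"))
    if (extra %in% names(raw)) df[[extra]] <- raw[[extra]]
  bad_row <- is.na(df$t) | is.na(df$lat) | is.na(df$lon) | is.na(df$sog)
  if (any(bad_row)) {
    message("read_tracks: rejected ", sum(bad_row), " unparseable row(s): ",
            paste(utils::head(which(bad_row), 10L), collapse = ", "))
    df <- df[!bad_row, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows in ", path)
  out <- lapply(split(df, df$vessel_id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    dup <- duplicated(d$t)
    if (any(dup)) {
      message("read_tracks: vessel ", d$vessel_id[1], ": dropped ",
              sum(dup), " duplicate timestamp row(s)")
      d <- d[!dup, , drop = FALSE]
    }
    as_track(d, sort = FALSE)
  })
  out[order(names(out))]
}

#' Write labeled tracks to a delimited text file
#'
#' Every point must carry a predicted or ground-truth label.  Numeric
#' fields are written at full double precision so that
#' `read_tracks(write_labels(x))` reproduces ids, times, coordinates,
#' speeds and labels exactly.
#'
#' @param tracks a track or list of tracks.
#' @param path output file.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_labels <- function(tracks, path, sep = ",") {
  tracks <- .as_track_list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  header <- c("mmsi", "timestamp", "lat", "lon", "sog", "label")
  if (is.null(df) || nrow(df) == 0L) {
    writeLines(paste(header, collapse = sep), path)
    return(invisible(path))
  }
  if (anyNA(df$label))
    stop("write_labels: ", sum(is.na(df$label)), " point(s) have no label")
  num <- function(x) formatC(x, digits = 17, format = "g")
  out <- data.frame(mmsi = df$vessel_id,
                    timestamp = format(df$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    lat = num(df$lat), lon = num(df$lon), sog = num(df$sog),
                    label = df$label, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Export labeled points as a GeoJSON FeatureCollection
#'
#' One Point feature per position report, with vessel id, time, speed and
#' label as properties.
#'
#' @inheritParams write_labels
#' @return `path`, invisibly.
#' @export
write_geojson <- function(tracks, path) {
  tracks <- .as_track_list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = list(vessel_id = df$vessel_id[i],
                           timestamp = format(df$t[i], "%Y-%m-%dT%H:%M:%SZ",
                                              tz = "UTC"),
                           sog = df$sog[i],
                           label = if (is.na(df$label[i])) NULL else df$label[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Validate track invariants
#'
#' Checks coordinate bounds, non-negative finite speeds, strictly
#' increasing timestamps and a single vessel id.  Violations are returned
#' as data, never raised.
#'
#' @param track a track object or data frame with the track columns.
#' @return Character vector of human-readable violations; empty if the
#'   track is valid.
#' @export
validate_track <- function(track) {
  v <- character(0)
  if (nrow(track) < 1L) return("track has no points")
  if (length(unique(track$vessel_id)) != 1L)
    v <- c(v, "multiple vessel_id values in one track")
  bad_lat <- which(is.na(track$lat) | track$lat < -90 | track$lat > 90)
  if (length(bad_lat))
    v <- c(v, sprintf("latitude out of [-90, 90] at row(s) %s",
                      paste(utils::head(bad_lat, 5L), collapse = ", ")))
  bad_lon <- which(is.na(track$lon) | track$lon < -180 | track$lon > 180)
  if (length(bad_lon))
    v <- c(v, sprintf("longitude out of [-180, 180] at row(s) %s",
                      paste(utils::head(bad_lon, 5L), collapse = ", ")))
  bad_sog <- which(is.na(track$sog) | !is.finite(track$sog) | track$sog < 0)
  if (length(bad_sog))
    v <- c(v, sprintf("negative or non-finite speed at row(s) %s",
                      paste(utils::head(bad_sog, 5L), collapse = ", ")))
  if (anyNA(track$t)) v <- c(v, "undefined timestamp(s)")
  else if (nrow(track) > 1L && any(diff(as.numeric(track$t)) <= 0))
    v <- c(v, "timestamps not strictly increasing")
  v
}

.as_track_list <- function(tracks) {
  if (inherits(tracks, "track")) return(list(tracks))
  if (is.data.frame(tracks)) return(list(as_track(tracks)))
  if (!is.list(tracks)) stop("expected a track or a list of tracks")
  tracks
}
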