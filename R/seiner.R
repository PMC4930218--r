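#' Purse-seine filter parameters
#'
#' The multi-layer filter calls a point fishing iff it is in daylight,
#' at least `offshore_km` from shore and moving at `speed_max` knots or
#' slower.  Both boundaries are inclusive on the fishing side.
#'
#' @param speed_max maximum fishing speed over ground, knots
#'   (default 2.5).
#' @param offshore_km minimum distance to shore, km (default 10).
#' @param require_day gate on daylight (default `TRUE`; the large majority
#'   of purse seiners do not fish at night).
#' @return Object of class `seiner_params`.
#' @export
seiner_params <- function(speed_max = 2.5, offshore_km = 10,
                          require_day = TRUE) {
  stopifnot(speed_max > 0, offshore_km >= 0, is.logical(require_day))
  structure(list(speed_max = speed_max, offshore_km = offshore_km,
                 require_day = require_day), class = "seiner_params")
}

#' Purse-seine fishing detection
#'
#' Pure per-point filter: label `"F"` iff (daylight or day-gating off) and
#' `shore_km >= offshore_km` and `sog <= speed_max`; otherwise `"NF"`.
#' No sequence context; idempotent.  An optional minimum-event-duration
#' post-filter drops fishing runs shorter than `min_event_minutes`.
#'
#' @param track an annotated track: `is_day` and `shore_km` must be
#'   present on every point (see [annotate_track()]).
#' @param params a [seiner_params()] object.
#' @param min_event_minutes if positive, relabel to `"NF"` any maximal
#'   fishing run whose first-to-last time span is shorter than this
#'   (default 0 = off, the per-point behavior).
#' @return Character vector of `"F"`/`"NF"` labels.
#' @export
detect_seiner <- function(track, params = seiner_params(),
                          min_event_minutes = 0) {
  for (col in c("is_day", "shore_km"))
    if (!col %in% names(track) || anyNA(track[[col]]))
      stop("detect_seiner: annotation column '", col,
           "' missing or incomplete; run annotate_track() first")
  f <- (!params$require_day | track$is_day) &
    track$shore_km >= params$offshore_km &
    track$sog <= params$speed_max
  labels <- ifelse(f, "F", "NF")
  if (min_event_minutes > 0 && any(f)) {
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values == "F")) {
      span_min <- (as.numeric(track$t[ends[k]]) -
                   as.numeric(track$t[starts[k]])) / 60
      if (span_min < min_event_minutes)
        labels[starts[k]:ends[k]] <- "NF"
    }
  }
  labels
}
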