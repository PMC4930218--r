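# Dead reckoning on a local tangent plane: advance d_km on a compass
# heading (degrees clockwise from north).
.advance <- function(lat, lon, heading_deg, d_km) {
  h <- heading_deg * pi / 180
  lat2 <- lat + d_km * cos(h) / 110.574
  lon2 <- lon + d_km * sin(h) / (111.320 * cos(lat * pi / 180))
  c(lat2, lon2)
}

.trunc_norm <- function(n, mean, sd, lo = 0, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Gear behavior profile for the track simulator
#'
#' Kinematic and reporting parameters for one gear type.  The fishing
#' envelopes (trawl speeds 2.5-5.5 knots lasting 3-5 hours; longline sets
#' with a 6.5-hour median duration, slow soak drift and a retraced haul;
#' purse-seine hauls at 2.5 knots and less, 1-4 hours, daylight only)
#' follow the operational definitions of each gear; steaming-speed and
#' reporting parameters are surrogate values chosen to resemble
#' satellite-AIS trawler/longliner/seiner tracks, since the underlying
#' speed distributions are not published as parameters.
#'
#' @param gear `"trawler"`, `"longliner"` or `"seiner"`.
#' @param ... named overrides of profile fields.
#' @return Object of class `gear_profile` (a named list).
#' @export
gear_profile <- function(gear = c("trawler", "longliner", "seiner"), ...) {
  gear <- match.arg(gear)
  p <- switch(gear,
    trawler = list(
      steaming_speed = c(mean = 10.5, sd = 3),  # heavy overlap with trawl band
      fishing_speed_range = c(2.5, 5.5),
      event_duration_h = c(3, 5),               # uniform
      steam_duration_h = c(4, 10),
      heading_sd_steam = 2, heading_sd_fish = 8,
      report_interval_min = 5,                  # mean of gamma(shape 2)
      gap_prob = 0.02, gap_duration_h = c(0.5, 3),
      gps_noise_km = 0.05, day_only = FALSE),
    longliner = list(
      steaming_speed = c(mean = 11, sd = 1.5),
      set_speed = c(mean = 8.5, sd = 0.7),      # slightly below steaming
      set_duration_meanlog = log(6.5), set_duration_sdlog = 0.25,
      soak_duration_h = c(4, 8), soak_speed_kn = c(0.2, 1.9),
      soak_radius_km = 0.2,
      haul_speed_kn = c(4, 6),
      sets_per_trip = c(1, 4),
      steam_duration_h = c(6, 12),
      heading_sd_steam = 2,
      report_interval_min = 5,
      gap_prob = 0.02, gap_duration_h = c(0.5, 3),
      gps_noise_km = 0.05, day_only = FALSE),
    seiner = list(
      search_speed = c(mean = 13, sd = 1.5),
      night_speed = c(mean = 9, sd = 2),
      night_drift_prob = 0.3, night_drift_kn = c(0.3, 2),
      haul_speed_kn = c(0.1, 2.4),
      haul_duration_h = c(1, 4),
      search_duration_h = c(2, 5),
      haul_prob = 0.35,                          # after each day search leg
      heading_sd_steam = 3,
      report_interval_min = 5,
      gap_prob = 0.02, gap_duration_h = c(0.5, 3),
      gps_noise_km = 0.05, day_only = TRUE))
  p$gear <- gear
  over <- list(...)
  p[names(over)] <- over
  class(p) <- "gear_profile"
  p
}

# Shared phase emitter.  Walks wall-clock time through one phase, emitting
# reports at irregular gamma intervals with occasional coverage gaps.
# speed_fun(dt_reports) returns per-report speeds; move_fun(state, v, dt)
# returns new (lat, lon) true position.  Returns updated sim state.
.emit_phase <- function(st, prof, duration_h, phase, label, speed_fun,
                        heading_sd = 0, fixed_heading = NULL,
                        stop_if = NULL) {
  end_t <- st$t + duration_h * 3600
  while (st$t < end_t) {
    dt <- stats::rgamma(1, shape = 2,
                        rate = 2 / (prof$report_interval_min * 60))
    dt <- min(dt, end_t - st$t)
    if (dt <= 0) break
    v <- speed_fun()
    d_km <- v * (dt / 3600) * KM_PER_NM
    if (!is.null(fixed_heading)) st$heading <- fixed_heading
    else st$heading <- st$heading + stats::rnorm(1, 0, heading_sd)
    pos <- .advance(st$lat, st$lon, st$heading, d_km)
    st$lat <- pos[1]; st$lon <- pos[2]
    st$t <- st$t + dt
    # the interval that crosses the stop condition advances the vessel
    # but is never reported under this phase's label
    if (!is.null(stop_if) && stop_if(st$lat, st$lon, st$t)) break
    if (stats::runif(1) < prof$gap_prob) {
      st$t <- st$t + stats::runif(1, prof$gap_duration_h[1],
                                  prof$gap_duration_h[2]) * 3600
      next                                    # coverage gap: no report
    }
    noise <- stats::rnorm(2, 0, prof$gps_noise_km)
    st$rec$t[st$n + 1L] <- st$t
    st$rec$lat[st$n + 1L] <- st$lat + noise[1] / 110.574
    st$rec$lon[st$n + 1L] <- st$lon +
      noise[2] / (111.320 * cos(st$lat * pi / 180))
    st$rec$sog[st$n + 1L] <- v
    st$rec$label[st$n + 1L] <- label
    st$rec$phase[st$n + 1L] <- phase
    st$n <- st$n + 1L
  }
  st
}

# Emit one report at the current true position after a reporting delay
# (vessel pausing at a phase boundary: gear deployment or turnaround).
.emit_boundary <- function(st, prof, phase, label, v) {
  st$t <- st$t + stats::rgamma(1, shape = 2,
                               rate = 2 / (prof$report_interval_min * 60))
  noise <- stats::rnorm(2, 0, prof$gps_noise_km)
  st$rec$t[st$n + 1L] <- st$t
  st$rec$lat[st$n + 1L] <- st$lat + noise[1] / 110.574
  st$rec$lon[st$n + 1L] <- st$lon +
    noise[2] / (111.320 * cos(st$lat * pi / 180))
  st$rec$sog[st$n + 1L] <- v
  st$rec$label[st$n + 1L] <- label
  st$rec$phase[st$n + 1L] <- phase
  st$n <- st$n + 1L
  st
}

.new_sim_state <- function(start_lat, start_lon, start_time, n_cap) {
  list(lat = start_lat, lon = start_lon,
       t = as.numeric(.parse_utc(start_time)),
       heading = stats::runif(1, 0, 360), n = 0L,
       rec = list(t = numeric(n_cap), lat = numeric(n_cap),
                  lon = numeric(n_cap), sog = numeric(n_cap),
                  label = character(n_cap), phase = character(n_cap)))
}

.sim_finish <- function(st, vessel_id) {
  idx <- seq_len(st$n)
  d <- data.frame(vessel_id = vessel_id,
                  t = as.POSIXct(st$rec$t[idx], origin = "1970-01-01",
                                 tz = "UTC"),
                  lat = st$rec$lat[idx], lon = st$rec$lon[idx],
                  sog = st$rec$sog[idx], label = st$rec$label[idx],
                  stringsAsFactors = FALSE)
  d$phase <- st$rec$phase[idx]
  d <- d[!duplicated(d$t), , drop = FALSE]
  as_track(d, sort = FALSE)
}

#' Simulate a labeled trawler track
#'
#' Alternates steaming phases (truncated-normal speed, persistent heading)
#' with trawl phases (speed uniform on the trawl band, 3-5 hour duration,
#' gentle heading drift).  Trawl-phase points are ground-truth fishing.
#' Reports arrive at irregular intervals with occasional coverage gaps;
#' reported positions carry GPS noise while reported speed is the true
#' phase speed.  Bit-reproducible for a given seed.
#'
#' @param profile a [gear_profile()] (`"trawler"`).
#' @param n_hours simulated duration.
#' @param seed RNG seed.
#' @param start_lat,start_lon,start_time starting position/instant.
#' @param vessel_id id stamped on the track.
#' @return A labeled track with a `phase` column.
#' @export
simulate_trawler <- function(profile = gear_profile("trawler"), n_hours = 240,
                             seed = 1, start_lat = 47, start_lon = -145,
                             start_time = "2013-07-01T00:00:00Z",
                             vessel_id = "SIM-TRAWL-1") {
  set.seed(seed)
  st <- .new_sim_state(start_lat, start_lon, start_time,
                       n_cap = ceiling(n_hours * 60 / profile$report_interval_min) + 64L)
  elapsed <- 0
  fishing <- FALSE
  while (elapsed < n_hours) {
    if (fishing) {
      dur <- stats::runif(1, profile$event_duration_h[1],
                          profile$event_duration_h[2])
      lo <- profile$fishing_speed_range[1]
      hi <- profile$fishing_speed_range[2]
      base <- stats::runif(1, lo, hi)
      st <- .emit_phase(st, profile, min(dur, n_hours - elapsed), "trawl", "F",
                        speed_fun = function()
                          min(max(base + stats::rnorm(1, 0, 0.15), lo), hi),
                        heading_sd = profile$heading_sd_fish)
    } else {
      dur <- stats::runif(1, profile$steam_duration_h[1],
                          profile$steam_duration_h[2])
      st <- .emit_phase(st, profile, min(dur, n_hours - elapsed), "steam", "NF",
                        speed_fun = function()
                          .trunc_norm(1, profile$steaming_speed["mean"],
                                      profile$steaming_speed["sd"], lo = 0.5),
                        heading_sd = profile$heading_sd_steam)
    }
    elapsed <- elapsed + dur
    fishing <- !fishing
  }
  .sim_finish(st, vessel_id)
}

#' Simulate a labeled longliner track
#'
#' Trips cycle steam -> fishing ground, where 1-4 consecutive set cycles
#' occur: a straight set leg slightly slower than steaming (duration
#' log-normal, median 6.5 h), a soak phase station-keeping near the line
#' end at under 2 knots, and a haul that retraces the set leg at reduced
#' speed back to its start.  Set, soak and haul points are ground-truth
#' fishing (gear in the water).  Reporting and noise as in
#' [simulate_trawler()].
#'
#' @inheritParams simulate_trawler
#' @export
simulate_longliner <- function(profile = gear_profile("longliner"),
                               n_hours = 720, seed = 1,
                               start_lat = 10, start_lon = -140,
                               start_time = "2013-01-01T00:00:00Z",
                               vessel_id = "SIM-LL-1") {
  set.seed(seed)
  st <- .new_sim_state(start_lat, start_lon, start_time,
                       n_cap = ceiling(n_hours * 60 / profile$report_interval_min) + 64L)
  t_end <- st$t + n_hours * 3600
  while (st$t < t_end) {
    dur <- stats::runif(1, profile$steam_duration_h[1],
                        profile$steam_duration_h[2])
    st <- .emit_phase(st, profile, dur, "steam", "NF",
                      speed_fun = function()
                        .trunc_norm(1, profile$steaming_speed["mean"],
                                    profile$steaming_speed["sd"], lo = 0.5),
                      heading_sd = profile$heading_sd_steam)
    if (st$t >= t_end) break
    n_sets <- sample(profile$sets_per_trip[1]:profile$sets_per_trip[2], 1)
    for (s in seq_len(n_sets)) {
      if (st$t >= t_end) break
      # --- set: straight leg, heading fixed; explicit reports mark the
      # leg endpoints (the vessel pauses to start and finish deployment)
      A <- c(st$lat, st$lon)
      hdg <- stats::runif(1, 0, 360)
      set_dur <- stats::rlnorm(1, profile$set_duration_meanlog,
                               profile$set_duration_sdlog)
      set_v <- function() .trunc_norm(1, profile$set_speed["mean"],
                                      profile$set_speed["sd"], lo = 1)
      st <- .emit_boundary(st, profile, "set", "F", v = set_v())
      st <- .emit_phase(st, profile, set_dur, "set", "F",
                        speed_fun = set_v, fixed_heading = hdg)
      B <- c(st$lat, st$lon)
      st <- .emit_boundary(st, profile, "set", "F", v = set_v())
      # --- soak: station-keeping near the line end
      soak_dur <- stats::runif(1, profile$soak_duration_h[1],
                               profile$soak_duration_h[2])
      soak_end <- min(st$t + soak_dur * 3600, t_end)
      while (st$t < soak_end) {
        dt <- stats::rgamma(1, shape = 2,
                            rate = 2 / (profile$report_interval_min * 60))
        dt <- min(dt, soak_end - st$t)
        if (dt <= 0) break
        st$t <- st$t + dt
        v <- stats::runif(1, profile$soak_speed_kn[1], profile$soak_speed_kn[2])
        jit <- stats::runif(2, -profile$soak_radius_km, profile$soak_radius_km)
        st$lat <- B[1] + jit[1] / 110.574
        st$lon <- B[2] + jit[2] / (111.320 * cos(B[1] * pi / 180))
        if (stats::runif(1) < profile$gap_prob) {
          st$t <- st$t + stats::runif(1, profile$gap_duration_h[1],
                                      profile$gap_duration_h[2]) * 3600
          next
        }
        noise <- stats::rnorm(2, 0, profile$gps_noise_km)
        st$rec$t[st$n + 1L] <- st$t
        st$rec$lat[st$n + 1L] <- st$lat + noise[1] / 110.574
        st$rec$lon[st$n + 1L] <- st$lon +
          noise[2] / (111.320 * cos(st$lat * pi / 180))
        st$rec$sog[st$n + 1L] <- v
        st$rec$label[st$n + 1L] <- "F"
        st$rec$phase[st$n + 1L] <- "soak"
        st$n <- st$n + 1L
      }
      # --- haul: retrace the set leg B -> A at reduced speed; the
      # turnaround at the line end is itself reported
      leg_km <- haversine_km(A[1], A[2], B[1], B[2])
      haul_v <- stats::runif(1, profile$haul_speed_kn[1],
                             profile$haul_speed_kn[2])
      frac_done <- 0
      st$lat <- B[1]; st$lon <- B[2]
      st <- .emit_boundary(st, profile, "haul", "F", v = haul_v)
      while (frac_done < 1 && st$t < t_end) {
        dt <- stats::rgamma(1, shape = 2,
                            rate = 2 / (profile$report_interval_min * 60))
        adv <- haul_v * (dt / 3600) * KM_PER_NM / max(leg_km, 1e-9)
        frac_done <- min(1, frac_done + adv)
        st$t <- st$t + dt
        st$lat <- B[1] + frac_done * (A[1] - B[1])
        st$lon <- B[2] + frac_done * (A[2] - B[2])
        if (stats::runif(1) < profile$gap_prob && frac_done < 1) {
          st$t <- st$t + stats::runif(1, profile$gap_duration_h[1],
                                      profile$gap_duration_h[2]) * 3600
          next
        }
        noise <- stats::rnorm(2, 0, profile$gps_noise_km)
        st$rec$t[st$n + 1L] <- st$t
        st$rec$lat[st$n + 1L] <- st$lat + noise[1] / 110.574
        st$rec$lon[st$n + 1L] <- st$lon +
          noise[2] / (111.320 * cos(st$lat * pi / 180))
        st$rec$sog[st$n + 1L] <- haul_v
        st$rec$label[st$n + 1L] <- "F"
        st$rec$phase[st$n + 1L] <- "haul"
        st$n <- st$n + 1L
      }
    }
  }
  .sim_finish(st, vessel_id)
}

#' Simulate a labeled purse-seiner track
#'
#' Daylight-gated fishing: during the day the vessel alternates
#' high-speed search legs with occasional haul/drift events at 2.5 knots
#' or less lasting 1-4 hours; a haul ends early if the sun sets.  At
#' night the vessel steams or drifts without fishing.  Haul points are
#' ground-truth fishing.
#'
#' @inheritParams simulate_trawler
#' @param n_days simulated duration in days.
#' @export
simulate_seiner <- function(profile = gear_profile("seiner"), n_days = 10,
                            seed = 1, start_lat = 0, start_lon = -120,
                            start_time = "2013-03-01T00:00:00Z",
                            vessel_id = "SIM-PS-1") {
  set.seed(seed)
  n_hours <- n_days * 24
  st <- .new_sim_state(start_lat, start_lon, start_time,
                       n_cap = ceiling(n_hours * 60 / profile$report_interval_min) + 64L)
  t_end <- st$t + n_hours * 3600
  while (st$t < t_end) {
    day_now <- is_day(st$lat, st$lon, st$t)
    if (!day_now) {
      # night: steam or drift for 1-3 h, never fish; a night phase breaks
      # off at dawn (operations switch to searching with first light)
      dur <- stats::runif(1, 1, 3)
      at_dawn <- function(lat, lon, t) is_day(lat, lon, t)
      if (stats::runif(1) < profile$night_drift_prob)
        st <- .emit_phase(st, profile, dur, "drift", "NF",
                          speed_fun = function()
                            stats::runif(1, profile$night_drift_kn[1],
                                         profile$night_drift_kn[2]),
                          heading_sd = 20, stop_if = at_dawn)
      else
        st <- .emit_phase(st, profile, dur, "steam", "NF",
                          speed_fun = function()
                            .trunc_norm(1, profile$night_speed["mean"],
                                        profile$night_speed["sd"], lo = 0.5),
                          heading_sd = profile$heading_sd_steam,
                          stop_if = at_dawn)
      next
    }
    # day: search leg, then possibly a haul
    dur <- stats::runif(1, profile$search_duration_h[1],
                        profile$search_duration_h[2])
    st <- .emit_phase(st, profile, dur, "search", "NF",
                      speed_fun = function()
                        .trunc_norm(1, profile$search_speed["mean"],
                                    profile$search_speed["sd"], lo = 3),
                      heading_sd = 10)
    if (st$t < t_end && stats::runif(1) < profile$haul_prob &&
        is_day(st$lat, st$lon, st$t)) {
      dur <- stats::runif(1, profile$haul_duration_h[1],
                          profile$haul_duration_h[2])
      # emit haul reports one at a time so every fishing report is
      # guaranteed to fall in daylight (a haul ends at sunset)
      haul_end <- min(st$t + dur * 3600, t_end)
      while (st$t < haul_end) {
        dt <- stats::rgamma(1, shape = 2,
                            rate = 2 / (profile$report_interval_min * 60))
        dt <- min(dt, haul_end - st$t)
        if (dt <= 0) break
        v <- stats::runif(1, profile$haul_speed_kn[1],
                          profile$haul_speed_kn[2])
        st$heading <- st$heading + stats::rnorm(1, 0, 30)
        pos <- .advance(st$lat, st$lon, st$heading,
                        v * (dt / 3600) * KM_PER_NM)
        if (!is_day(pos[1], pos[2], st$t + dt)) break
        st$lat <- pos[1]; st$lon <- pos[2]
        st$t <- st$t + dt
        if (stats::runif(1) < profile$gap_prob) {
          st$t <- st$t + stats::runif(1, profile$gap_duration_h[1],
                                      profile$gap_duration_h[2]) * 3600
          break
        }
        noise <- stats::rnorm(2, 0, profile$gps_noise_km)
        st$rec$t[st$n + 1L] <- st$t
        st$rec$lat[st$n + 1L] <- st$lat + noise[1] / 110.574
        st$rec$lon[st$n + 1L] <- st$lon +
          noise[2] / (111.320 * cos(st$lat * pi / 180))
        st$rec$sog[st$n + 1L] <- v
        st$rec$label[st$n + 1L] <- "F"
        st$rec$phase[st$n + 1L] <- "haul"
        st$n <- st$n + 1L
      }
    }
  }
  .sim_finish(st, vessel_id)
}

#' Thin a track with a coverage-gap model
#'
#' Drops runs of reports to emulate satellite-coverage dropouts: at each
#' surviving report a gap opens with probability `gap_prob` and removes
#' all reports in the following exponential-length window.  Order and
#' ground-truth labels of survivors are untouched.
#'
#' @param track a track.
#' @param gap_prob per-report probability that a gap opens (default 0.05).
#' @param gap_mean_hours mean gap length (default 2).
#' @param seed RNG seed.
#' @return The thinned track.
#' @export
degrade_track <- function(track, gap_prob = 0.05, gap_mean_hours = 2,
                          seed = 1) {
  set.seed(seed)
  if (gap_prob <= 0) return(track)
  tt <- as.numeric(track$t)
  keep <- rep(TRUE, nrow(track))
  gap_until <- -Inf
  for (i in seq_len(nrow(track))) {
    if (tt[i] < gap_until) { keep[i] <- FALSE; next }
    if (stats::runif(1) < gap_prob)
      gap_until <- tt[i] + stats::rexp(1, 1 / (gap_mean_hours * 3600))
  }
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
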