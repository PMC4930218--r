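# Independent oracles and toy-track builders shared across the suite.
# Every oracle is coded from first principles, separately from the package
# implementation it checks.

# Build a toy track from vectors; times given in hours from an epoch.
mk_track <- function(lat, lon, hours = seq_along(lat) - 1, sog = 5,
                     label = NA_character_, vessel_id = "V1",
                     origin = "2013-06-01T00:00:00Z") {
  n <- length(lat)
  as_track(data.frame(
    vessel_id = vessel_id,
    t = as.POSIXct(origin, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ") +
      hours * 3600,
    lat = lat, lon = rep_len(lon, n), sog = rep_len(sog, n),
    label = rep_len(label, n), stringsAsFactors = FALSE))
}

# --- exhaustive Viterbi oracle -----------------------------------------
# Joint probability of one state sequence computed term by term from the
# model's parameters (histogram emission lookup done by hand).
oracle_joint <- function(model, states_idx, speeds) {
  emis <- function(y, s) {
    y <- min(max(y, 0), model$v_max)
    nb <- length(model$breaks) - 1L
    bin <- min(floor(y / model$w) + 1L, nb)
    model$mass[bin, s]
  }
  p <- model$pi[states_idx[1]] * emis(speeds[1], states_idx[1])
  for (t in seq_along(states_idx)[-1])
    p <- p * model$A[states_idx[t - 1], states_idx[t]] *
      emis(speeds[t], states_idx[t])
  unname(p)
}

# All 2^T sequences; returns list(path_idx, log_score).  Ties resolve the
# same way as the implementation contract: toward NF (state index 1),
# i.e. the lexicographically smallest index vector among maximizers.
oracle_viterbi <- function(model, speeds) {
  T_ <- length(speeds)
  grid <- as.matrix(expand.grid(rep(list(1:2), T_)))[, T_:1, drop = FALSE]
  ord <- do.call(order, as.data.frame(grid))     # lexicographic
  grid <- grid[ord, , drop = FALSE]
  scores <- apply(grid, 1, function(s) oracle_joint(model, s, speeds))
  best <- which.max(scores)                      # first max = smallest lex
  list(path = grid[best, ], log_score = log(scores[best]))
}

random_hmm <- function() {
  nb <- 51L
  mass <- cbind(NF = as.numeric(stats::rgamma(nb, 1)) ,
                F = as.numeric(stats::rgamma(nb, 1)))
  mass <- sweep(mass, 2, colSums(mass), "/")
  A <- matrix(stats::runif(4, 0.05, 1), 2, 2)
  A <- A / rowSums(A)
  dimnames(A) <- list(c("NF", "F"), c("NF", "F"))
  pi0 <- stats::runif(1, 0.1, 0.9)
  m <- list(pi = c(NF = pi0, F = 1 - pi0), A = A, emission = "histogram",
            w = 0.5, v_max = 25.5, alpha = 1,
            breaks = seq(0, 25.5, by = 0.5), mass = mass)
  class(m) <- "trawler_hmm"
  m
}

# --- exhaustive Lavielle oracle ----------------------------------------
# Minimum least-squares contrast over all admissible K-segmentations.
oracle_lavielle <- function(series, K, Lmin = 2) {
  n <- length(series)
  sse <- function(i, j) {
    x <- series[i:j]
    sum((x - mean(x))^2)
  }
  if (K == 1) return(list(breakpoints = integer(0), contrast = sse(1, n)))
  combos <- utils::combn(seq_len(n - 1), K - 1, simplify = FALSE)
  best <- NULL
  best_c <- Inf
  for (bp in combos) {
    lens <- diff(c(0, bp, n))
    if (any(lens < Lmin)) next
    bounds <- c(0, bp, n)
    ct <- sum(vapply(seq_len(K), function(k)
      sse(bounds[k] + 1, bounds[k + 1]), numeric(1)))
    if (ct < best_c - 1e-12) {
      best_c <- ct
      best <- bp
    }
  }
  list(breakpoints = best, contrast = best_c)
}

# --- O(n^2) first-passage-time oracle ----------------------------------
oracle_fpt <- function(lat, lon, t, r) {
  tt <- as.numeric(t)
  n <- length(lat)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- sqrt((lat - lat[i])^2 + (lon - lon[i])^2)
    fw <- bw <- NA_real_
    j <- i
    while (j < n) {
      j <- j + 1
      if (d[j] > r) {
        fw <- tt[j - 1] + (r - d[j - 1]) / (d[j] - d[j - 1]) *
          (tt[j] - tt[j - 1])
        break
      }
    }
    j <- i
    while (j > 1) {
      j <- j - 1
      if (d[j] > r) {
        bw <- tt[j + 1] + (r - d[j + 1]) / (d[j] - d[j + 1]) *
          (tt[j] - tt[j + 1])
        break
      }
    }
    if (!is.na(fw) && !is.na(bw)) out[i] <- (fw - bw) / 3600
  }
  out
}

# --- Michalsky (Astronomical Almanac) solar elevation oracle -----------
# Entirely different formulation from the package's fractional-year
# series: mean longitude / mean anomaly -> ecliptic longitude -> right
# ascension & declination -> local mean sidereal time -> hour angle.
oracle_solar_elevation <- function(lat, lon, t) {
  t <- as.POSIXct(t, tz = "UTC")
  jd <- as.numeric(t) / 86400 + 2440587.5
  n <- jd - 2451545.0
  hour <- (as.numeric(t) %% 86400) / 3600
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 0.0000004 * n) * pi / 180
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda))        # rad
  dec <- asin(sin(eps) * sin(lambda))
  gmst <- (6.697375 + 0.0657098242 * n + hour) %% 24      # hours
  lmst <- (gmst + lon / 15) %% 24
  ha <- lmst * 15 * pi / 180 - ra
  p <- pi / 180
  el <- asin(sin(lat * p) * sin(dec) + cos(lat * p) * cos(dec) * cos(ha))
  el / p
}

# First upward zero-crossing (sunrise) of an elevation function within a
# UTC day, by bisection on an hourly bracket; NA if none.
find_sunrise <- function(elev_fun, lat, lon, date_utc) {
  t0 <- as.POSIXct(paste0(date_utc, " 00:00:00"), tz = "UTC")
  hrs <- seq(0, 24, by = 0.25)
  el <- vapply(hrs, function(h) elev_fun(lat, lon, t0 + h * 3600), numeric(1))
  idx <- which(el[-length(el)] < 0 & el[-1] >= 0)
  if (!length(idx)) return(NA)
  i <- idx[1]
  root <- stats::uniroot(function(h) elev_fun(lat, lon, t0 + h * 3600),
                         lower = hrs[i], upper = hrs[i + 1], tol = 1e-6)$root
  t0 + root * 3600
}
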