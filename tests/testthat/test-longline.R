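test_that("minimum-contrast segmentation handles canonical cases", {
  seg <- lavielle_segment(rep(5, 10), K = 1)
  expect_equal(seg$breakpoints, integer(0))
  expect_equal(seg$contrast, 0)

  seg2 <- lavielle_segment(c(rep(0, 10), rep(5, 10)), K = 2)
  expect_equal(seg2$breakpoints, 10L)
  expect_equal(seg2$contrast, 0)

  expect_error(lavielle_segment(1:5, K = 3, Lmin = 2), "infeasible")
})

test_that("segmentation DP equals exhaustive search on random series", {
  set.seed(11)
  for (k in 1:30) {
    n <- sample(12:30, 1)
    K <- sample(2:3, 1)
    x <- cumsum(rnorm(n)) + rep(rnorm(3, sd = 4), length.out = n)
    got <- lavielle_segment(x, K)
    ref <- oracle_lavielle(x, K)
    expect_equal(got$contrast, ref$contrast, tolerance = 1e-9)
    expect_equal(got$breakpoints, as.integer(ref$breakpoints))
  }
})

test_that("segments partition the series and respect the minimum length", {
  set.seed(12)
  x <- rnorm(40)
  seg <- lavielle_segment(x, K = 5, Lmin = 3)
  expect_equal(sort(unlist(seg$segments)), 1:40)
  expect_true(all(lengths(seg$segments) >= 3))
})

test_that("turning cosines distinguish straight, zigzag and reversal geometry", {
  # collinear equally spaced points
  expect_equal(turning_cosines(lat = rep(0, 5), lon = 0:4), rep(1, 3))
  # right-angle zigzag (equator: degrees locally isometric)
  zig_lat <- c(0, 0, 1, 1, 2)
  zig_lon <- c(0, 1, 1, 2, 2)
  expect_equal(turning_cosines(zig_lat, zig_lon), rep(0, 3),
               tolerance = 1e-6)
  # exact back-and-forth reversal
  expect_equal(turning_cosines(lat = c(0, 0, 0), lon = c(0, 1, 0)), -1)
  # zero-length displacement counts as no turn
  expect_equal(turning_cosines(lat = c(0, 0, 0), lon = c(0, 0, 1)), 1)
  expect_length(turning_cosines(lat = c(0, 1), lon = 0), 0)
})

test_that("straightness rule accepts both forward and reversal movement", {
  expect_true(classify_straight(rep(0, 5), 0:4)$straight)
  rev <- classify_straight(c(0, 0, 0), c(0, 1, 0))
  expect_true(rev$straight)            # mean cosine -1: straight-line rule
  expect_equal(rev$mean_cos, -1)
  zig <- classify_straight(c(0, 0, 1, 1, 2), c(0, 1, 1, 2, 2))
  expect_false(zig$straight)
  expect_equal(zig$mean_cos, 0, tolerance = 1e-6)
})

test_that("FPT on a straight constant-speed path equals 2r/v and is monotone in r", {
  # 0.1 degrees/hour along the equator
  n <- 41
  lon <- seq(0, 4, by = 0.1)
  tr_t <- as.POSIXct("2013-01-01", tz = "UTC") + 3600 * (0:(n - 1))
  radii <- seq(0.1, 1, length.out = 30)
  for (r in radii) {
    fpt <- first_passage_times(rep(0, n), lon, tr_t, r)
    interior <- !is.na(fpt)
    expect_true(any(interior))
    expect_equal(fpt[interior], rep(2 * r / 0.1, sum(interior)),
                 tolerance = 1e-6)
  }
  # radius larger than the path's extent: all undefined
  expect_true(all(is.na(first_passage_times(rep(0, 5), seq(0, 0.4, 0.1),
                                            tr_t[1:5], r = 5))))
})

test_that("FPT matches the brute-force crossing scan on a random walk", {
  set.seed(13)
  lat <- cumsum(rnorm(30, sd = 0.15))
  lon <- cumsum(rnorm(30, sd = 0.15))
  tr_t <- as.POSIXct("2013-01-01", tz = "UTC") + 7 * 3600 * (0:29)
  for (r in c(0.1, 0.35, 0.8)) {
    expect_equal(first_passage_times(lat, lon, tr_t, r),
                 oracle_fpt(lat, lon, tr_t, r))
  }
})

test_that("FPT is monotonically non-decreasing in r where defined", {
  set.seed(14)
  lat <- cumsum(rnorm(25, sd = 0.1))
  lon <- cumsum(rnorm(25, sd = 0.1))
  tr_t <- as.POSIXct("2013-01-01", tz = "UTC") + 7 * 3600 * (0:24)
  radii <- seq(0.1, 1, length.out = 10)
  prev <- rep(-Inf, 25)
  for (r in radii) {
    fpt <- first_passage_times(lat, lon, tr_t, r)
    ok <- !is.na(fpt) & is.finite(prev)
    expect_true(all(fpt[ok] >= prev[ok] - 1e-9))
    prev <- ifelse(is.na(fpt), prev, fpt)
  }
})

test_that("FPT variance filter relabels transit and keeps area-restricted movement", {
  # constant-speed straight path: Var(log FPT) = 0 at every radius
  lon <- seq(0, 4, by = 0.1)
  tr_t <- as.POSIXct("2013-01-01", tz = "UTC") + 3600 * (0:40)
  res <- fpt_variance_filter(rep(0, 41), lon, tr_t)
  expect_false(res$keep_fishing)
  expect_lt(res$fpt_var, 1e-10)

  # alternating tight clusters and transit: high log-FPT variance
  set.seed(15)
  cl1 <- cbind(rnorm(12, 0, 0.03), rnorm(12, 0, 0.03))
  leg <- cbind(seq(0.1, 1.9, length.out = 6), seq(0.1, 1.9, length.out = 6))
  cl2 <- cbind(2 + rnorm(12, 0, 0.03), 2 + rnorm(12, 0, 0.03))
  pts <- rbind(cl1, leg, cl2)
  tr_t2 <- as.POSIXct("2013-01-01", tz = "UTC") + 3600 * seq_len(nrow(pts))
  res2 <- fpt_variance_filter(pts[, 1], pts[, 2], tr_t2)
  expect_true(res2$keep_fishing)
  expect_gt(res2$fpt_var, 0.1)
  # direct variance computation at the argmax radius agrees
  radii <- seq(0.1, 1, length.out = 30)
  best <- which.max(res2$S)
  fpt <- first_passage_times(pts[, 1], pts[, 2], tr_t2, radii[best])
  expect_equal(res2$S[best], var(log(fpt[!is.na(fpt) & fpt > 0])),
               tolerance = 1e-12)

  # degenerate: too few defined FPTs is a conservative non-fishing call
  expect_warning(
    res3 <- fpt_variance_filter(c(0, 0.01, 0.02), c(0, 0, 0),
                                tr_t[1:3]),
    "fewer than")
  expect_false(res3$keep_fishing)
})

test_that("UD correction removes sporadic outliers and honors the full-mass isopleth", {
  set.seed(16)
  lat <- c(rnorm(50, 0, 0.05), 3)
  lon <- c(rnorm(50, 0, 0.05), 3)
  keep <- ud_correct(lat, lon, isopleth = 0.95)
  expect_false(keep[51])               # far outlier relabeled
  expect_gt(mean(keep[1:50]), 0.9)     # cluster core retained
  # independent kernel-sum density: the outlier has the lowest density
  bw <- c(MASS::bandwidth.nrd(lon), MASS::bandwidth.nrd(lat)) / 4
  dens <- sapply(seq_along(lat), function(i)
    mean(dnorm(lon - lon[i], sd = bw[1]) * dnorm(lat - lat[i], sd = bw[2])))
  expect_equal(which.min(dens), 51L)

  expect_true(all(ud_correct(lat, lon, isopleth = 1)))
  expect_message(k2 <- ud_correct(rep(0, 5), rep(0, 5)), "fewer than 10")
  expect_true(all(k2))
  expect_warning(k3 <- ud_correct(rep(1, 20), rep(1, 20)), "degenerate")
  expect_true(all(k3))
})

test_that("pure transit tracks and shore-locked tracks yield no fishing", {
  # straight constant 10 kn transit, 10 days
  hrs <- seq(0, 240, by = 0.2)
  lon <- 10 * 1.852 / 111.32 * hrs     # 10 kn eastward at the equator
  tr <- mk_track(lat = rep(0, length(hrs)), lon = lon, hours = hrs,
                 sog = 10)
  coast <- as_shoreline(lat = 30, lon = 30)    # far away
  tr <- annotate_track(tr, coast)
  expect_true(all(detect_longline(tr) == "NF"))

  # same geometry but hugging the shoreline: forced NF
  coast2 <- as_shoreline(lat = rep(0.01, 200), lon = seq(0, 9, length.out = 200))
  tr2 <- annotate_track(mk_track(lat = rep(0, 300), lon = seq(0, 8, length.out = 300),
                                 hours = seq(0, 299) * 0.8, sog = 3), coast2)
  expect_true(all(tr2$shore_km < 10))
  expect_true(all(detect_longline(tr2) == "NF"))
})

test_that("longline pipeline recovers simulated fishing with high recall and only ever demotes", {
  ll <- simulate_longliner(n_hours = 900, seed = 77)
  coast <- as_shoreline(lat = 30, lon = -120)
  ll <- annotate_track(ll, coast)
  pred <- detect_longline(ll)
  m <- confusion_metrics(pred, ll$label)
  expect_gte(m$specificity, 0.75)      # F recall against simulator truth

  # monotone filtering: disabling the FPT and UD stages can only enlarge
  # the fishing set
  pred_loose <- detect_longline(ll, fpt_var_threshold = -1, ud_isopleth = 1)
  expect_true(all(!(pred == "F" & pred_loose == "NF")))
})

test_that("longline labels are invariant under a constant longitude shift", {
  ll <- simulate_longliner(n_hours = 500, seed = 78)
  coast <- as_shoreline(lat = 30, lon = -120)
  base <- detect_longline(annotate_track(ll, coast))
  shifted <- ll
  shifted$lon <- shifted$lon + 15
  coast2 <- as_shoreline(lat = 30, lon = -105)
  expect_identical(detect_longline(annotate_track(shifted, coast2)), base)
})

test_that("tracks too short to regularize come back all non-fishing", {
  tr <- mk_track(lat = c(0, 0.1), lon = 0, hours = c(0, 2), sog = 3)
  coast <- as_shoreline(lat = 30, lon = 30)
  tr <- annotate_track(tr, coast)
  expect_warning(out <- suppressMessages(detect_longline(tr)), "too short")
  expect_equal(out, c("NF", "NF"))
})
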