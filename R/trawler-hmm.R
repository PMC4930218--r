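# State order is fixed: NF first, F second.  Ties in decoding resolve to
# the earlier index, i.e. toward non-fishing — the conservative call.
.hmm_states <- c("NF", "F")

#' Fit a two-state speed HMM for trawler fishing detection
#'
#' Supervised training from expert-labeled tracks.  The transition matrix
#' is the row-normalized count of consecutive label pairs (pooled across
#' tracks, never across a track boundary), the initial distribution is the
#' empirical state frequency, and the per-state speed emission is either a
#' smoothed binned histogram over `[0, v_max]` or a Gaussian fit.
#'
#' @param tracks a labeled track or list of labeled tracks (every point
#'   labeled `"F"` or `"NF"`).
#' @param emission `"histogram"` (default) or `"gaussian"`.
#' @param w histogram bin width, knots (default 0.5).
#' @param v_max speed cap, knots (default 25.5, the AIS speed-field
#'   saturation convention); faster reports are clipped into the top bin.
#' @param alpha additive smoothing pseudo-count per histogram bin
#'   (default 1).
#' @return An object of class `trawler_hmm` with elements `pi` (initial
#'   distribution), `A` (2x2 transition matrix, rows `from`, columns `to`,
#'   states NF then F) and the emission specification.
#' @export
fit_trawler_hmm <- function(tracks, emission = c("histogram", "gaussian"),
                            w = 0.5, v_max = 25.5, alpha = 1) {
  emission <- match.arg(emission)
  tracks <- .as_track_list(tracks)
  labs <- unlist(lapply(tracks, function(d) d$label))
  sogs <- unlist(lapply(tracks, function(d) d$sog))
  if (anyNA(labs)) stop("fit_trawler_hmm: all points must be labeled")
  for (s in .hmm_states)
    if (!any(labs == s))
      stop("fit_trawler_hmm: no training points for state ", s)
  trans <- matrix(0, 2, 2, dimnames = list(.hmm_states, .hmm_states))
  for (d in tracks) {
    if (nrow(d) < 2L) next           # single-point tracks: no transitions
    from <- d$label[-nrow(d)]
    to <- d$label[-1L]
    for (i in 1:2) for (j in 1:2)
      trans[i, j] <- trans[i, j] +
        sum(from == .hmm_states[i] & to == .hmm_states[j])
  }
  if (sum(trans) == 0) stop("fit_trawler_hmm: no observed transitions")
  A <- trans / pmax(rowSums(trans), 1)
  # a state never seen as a transition source keeps itself
  for (i in 1:2) if (rowSums(trans)[i] == 0) A[i, ] <- c(i == 1, i == 2)
  pi0 <- c(mean(labs == "NF"), mean(labs == "F"))
  names(pi0) <- .hmm_states
  m <- list(pi = pi0, A = A, emission = emission,
            w = w, v_max = v_max, alpha = alpha)
  if (emission == "histogram") {
    breaks <- seq(0, v_max, by = w)
    nb <- length(breaks) - 1L
    mass <- sapply(.hmm_states, function(s) {
      v <- pmin(pmax(sogs[labs == s], 0), v_max)
      cnt <- tabulate(pmin(floor(v / w) + 1L, nb), nbins = nb) + alpha
      cnt / sum(cnt)
    })
    m$breaks <- breaks
    m$mass <- mass                    # nb x 2, columns NF, F
  } else {
    m$mu <- vapply(.hmm_states, function(s) mean(sogs[labs == s]), numeric(1))
    m$sigma <- vapply(.hmm_states, function(s) {
      sd0 <- stats::sd(sogs[labs == s])
      if (is.na(sd0) || sd0 <= 0) 1e-3 else sd0
    }, numeric(1))
  }
  class(m) <- "trawler_hmm"
  m
}

# T x 2 matrix of log emission densities, columns NF, F.  Zero-probability
# observations (possible with alpha = 0) are floored and reported.
.hmm_log_emission <- function(model, sog, floor_log = log(1e-300)) {
  sog <- pmin(pmax(sog, 0), model$v_max)
  if (model$emission == "histogram") {
    nb <- length(model$breaks) - 1L
    bin <- pmin(floor(sog / model$w) + 1L, nb)
    le <- log(model$mass[bin, , drop = FALSE])
  } else {
    le <- cbind(stats::dnorm(sog, model$mu[1], model$sigma[1], log = TRUE),
                stats::dnorm(sog, model$mu[2], model$sigma[2], log = TRUE))
  }
  if (any(!is.finite(le))) {
    message("decode: ", sum(!is.finite(le)),
            " zero-probability emission(s) floored")
    le[!is.finite(le)] <- floor_log
  }
  colnames(le) <- .hmm_states
  le
}

#' Decode fishing states along a track
#'
#' Viterbi decoding returns the jointly most probable state sequence under
#' the fitted model (computed in log space); posterior decoding returns
#' the per-point argmax of the forward-backward marginals.  Ties break
#' toward `"NF"`.
#'
#' @param model a [fit_trawler_hmm()] model.
#' @param track a track object (or data frame with an `sog` column).
#' @param method `"viterbi"` (default) or `"posterior"`.
#' @param floor_log log-emission floor for zero-probability observations.
#' @return Character vector of `"F"`/`"NF"` labels, one per point.
#' @export
decode_trawler <- function(model, track, method = c("viterbi", "posterior"),
                           floor_log = log(1e-300)) {
  method <- match.arg(method)
  stopifnot(inherits(model, "trawler_hmm"))
  sog <- if (is.data.frame(track)) track$sog else as.numeric(track)
  n <- length(sog)
  if (n == 0L) stop("decode_trawler: empty track")
  le <- .hmm_log_emission(model, sog, floor_log)
  lA <- log(model$A)
  lpi <- log(model$pi)
  if (method == "viterbi") {
    delta <- matrix(-Inf, n, 2)
    back <- matrix(1L, n, 2)
    delta[1, ] <- lpi + le[1, ]
    if (n > 1) for (t in 2:n) for (j in 1:2) {
      cand <- delta[t - 1, ] + lA[, j]
      back[t, j] <- which.max(cand)       # ties -> NF (index 1)
      delta[t, j] <- cand[back[t, j]] + le[t, j]
    }
    path <- integer(n)
    path[n] <- which.max(delta[n, ])
    if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
    return(.hmm_states[path])
  }
  post <- .hmm_forward_backward(lpi, lA, le)
  .hmm_states[max.col(post, ties.method = "first")]
}

# Scaled forward-backward; returns n x 2 posterior state marginals.
.hmm_forward_backward <- function(lpi, lA, le) {
  n <- nrow(le)
  A <- exp(lA)
  f <- matrix(0, n, 2)
  b <- matrix(1, n, 2)
  scale <- numeric(n)
  f[1, ] <- exp(lpi + le[1, ])
  scale[1] <- sum(f[1, ])
  if (scale[1] == 0) { f[1, ] <- 0.5; scale[1] <- 1 }   # fully floored point
  f[1, ] <- f[1, ] / scale[1]
  if (n > 1) for (t in 2:n) {
    f[t, ] <- (f[t - 1, ] %*% A) * exp(le[t, ])
    scale[t] <- sum(f[t, ])
    if (scale[t] == 0) { f[t, ] <- 0.5; scale[t] <- 1 }
    f[t, ] <- f[t, ] / scale[t]
  }
  if (n > 1) for (t in (n - 1):1)
    b[t, ] <- (A %*% (exp(le[t + 1, ]) * b[t + 1, ])) / scale[t + 1]
  post <- f * b
  post / rowSums(post)
}

#' Log joint probability of a state/observation sequence
#'
#' The log of `Pr(S1) Pr(Y1|S1) prod_t Pr(Yt|St) Pr(St|S_{t-1})` — the
#' quantity Viterbi decoding maximizes over state sequences.
#'
#' @param model a [fit_trawler_hmm()] model.
#' @param states character vector of `"F"`/`"NF"`.
#' @param speeds numeric vector of speeds, same length.
#' @param floor_log log-emission floor.
#' @return Log probability (scalar).
#' @export
hmm_log_joint <- function(model, states, speeds, floor_log = log(1e-300)) {
  if (length(states) != length(speeds))
    stop("states and speeds lengths differ")
  if (length(states) < 1L) stop("empty sequence")
  si <- match(states, .hmm_states)
  if (anyNA(si)) stop("states must be 'F' or 'NF'")
  le <- .hmm_log_emission(model, speeds, floor_log)
  n <- length(si)
  lp <- log(model$pi)[si[1]] + le[1, si[1]]
  if (n > 1)
    lp <- lp + sum(log(model$A)[cbind(si[-n], si[-1])] +
                   le[cbind(2:n, si[-1])])
  unname(lp)
}

#' Serialize a trawler HMM to JSON
#'
#' Writes initial distribution, transition matrix and emission
#' specification (bins and masses, or Gaussian moments) at full double
#' precision; [read_hmm()] restores an identical model.
#'
#' @param model a [fit_trawler_hmm()] model.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(model, path) {
  stopifnot(inherits(model, "trawler_hmm"))
  obj <- list(states = .hmm_states, pi = unname(model$pi),
              A = unname(model$A), emission = model$emission,
              w = model$w, v_max = model$v_max, alpha = model$alpha)
  if (model$emission == "histogram") {
    obj$breaks <- model$breaks
    obj$mass <- unname(model$mass)
  } else {
    obj$mu <- unname(model$mu)
    obj$sigma <- unname(model$sigma)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- list(pi = stats::setNames(as.numeric(obj$pi), .hmm_states),
            A = matrix(as.numeric(obj$A), 2, 2,
                       dimnames = list(.hmm_states, .hmm_states)),
            emission = obj$emission, w = obj$w, v_max = obj$v_max,
            alpha = obj$alpha)
  if (obj$emission == "histogram") {
    m$breaks <- as.numeric(obj$breaks)
    m$mass <- matrix(as.numeric(obj$mass), ncol = 2,
                     dimnames = list(NULL, .hmm_states))
  } else {
    m$mu <- stats::setNames(as.numeric(obj$mu), .hmm_states)
    m$sigma <- stats::setNames(as.numeric(obj$sigma), .hmm_states)
  }
  class(m) <- "trawler_hmm"
  m
}
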