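#' Confusion metrics for fishing/non-fishing labels
#'
#' Per-class confusion statistics using the reporting convention of
#' fisheries activity-detection validation tables: the non-fishing class
#' plays the "positive" role, so *sensitivity* is the recall of NF,
#' *specificity* the recall of F, and `prediction_NF` / `prediction_F` are
#' the class-wise precisions (how often a predicted label is right —
#' the expected performance on unseen data).  Ratios with a zero
#' denominator (e.g. specificity when the truth contains no fishing) are
#' reported as `NA`.
#'
#' @param pred,truth equal-length character vectors of `"F"`/`"NF"`.
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `prediction_F`, `prediction_NF`,
#'   `auc` (balanced accuracy of the hard labels), `pct_fishing`
#'   (truth fishing fraction) and `n`.
#' @export
confusion_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  n <- length(pred)
  if (n < 1L) stop("empty label vectors")
  if (!all(pred %in% c("F", "NF")) || !all(truth %in% c("F", "NF")))
    stop("labels must be 'F' or 'NF'")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  tp_nf <- sum(pred == "NF" & truth == "NF")
  tp_f <- sum(pred == "F" & truth == "F")
  sens <- rat(tp_nf, sum(truth == "NF"))     # NF recall
  spec <- rat(tp_f, sum(truth == "F"))       # F recall
  out <- list(
    accuracy = (tp_nf + tp_f) / n,
    sensitivity = sens,
    specificity = spec,
    prediction_F = rat(tp_f, sum(pred == "F")),
    prediction_NF = rat(tp_nf, sum(pred == "NF")),
    auc = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    pct_fishing = mean(truth == "F"),
    n = n)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("n=%d  accuracy=%.3f  Pred(F)=%s  Pred(NF)=%s  ",
                     "sensitivity=%s  specificity=%s  %%F=%.3f\n"),
              x$n, x$accuracy,
              ifelse(is.na(x$prediction_F), "--", sprintf("%.3f", x$prediction_F)),
              ifelse(is.na(x$prediction_NF), "--", sprintf("%.3f", x$prediction_NF)),
              ifelse(is.na(x$sensitivity), "--", sprintf("%.3f", x$sensitivity)),
              ifelse(is.na(x$specificity), "--", sprintf("%.3f", x$specificity)),
              x$pct_fishing))
  invisible(x)
}

#' Area under the ROC curve for a binary detector
#'
#' For hard `"F"`/`"NF"` predictions, the trapezoid through the single
#' operating point: `(specificity + sensitivity) / 2` (balanced
#' accuracy).  When `scores` is supplied instead (higher = more fishing),
#' the rank-based (Mann-Whitney) AUC with the half-tie convention.
#' `NA` when the truth contains a single class.
#'
#' @param pred character predictions, or `NULL` when using `scores`.
#' @param truth character truth labels.
#' @param scores optional numeric scores for the fishing class.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
auc_binary <- function(pred, truth, scores = NULL) {
  if (!all(truth %in% c("F", "NF"))) stop("labels must be 'F' or 'NF'")
  n_f <- sum(truth == "F")
  n_nf <- sum(truth == "NF")
  if (n_f == 0 || n_nf == 0) return(NA_real_)
  if (!is.null(scores)) {
    if (length(scores) != length(truth)) stop("scores and truth lengths differ")
    r <- rank(scores)
    return((sum(r[truth == "F"]) - n_f * (n_f + 1) / 2) / (n_f * n_nf))
  }
  m <- confusion_metrics(pred, truth)
  (m$sensitivity + m$specificity) / 2
}

#' Fishing-effort event durations
#'
#' Tags fishing periods at the label change points and returns, for each
#' maximal run of `"F"` labels, the time difference in hours between its
#' first and last report.  Single-point events have duration 0.
#'
#' @param labels character `"F"`/`"NF"` vector.
#' @param times POSIXct (or numeric seconds) aligned with `labels`.
#' @return Numeric vector of event durations, hours (possibly empty).
#' @export
fishing_effort <- function(labels, times) {
  if (length(labels) != length(times)) stop("labels and times lengths differ")
  if (!length(labels)) return(numeric(0))
  tt <- as.numeric(times)
  r <- rle(labels == "F")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  f <- which(r$values)
  (tt[ends[f]] - tt[starts[f]]) / 3600
}

#' Compare predicted and true fishing effort
#'
#' Welch two-sample t-test between the per-event duration lists extracted
#' from the predicted and the reference labels; a significant difference
#' (p < 0.05) means the detector's effort distribution departs from the
#' reference.  Sides with fewer than 2 events yield `NA` (not testable).
#'
#' @param pred,truth character label vectors.
#' @param times aligned time vector.
#' @return Object of class `effort_comparison`: list with `effort_pred`,
#'   `effort_true` (duration vectors, hours), `t_stat`, `p_value`,
#'   `significant`.
#' @export
compare_effort <- function(pred, truth, times) {
  ep <- fishing_effort(pred, times)
  et <- fishing_effort(truth, times)
  t_stat <- NA_real_
  p <- NA_real_
  if (length(ep) >= 2 && length(et) >= 2 &&
      (stats::var(ep) > 0 || stats::var(et) > 0)) {
    ht <- stats::t.test(ep, et, var.equal = FALSE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  } else if (length(ep) >= 2 && length(et) >= 2) {
    # both duration lists constant: no sampling variance to test against
    d <- mean(ep) - mean(et)
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  }
  structure(list(effort_pred = ep, effort_true = et,
                 t_stat = t_stat, p_value = p,
                 significant = !is.na(p) && p < 0.05),
            class = "effort_comparison")
}

#' Monte Carlo sliding-window experiment
#'
#' Assesses a trainable detector under time variation: for each training
#' size, `n_windows` window start offsets are drawn (one per equal
#' stratum of the feasible range, so successive windows dislocate forward
#' and test stretches are not reused), the detector is trained on
#' `[s, s + train)` and evaluated on the following `test_size` points.
#' Sizes too large for the data are scaled down proportionally with a
#' warning.
#'
#' @param track a labeled track (or data frame with `sog`, `label`, `t`).
#' @param trainer function(train_df) returning a function(test_df) that
#'   yields `"F"`/`"NF"` labels — e.g. wrap [fit_trawler_hmm()] +
#'   [decode_trawler()].
#' @param train_sizes integer vector of training-window sizes.
#' @param test_size points predicted "in the future" after each training
#'   window (default 100000).
#' @param n_windows windows per training size (default 20).
#' @param seed RNG seed; results are reproducible per seed.
#' @return Data frame with one row per (train_size, window): accuracy,
#'   sensitivity, specificity, auc; plus a `"summary"` attribute of
#'   per-size means and sds.
#' @export
monte_carlo <- function(track, trainer, train_sizes,
                        test_size = 100000, n_windows = 20, seed = 1) {
  set.seed(seed)
  n <- nrow(track)
  rows <- list()
  for (tr in train_sizes) {
    tr_i <- tr
    te_i <- test_size
    if (tr_i + te_i > n) {
      f <- n / (tr_i + te_i)
      tr_i <- max(2L, floor(tr_i * f))
      te_i <- max(1L, n - tr_i)
      warning("monte_carlo: window sizes scaled down to train=", tr_i,
              " test=", te_i, " for n=", n)
    }
    max_start <- n - tr_i - te_i + 1L
    # one start per stratum: windows dislocate forward through the track
    edges <- floor(seq(1, max_start + 1, length.out = n_windows + 1))
    starts <- vapply(seq_len(n_windows), function(k) {
      lo <- edges[k]
      hi <- max(lo, edges[k + 1] - 1L)
      if (hi > lo) sample(lo:hi, 1L) else lo
    }, numeric(1))
    for (w in seq_len(n_windows)) {
      s <- starts[w]
      train <- track[s:(s + tr_i - 1L), , drop = FALSE]
      test <- track[(s + tr_i):(s + tr_i + te_i - 1L), , drop = FALSE]
      if (length(unique(train$label)) < 2L) {
        message("monte_carlo: window ", w, " at size ", tr,
                " skipped (single-class training data)")
        next
      }
      predict_fun <- trainer(train)
      pred <- predict_fun(test)
      m <- confusion_metrics(pred, test$label)
      rows[[length(rows) + 1L]] <-
        data.frame(train_size = tr, window = w, start = s,
                   accuracy = m$accuracy, sensitivity = m$sensitivity,
                   specificity = m$specificity, auc = m$auc)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(train_size = numeric(0), window = integer(0),
               start = integer(0), accuracy = numeric(0),
               sensitivity = numeric(0), specificity = numeric(0),
               auc = numeric(0))
  agg <- NULL
  if (nrow(out)) {
    agg <- do.call(rbind, lapply(split(out, out$train_size), function(d)
      data.frame(train_size = d$train_size[1], n_windows = nrow(d),
                 mean_accuracy = mean(d$accuracy), sd_accuracy = stats::sd(d$accuracy),
                 mean_sensitivity = mean(d$sensitivity, na.rm = TRUE),
                 mean_specificity = mean(d$specificity, na.rm = TRUE),
                 mean_auc = mean(d$auc, na.rm = TRUE))))
    rownames(agg) <- NULL
  }
  attr(out, "summary") <- agg
  out
}

#' Convenience trainer for [monte_carlo()]: speed HMM
#'
#' Returns a `trainer` closure fitting [fit_trawler_hmm()] on the training
#' window and decoding the test window.
#'
#' @param ... passed to [fit_trawler_hmm()].
#' @param method decoding method.
#' @return A function suitable as the `trainer` argument of
#'   [monte_carlo()].
#' @export
hmm_trainer <- function(..., method = "viterbi") {
  function(train_df) {
    model <- fit_trawler_hmm(train_df, ...)
    function(test_df) decode_trawler(model, test_df, method = method)
  }
}
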