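test_that("confusion metrics follow the NF-positive reporting convention", {
  pred <- c("NF", "NF", "F", "F", "F", "NF")
  truth <- c("NF", "F", "F", "F", "NF", "NF")
  m <- confusion_metrics(pred, truth)
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$sensitivity, 2 / 3)       # NF recall
  expect_equal(m$specificity, 2 / 3)       # F recall
  expect_equal(m$prediction_F, 2 / 3)
  expect_equal(m$prediction_NF, 2 / 3)
  expect_equal(m$pct_fishing, 0.5)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # all-NF truth and prediction: specificity and Prediction(F) undefined
  allnf <- confusion_metrics(rep("NF", 5), rep("NF", 5))
  expect_equal(allnf$sensitivity, 1)
  expect_true(is.na(allnf$specificity))
  expect_true(is.na(allnf$prediction_F))

  expect_error(confusion_metrics("F", c("F", "NF")), "lengths differ")
  expect_error(confusion_metrics(c("F", "X"), c("F", "NF")), "labels")
})

test_that("metrics agree with direct confusion-count arithmetic on random labels", {
  set.seed(61)
  for (k in 1:20) {
    pred <- sample(c("F", "NF"), 200, replace = TRUE)
    truth <- sample(c("F", "NF"), 200, replace = TRUE, prob = c(0.3, 0.7))
    m <- confusion_metrics(pred, truth)
    tp <- sum(pred == "F" & truth == "F")
    tn <- sum(pred == "NF" & truth == "NF")
    fp <- sum(pred == "F" & truth == "NF")
    fn <- sum(pred == "NF" & truth == "F")
    expect_equal(m$accuracy, (tp + tn) / 200)
    expect_equal(m$specificity, tp / (tp + fn))
    expect_equal(m$sensitivity, tn / (tn + fp))
    expect_equal(m$prediction_F, tp / (tp + fp))
    expect_equal(m$prediction_NF, tn / (tn + fn))
    # accuracy decomposition identity
    expect_equal(m$accuracy,
                 m$pct_fishing * m$specificity +
                   (1 - m$pct_fishing) * m$sensitivity,
                 tolerance = 1e-12)
  }
})

test_that("binary AUC is balanced accuracy for hard labels and rank-based for scores", {
  truth <- c("F", "F", "NF", "NF", "NF")
  expect_equal(auc_binary(truth, truth), 1)
  expect_equal(auc_binary(rep("NF", 5), truth), 0.5)   # chance line
  expect_true(is.na(auc_binary(rep("NF", 3), rep("NF", 3))))

  set.seed(62)
  for (k in 1:20) {
    truth <- sample(c("F", "NF"), 50, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- rnorm(50)
    # direct Mann-Whitney pair count with half ties
    sf <- scores[truth == "F"]
    snf <- scores[truth == "NF"]
    pairs <- outer(sf, snf, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_binary(NULL, truth, scores = scores), mean(pairs),
                 tolerance = 1e-12)
  }
})

test_that("fishing effort extracts per-event first-to-last durations", {
  t0 <- as.POSIXct("2013-01-01", tz = "UTC")
  expect_equal(fishing_effort(c("F", "F", "F", "NF"), t0 + 3600 * (0:3)),
               2.0)
  expect_equal(fishing_effort(rep("NF", 4), t0 + 3600 * (0:3)), numeric(0))
  # two separated runs + a single-point event
  labs <- c("F", "F", "NF", "NF", "F", "F", "F", "NF", "F")
  times <- t0 + 3600 * c(0, 1.5, 2, 3, 10, 11, 12.25, 13, 20)
  expect_equal(fishing_effort(labs, times), c(1.5, 2.25, 0))
  # total effort never exceeds the track span
  set.seed(63)
  for (k in 1:20) {
    labs <- sample(c("F", "NF"), 50, replace = TRUE)
    times <- t0 + sort(runif(50, 0, 1e6))
    expect_lte(sum(fishing_effort(labs, times)),
               diff(range(as.numeric(times))) / 3600)
  }
})

test_that("effort comparison runs a Welch t-test with NA degenerate sides", {
  t0 <- as.POSIXct("2013-01-01", tz = "UTC")
  labs <- c("F", "F", "NF", "F", "F", "F", "NF", "F", "F")
  times <- t0 + 3600 * c(0, 2, 3, 5, 6, 7.5, 8, 10, 14)
  same <- compare_effort(labs, labs, times)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # truth with no fishing at all: not testable
  none <- compare_effort(labs, rep("NF", 9), times)
  expect_true(is.na(none$p_value))

  # two fixed duration lists on a shared hourly grid vs the textbook
  # Welch formula
  grid <- 0:59
  runs_pred <- list(c(0, 1), c(3, 5), c(7, 10), c(12, 17))
  runs_true <- list(c(20, 22), c(24, 28), c(30, 36), c(38, 46), c(48, 57))
  lab_from <- function(runs) {
    l <- rep("NF", length(grid))
    for (r in runs) l[grid >= r[1] & grid <= r[2]] <- "F"
    l
  }
  ep <- vapply(runs_pred, diff, numeric(1))    # 1 2 3 5
  et <- vapply(runs_true, diff, numeric(1))    # 2 4 6 8 9
  cmp <- compare_effort(lab_from(runs_pred), lab_from(runs_true),
                        t0 + 3600 * grid)
  # oracle: Welch statistic from first principles
  s2p <- var(ep) / length(ep)
  s2t <- var(et) / length(et)
  t_ref <- (mean(ep) - mean(et)) / sqrt(s2p + s2t)
  df_ref <- (s2p + s2t)^2 / (s2p^2 / (length(ep) - 1) + s2t^2 / (length(et) - 1))
  expect_equal(cmp$effort_pred, ep)
  expect_equal(cmp$t_stat, t_ref, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-12)
})

test_that("Monte Carlo windows are counted, seeded and perfect on separable data", {
  # perfectly separable synthetic speeds
  set.seed(64)
  n <- 9000
  lab <- sample(c("F", "NF"), n, replace = TRUE, prob = c(0.4, 0.6))
  sog <- ifelse(lab == "F", runif(n, 2.5, 5.0), runif(n, 9, 15))
  tr <- mk_track(lat = seq(0, 1, length.out = n), lon = 0,
                 hours = seq_len(n) / 12, sog = sog, label = lab)
  res <- monte_carlo(tr, hmm_trainer(), train_sizes = c(1000, 2000),
                     test_size = 3000, n_windows = 5, seed = 3)
  expect_equal(nrow(res), 10)                     # windows per size respected
  expect_equal(as.integer(table(res$train_size)), c(5L, 5L))
  expect_true(all(res$accuracy == 1))
  smry <- attr(res, "summary")
  expect_equal(smry$mean_accuracy, c(1, 1))
  # per-size means lie within the per-window range
  for (sz in unique(res$train_size)) {
    d <- res[res$train_size == sz, ]
    expect_gte(smry$mean_accuracy[smry$train_size == sz], min(d$accuracy))
    expect_lte(smry$mean_accuracy[smry$train_size == sz], max(d$accuracy))
  }
  res2 <- monte_carlo(tr, hmm_trainer(), train_sizes = c(1000, 2000),
                      test_size = 3000, n_windows = 5, seed = 3)
  expect_identical(res, res2)
  # oversized windows are scaled down with a warning
  expect_warning(monte_carlo(tr[1:500, ], hmm_trainer(), train_sizes = 400,
                             test_size = 300, n_windows = 2, seed = 1),
                 "scaled down")
})
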