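# Alarm rule, prediction time, metric identities, evaluation protocols.

test_that("alarm counter triggers exactly at the alarm length", {
  expect_false(alarmScan(c(rep(2, 29), 1), alarmLen = 30)$alert)
  s <- alarmScan(rep(2, 40), alarmLen = 30)
  expect_true(s$alert)
  expect_identical(s$triggerIndex, 30L)            # 0-based index 29
  s2 <- alarmScan(c(rep(2, 10), 1, rep(2, 30), 1, 1), alarmLen = 30)
  expect_identical(s2$triggerIndex, 41L)           # 0-based index 40
  expect_error(alarmScan(c(1, 2, 3), 5), "label")
})

test_that("alarm scan agrees with the counter-simulation oracle on random streams", {
  set.seed(60)
  for (i in 1:1000) {
    len <- sample(5:80, 1)
    stream <- sample(1:2, len, replace = TRUE, prob = c(0.3, 0.7))
    al <- sample(2:12, 1)
    got <- alarmScan(stream, al)
    want <- oracleAlarm(stream, al)
    expect_identical(got$triggerIndex, want)
    expect_identical(got$alert, !is.na(want))
  }
})

test_that("prediction time follows T = s * (n + 1)", {
  expect_equal(predictionTime(674, 674, s = 4), 4)     # alert at final window
  expect_equal(predictionTime(674, 501, s = 4), 696)   # n = 173
  expect_equal(predictionTime(100, 60, s = 8),
               2 * predictionTime(100, 60, s = 4))
  expect_error(predictionTime(10, 11), "triggerIndex")
})

test_that("metric identities hold exactly for arbitrary counts", {
  set.seed(61)
  for (i in 1:20) {
    k <- sample(0:30, 4, replace = TRUE)
    m <- evaluationMetrics(k[1], k[2], k[3], k[4])
    tp <- k[1]; fp <- k[2]; tn <- k[3]; fn <- k[4]
    if (tp + tn + fp + fn > 0) {
      expect_equal(m$accuracy, (tp + tn) / (tp + tn + fp + fn))
    }
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (2 * tp + fp + fn > 0) expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("cross-validation separates separable features and stays at chance on shuffled labels", {
  set.seed(62)
  X <- rbind(matrix(rnorm(200), 100, 2), matrix(rnorm(200, 8), 100, 2))
  y <- rep(c(1L, 2L), each = 100)
  cv <- tenfoldCv(X, y, M = 30, seed = 3)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$f1, 1)
  with(cv$counts, expect_equal(tp + tn + fp + fn, 200))

  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    tenfoldCv(X, sample(y), M = 30, seed = s)$accuracy
  }, numeric(1))
  half <- qbinom(c(0.025, 0.975), 200, 0.5) / 200
  expect_gt(mean(accs >= half[1] & accs <= half[2]), 0.7)
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("group-level folds keep rows of one segment on one side of each split", {
  set.seed(63)
  groups <- rep(1:8, each = 10)
  labels <- rep(rep(c(1L, 2L), 4), each = 10)
  fold <- dfntensor:::makeFolds(labels, 4, seed = 5, groups = groups)
  for (g in unique(groups)) {
    expect_length(unique(fold[groups == g]), 1L)
  }
})

test_that("leave-one-segment-out scores alarms per segment", {
  set.seed(64)
  # degenerate feature streams: class fully encoded in the features
  mkSeg <- function(mu, n = 40) matrix(rnorm(2 * n, mu), n, 2)
  segF <- c(lapply(1:3, function(i) mkSeg(0)), lapply(1:3, function(i) mkSeg(6)))
  labels <- rep(c(1L, 2L), each = 3)
  out <- leaveOneSegmentOut(segF, labels, alarmLen = 10, sSeconds = 4,
                            M = 20, seed = 6)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
  # every prediction time obeys T = s*(n+1) with the stream length used
  for (tr in out$trace) {
    if (isTRUE(tr$alert) && tr$label == 2) {
      expect_gte(tr$triggerIndex, 10)
      expect_lte(tr$triggerIndex, tr$nUnits)
    }
  }
  expect_equal(out$meanPredictionTimeS, mean(out$predictionTimesS))
})

test_that("degenerate constant classifiers give one-sided sensitivity/specificity", {
  # constant-1 streams: no alert ever -> sensitivity 0, specificity 1
  # constant-2 streams: alert always -> sensitivity 1, specificity 0
  # enforced through feature geometry: all segments identical per class swap
  tally <- function(streams, labels, alarmLen) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(streams)) {
      alert <- alarmScan(streams[[i]], alarmLen)$alert
      if (labels[i] == 2) { if (alert) tp <- tp + 1 else fn <- fn + 1 }
      else { if (alert) fp <- fp + 1 else tn <- tn + 1 }
    }
    evaluationMetrics(tp, fp, tn, fn)
  }
  labels <- c(1L, 1L, 2L, 2L)
  m1 <- tally(replicate(4, rep(1L, 50), simplify = FALSE), labels, 10)
  expect_equal(m1$sensitivity, 0); expect_equal(m1$specificity, 1)
  m2 <- tally(replicate(4, rep(2L, 50), simplify = FALSE), labels, 10)
  expect_equal(m2$sensitivity, 1); expect_equal(m2$specificity, 0)
})
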