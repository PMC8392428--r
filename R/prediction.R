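# Alarm rule, evaluation protocols and prediction time.

#' Consecutive-detection alarm scan
#'
#' A counter starts at 0, increments on every pre-ictal label (2) and resets
#' to 0 on every inter-ictal label (1). The alert triggers at the first
#' position where the counter reaches `alarmLen`; scanning stops there.
#'
#' @param labelStream vector over \{1, 2\}, in temporal order.
#' @param alarmLen number of consecutive pre-ictal detections required
#'   (default 30).
#' @return list with `alert` (logical), `triggerIndex` (1-based position
#'   where the counter reached `alarmLen`, or `NA`) and `alarmLen`.
#' @export
alarmScan <- function(labelStream, alarmLen = 30L) {
  stopifnot(length(labelStream) >= 1, alarmLen >= 1)
  if (!all(labelStream %in% c(1, 2))) {
    stop("label stream may only contain 1 (inter-ictal) and 2 (pre-ictal)")
  }
  runs <- rle(labelStream == 2)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= alarmLen)
  if (length(hit) == 0) {
    return(list(alert = FALSE, triggerIndex = NA_integer_,
                alarmLen = as.integer(alarmLen)))
  }
  start <- ends[hit[1]] - runs$lengths[hit[1]] + 1L
  list(alert = TRUE, triggerIndex = as.integer(start + alarmLen - 1L),
       alarmLen = as.integer(alarmLen))
}

#' Prediction time of a triggered alert
#'
#' `T = s * (n + 1)` where `n` is the number of sliding windows not yet
#' processed when the alert fires (`totalWindows - triggerIndex` with a
#' 1-based trigger index) and `s` is the step size in seconds.
#'
#' @param totalWindows length of the label stream for the segment.
#' @param triggerIndex 1-based index where the alert fired.
#' @param s step size in seconds (4 s per correlation window; one tensor
#'   step, `stride * stepS`, when the stream is per-tensor).
#' @return prediction time in seconds (always >= `s`).
#' @export
predictionTime <- function(totalWindows, triggerIndex, s = 4) {
  stopifnot(triggerIndex >= 1, triggerIndex <= totalWindows, s > 0)
  n <- totalWindows - triggerIndex
  s * (n + 1)
}

#' Classification metrics from confusion counts
#'
#' Positive class is pre-ictal (label 2).
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `f1` and the
#'   counts.
#' @export
evaluationMetrics <- function(tp, fp, tn, fn) {
  div <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    accuracy = div(tp + tn, tp + tn + fp + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    f1 = div(2 * tp, 2 * tp + fp + fn),
    counts = list(tp = tp, fp = fp, tn = tn, fn = fn)
  )
}

# Stratified fold assignment. With `groups`, whole groups (segments) are
# dealt to folds so that rows of one recording never straddle the
# train/test split of a fold.
makeFolds <- function(labels, nFolds, seed, groups = NULL) {
  n <- length(labels)
  fold <- integer(n)
  if (is.null(groups)) {
    withSeed(seed, {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(nFolds), length(idx))
      }
    })
  } else {
    stopifnot(length(groups) == n)
    ug <- unique(groups)
    glab <- labels[match(ug, groups)]
    gfold <- integer(length(ug))
    withSeed(seed, {
      for (cl in unique(glab)) {
        idx <- sample(which(glab == cl))
        gfold[idx] <- rep_len(seq_len(nFolds), length(idx))
      }
    })
    fold <- gfold[match(groups, ug)]
  }
  fold
}

#' Stratified ten-fold cross-validated classification
#'
#' Within every training fold the regularization parameter is selected by
#' PRESS leave-one-out ([selectRegularization()]) before training; metrics
#' are pooled over folds. When `groups` is supplied (one id per row, e.g.
#' the source segment), folds are assigned at the group level so that rows
#' of one recording never appear on both sides of a split.
#'
#' @param features N x d feature matrix.
#' @param labels length-N labels over \{1, 2\}; at least `nFolds` rows per
#'   class (or groups per class) are required.
#' @param M hidden neurons for the ELM.
#' @param Egrid regularization grid.
#' @param seed integer seed (fold assignment and hidden layers).
#' @param groups optional group id per row for group-level folding.
#' @param nFolds number of folds (default 10).
#' @return an [evaluationMetrics()] list with an extra `nFolds` element.
#' @export
tenfoldCv <- function(features, labels, M = 100L, Egrid = 2^seq(-10, 10, 2),
                      seed = 1L, groups = NULL, nFolds = 10L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  units <- if (is.null(groups)) labels else labels[match(unique(groups), groups)]
  if (min(table(units)) < nFolds && is.null(groups)) {
    stop(sprintf("need at least %d samples per class", nFolds))
  }
  fold <- makeFolds(labels, nFolds, childSeed(seed, 7L), groups)
  tp <- fp <- tn <- fn <- 0
  for (k in seq_len(nFolds)) {
    test <- which(fold == k)
    if (length(test) == 0) next
    train <- which(fold != k)
    if (length(unique(labels[train])) < 2) {
      stop("a training fold contains a single class; reduce nFolds")
    }
    sk <- childSeed(seed, 100L + k)
    E <- selectRegularization(features[train, , drop = FALSE], labels[train],
                              M = M, Egrid = Egrid, seed = sk)
    model <- elmTrain(features[train, , drop = FALSE], labels[train],
                      M = M, E = as.numeric(E), seed = sk)
    pred <- elmPredict(model, features[test, , drop = FALSE])
    truth <- labels[test]
    tp <- tp + sum(pred == 2 & truth == 2)
    fp <- fp + sum(pred == 2 & truth == 1)
    tn <- tn + sum(pred == 1 & truth == 1)
    fn <- fn + sum(pred == 1 & truth == 2)
  }
  out <- evaluationMetrics(tp, fp, tn, fn)
  out$nFolds <- nFolds
  dfnLog("%d-fold CV: accuracy %.3f", nFolds, out$accuracy)
  out
}

# Shared leave-one-segment-out core. `getFeatures(holdOut)` must return the
# per-segment feature matrices computed WITHOUT any use of the held-out
# segment's identity beyond exclusion from training (fold bookkeeping is
# asserted by construction: the training rows are all segments but holdOut).
losoCore <- function(getFeatures, labels, alarmLen, sSeconds, M, Egrid,
                     seed) {
  nSeg <- length(labels)
  stopifnot(nSeg >= 2)
  tp <- fp <- tn <- fn <- 0
  ptimes <- numeric(0)
  trace <- vector("list", nSeg)
  for (i in seq_len(nSeg)) {
    train <- setdiff(seq_len(nSeg), i)
    if (length(unique(labels[train])) < 2) {
      warning("training fold for segment ", i,
              " contains a single class; segment skipped")
      next
    }
    feats <- getFeatures(i)
    trainX <- do.call(rbind, feats[train])
    trainY <- rep(labels[train], vapply(feats[train], nrow, 1L))
    sk <- childSeed(seed, 200L + i)
    E <- selectRegularization(trainX, trainY, M = M, Egrid = Egrid,
                              seed = sk)
    model <- elmTrain(trainX, trainY, M = M, E = as.numeric(E), seed = sk)
    stream <- elmPredict(model, feats[[i]])
    scan <- alarmScan(stream, alarmLen)
    if (labels[i] == 2) {
      if (scan$alert) {
        tp <- tp + 1
        ptimes <- c(ptimes, predictionTime(length(stream),
                                           scan$triggerIndex, sSeconds))
      } else fn <- fn + 1
    } else {
      if (scan$alert) fp <- fp + 1 else tn <- tn + 1
    }
    trace[[i]] <- list(segment = i, label = labels[i], alert = scan$alert,
                       triggerIndex = scan$triggerIndex,
                       nUnits = length(stream))
  }
  out <- evaluationMetrics(tp, fp, tn, fn)
  out$meanPredictionTimeS <- if (length(ptimes)) mean(ptimes) else NA_real_
  out$predictionTimesS <- ptimes
  out$trace <- trace
  out
}

#' Leave-one-segment-out alarm prediction on precomputed features
#'
#' Each segment in turn is held out; the ELM is trained on all other
#' segments' feature rows, the held-out segment's rows are classified in
#' temporal order, and the alarm rule is applied. A pre-ictal segment counts
#' as correct (TP) iff an alert triggers; an inter-ictal segment counts as
#' correct (TN) iff no alert triggers. The mean prediction time averages
#' over correctly predicted pre-ictal segments only.
#'
#' Use this entry point for feature families that do not depend on the
#' training fold (degree, clustering); for tensor features, whose reference
#' decomposition must be refit inside each fold, use [losoTensor()].
#'
#' @param segFeatures list of per-segment feature matrices (rows in temporal
#'   order).
#' @param labels one label per segment, over \{1, 2\}; both classes needed.
#' @param alarmLen consecutive detections required for an alert.
#' @param sSeconds duration of one stream unit in seconds.
#' @param M,Egrid,seed ELM parameters, as in [tenfoldCv()].
#' @return an [evaluationMetrics()] list with `meanPredictionTimeS` and a
#'   per-segment `trace`.
#' @export
leaveOneSegmentOut <- function(segFeatures, labels, alarmLen = 30L,
                               sSeconds = 4, M = 100L,
                               Egrid = 2^seq(-10, 10, 2), seed = 1L) {
  stopifnot(length(segFeatures) == length(labels))
  losoCore(function(i) segFeatures, labels, alarmLen, sSeconds, M, Egrid,
           seed)
}

#' Leave-one-segment-out alarm prediction with tensor features
#'
#' As [leaveOneSegmentOut()], but the partially-fixed CP features are rebuilt
#' inside every fold: the reference tensor is the first tensor of the first
#' *training* segment in catalog order, so the held-out segment never
#' influences its own training fold. Reference fits are cached by reference
#' segment, of which there are at most two (the first catalog segment, and
#' the second for the fold that holds the first out).
#'
#' @param segTensors list (one per segment) of lists of network tensors.
#' @param labels one label per segment.
#' @param errThresh,Rmax rank-search parameters ([selectRank()]).
#' @inheritParams leaveOneSegmentOut
#' @return as [leaveOneSegmentOut()], plus `referenceR`, the rank(s) used.
#' @export
losoTensor <- function(segTensors, labels, errThresh = 0.05, Rmax = 100L,
                       alarmLen = 30L, sSeconds = 12, M = 100L,
                       Egrid = 2^seq(-10, 10, 2), seed = 1L) {
  stopifnot(length(segTensors) == length(labels))
  cache <- new.env(parent = emptyenv())
  ranks <- integer(0)
  getFeatures <- function(holdOut) {
    refSeg <- if (holdOut == 1L) 2L else 1L
    key <- as.character(refSeg)
    if (is.null(cache[[key]])) {
      ref <- fitReference(segTensors[[refSeg]][[1]], errThresh = errThresh,
                          seed = childSeed(seed, 300L), Rmax = Rmax)
      feats <- lapply(segTensors, featureMatrix, Afixed = ref$A,
                      Bfixed = ref$B)
      cache[[key]] <- list(ref = ref, feats = feats)
      ranks[[key]] <<- ref$R
    }
    cache[[key]]$feats
  }
  out <- losoCore(getFeatures, labels, alarmLen, sSeconds, M, Egrid, seed)
  out$referenceR <- ranks
  out
}
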