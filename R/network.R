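# Functional brain network construction: sliding windows, Pearson
# correlation, significance threshold, binarization.

#' Cut a segment into semi-overlapping windows
#'
#' Windows start at 0, `stepS`, `2*stepS`, ... seconds; trailing samples that
#' do not fill a whole window are dropped, so the count is
#' `floor((durationS - windowS) / stepS) + 1`.
#'
#' @param segment an [EegSegment-class].
#' @param windowS window length in seconds (default 8).
#' @param stepS step between window starts in seconds (default 4).
#' @return list of channels x samples matrices; each carries attributes
#'   `index` (1-based window position) and `startS`.
#' @export
slidingWindows <- function(segment, windowS = 8, stepS = 4) {
  stopifnot(windowS > 0, stepS > 0)
  fs <- samplingRate(segment)
  x <- eegData(segment)
  wlen <- round(windowS * fs)
  step <- round(stepS * fs)
  if (ncol(x) < wlen) {
    stop(sprintf("segment (%d samples) shorter than one %g-s window",
                 ncol(x), windowS))
  }
  nWin <- (ncol(x) - wlen) %/% step + 1L
  lapply(seq_len(nWin), function(i) {
    s0 <- (i - 1L) * step
    w <- x[, (s0 + 1L):(s0 + wlen), drop = FALSE]
    attr(w, "index") <- i
    attr(w, "startS") <- s0 / fs
    w
  })
}

#' Pearson correlation matrix of one window
#'
#' Entry (i, j) is the Pearson product-moment correlation of channels i and j
#' over the window. Channels with zero variance get correlation 0 with every
#' other channel (logged), so flat channels become isolated nodes rather than
#' errors; the diagonal is always 1.
#'
#' @param window channels x samples numeric matrix.
#' @return symmetric channels x channels correlation matrix.
#' @export
correlationMatrix <- function(window) {
  stopifnot(is.matrix(window), nrow(window) >= 2)
  sds <- apply(window, 1L, stats::sd)
  ok <- sds > 0
  n <- nrow(window)
  R <- diag(1, n)
  dimnames(R) <- list(rownames(window), rownames(window))
  if (sum(ok) >= 2) {
    R[ok, ok] <- stats::cor(t(window[ok, , drop = FALSE]))
  }
  if (any(!ok)) {
    dfnLog("zero-variance channel(s) %s: correlations set to 0",
           paste(which(!ok), collapse = ","))
    diag(R) <- 1
  }
  R
}

#' Statistical significance threshold for correlation binarization
#'
#' `Th = 1 - (1 - alpha)^(1 / (L - 1))` where `alpha` is the required
#' confidence level and `L` is the average number of disjoint sections the
#' recording is divided into.
#'
#' @param alpha confidence level in (0, 1); default 0.95.
#' @param L number of disjoint sections, integer >= 2.
#' @return the threshold, a value in (0, 1).
#' @examples
#' significanceThreshold(0.95, 2)    # 0.95
#' significanceThreshold(0.95, 337)  # ~ 0.00888
#' @export
significanceThreshold <- function(alpha = 0.95, L = 337) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (L < 2) stop("L must be an integer >= 2")
  1 - (1 - alpha)^(1 / (L - 1))
}

#' Binarize a correlation matrix into a functional brain network
#'
#' An edge is present when the correlation clears the significance threshold.
#' The default rule thresholds the magnitude, `|r| > Th` (strong negative
#' coupling counts as a connection); `rule = "signed"` applies the literal
#' `r > Th`. The diagonal is forced to zero: self-correlation is always 1 and
#' the degree counts neighbor nodes only.
#'
#' @param corr symmetric correlation matrix.
#' @param th threshold in (0, 1), from [significanceThreshold()].
#' @param rule "magnitude" (default) or "signed".
#' @return binary symmetric adjacency matrix with zero diagonal.
#' @export
binarize <- function(corr, th, rule = c("magnitude", "signed")) {
  rule <- match.arg(rule)
  if (!(th > 0 && th < 1)) stop("threshold must lie in (0, 1)")
  if (max(abs(corr - t(corr))) > 1e-9) {
    stop("correlation matrix is not symmetric")
  }
  a <- if (rule == "magnitude") (abs(corr) > th) * 1 else (corr > th) * 1
  diag(a) <- 0
  a <- (a + t(a)) / 2  # exact symmetry despite fp asymmetry below 1e-9
  a[a > 0] <- 1
  validateAdjacency(a)
  a
}

# Adjacency invariants, asserted on every construction.
validateAdjacency <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  invisible(TRUE)
}

#' Adjacency matrix series for one segment
#'
#' Convenience wrapper: windows the segment, computes a correlation matrix per
#' window, and binarizes each at the given threshold.
#'
#' @inheritParams slidingWindows
#' @inheritParams binarize
#' @return list of binary adjacency matrices, one per window.
#' @export
adjacencySeries <- function(segment, windowS = 8, stepS = 4,
                            th = significanceThreshold(),
                            rule = c("magnitude", "signed")) {
  rule <- match.arg(rule)
  wins <- slidingWindows(segment, windowS, stepS)
  dfnLog("adjacency series: %d windows of %g s (step %g s), Th=%.4g",
         length(wins), windowS, stepS, th)
  lapply(wins, function(w) binarize(correlationMatrix(w), th, rule))
}
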