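# Band splitting with a Fourier-transform (bin-zeroing) filter.

#' Canonical EEG band definitions
#'
#' The five classical bands plus the unfiltered signal:
#' delta 0.5-4, theta 4-8, alpha 8-15, beta 15-30, gamma 30-60 Hz.
#' Shared edges are assigned half-open, `[fLo, fHi)`, except the topmost
#' (gamma) band which is closed at 60 Hz, so the five bands tile
#' \[0.5, 60\] Hz without double counting. The DC bin is excluded from every
#' filtered band.
#'
#' @return data frame with columns `band`, `fLo`, `fHi` (NA for "raw").
#' @export
bandDefinitions <- function() {
  data.frame(
    band = c("delta", "theta", "alpha_band", "beta", "gamma", "raw"),
    fLo = c(0.5, 4, 8, 15, 30, NA),
    fHi = c(4, 8, 15, 30, 60, NA),
    stringsAsFactors = FALSE
  )
}

#' Fourier-transform bandpass filter
#'
#' Per channel: take the DFT, zero every bin whose frequency magnitude lies
#' outside the band, inverse-transform, and return the real part. Zeroing is
#' applied symmetrically to positive and negative frequencies, so the filter
#' has exactly zero phase distortion. Band membership is `fLo <= |f| < fHi`
#' (closed at the top for the gamma band); the DC bin is always removed.
#'
#' @param segment an [EegSegment-class].
#' @param band band name from [bandDefinitions()], or "raw" for the identity.
#' @param fLo,fHi explicit band edges in Hz (override `band`).
#' @return a filtered [EegSegment-class] of the same shape, tagged with the
#'   band name.
#' @examples
#' seg <- EegSegment(matrix(sin(2 * pi * 10 * (0:2047) / 256),
#'                          nrow = 1, ncol = 2048, byrow = TRUE), fs = 256)
#' alpha <- fftBandpass(seg, "alpha_band")   # 10 Hz is interior: passes
#' @export
fftBandpass <- function(segment, band = NULL, fLo = NULL, fHi = NULL) {
  stopifnot(is(segment, "EegSegment"))
  fs <- samplingRate(segment)
  closedTop <- FALSE
  if (!is.null(band)) {
    if (band == "raw") return(segment)
    defs <- bandDefinitions()
    i <- match(band, defs$band)
    if (is.na(i)) stop("unknown band: ", band)
    fLo <- defs$fLo[i]; fHi <- defs$fHi[i]
    closedTop <- band == "gamma"
  }
  if (is.null(fLo) || is.null(fHi) || fLo >= fHi || fLo < 0) {
    stop("invalid band edges")
  }
  if (fHi > fs / 2) {
    stop(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz", fHi, fs / 2))
  }
  x <- eegData(segment)
  n <- ncol(x)
  if (n < 2) stop("segment must have at least 2 samples")
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # frequency magnitude per DFT bin
  keep <- if (closedTop) freqs >= fLo & freqs <= fHi else
    freqs >= fLo & freqs < fHi
  keep[1] <- FALSE  # DC always excluded from filtered bands
  X <- t(stats::mvfft(t(x)))
  X[, !keep] <- 0
  y <- Re(t(stats::mvfft(t(X), inverse = TRUE))) / n
  dimnames(y) <- dimnames(x)
  EegSegment(y, fs = fs, label = segmentLabel(segment),
             band = if (is.null(band)) sprintf("%g-%gHz", fLo, fHi) else band)
}

#' Split a segment into the five bands plus raw
#'
#' @param segment an [EegSegment-class] (unfiltered).
#' @return named list of six [EegSegment-class] objects: delta, theta,
#'   alpha_band, beta, gamma, raw.
#' @export
splitBands <- function(segment) {
  defs <- bandDefinitions()
  out <- lapply(defs$band, function(b) fftBandpass(segment, band = b))
  names(out) <- defs$band
  dfnLog("split segment into %d bands", length(out))
  out
}
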