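# Synthetic multichannel EEG with controllable, band-limited, class- and
# time-dependent inter-channel coupling.
#
# Each channel mixes a small set of shared narrowband oscillators (one per
# canonical frequency band) into independent broadband noise. The coupling
# envelope scales the shared part; a nonzero drift rate makes it grow
# linearly in time, emulating the coupling build-up of the pre-ictal state.

#' The 23-channel bipolar scalp montage used as the default channel list
#'
#' Standard 10-20 bipolar derivations as used by the CHB-MIT scalp EEG
#' recordings.
#'
#' @return character vector of 23 channel labels.
#' @export
chbChannels <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3", "C3-P3",
    "P3-O1", "FP2-F4", "F4-C4", "C4-P4", "P4-O2", "FP2-F8", "F8-T8",
    "T8-P8", "P8-O2", "FZ-CZ", "CZ-PZ", "P7-T7", "T7-FT9", "FT9-FT10",
    "FT10-T8", "T8-P8-2")
}

#' Coupling specification for the synthetic EEG generator
#'
#' @param nChannels number of channels (default 23).
#' @param fs sampling rate in Hz (default 256).
#' @param nSources number of shared latent oscillators.
#' @param bandCenters center frequency of each source in Hz; defaults place
#'   one source in each canonical band (delta, theta, alpha, beta, gamma).
#' @param couplingStrength shared-source mixing scale in \[0, 1\].
#' @param driftRate per-second linear change of the coupling strength
#'   (nonzero models pre-ictal coupling build-up); the envelope is clamped
#'   to \[0, 1\].
#' @param noiseSd per-channel broadband noise standard deviation (> 0).
#' @param sourceScale amplitude of a fully-coupled unit-variance source
#'   relative to the noise; the default 0.4 keeps shared components a small
#'   fraction of channel variance, as for scalp EEG.
#' @param mixingRange range of the uniform per-channel, per-source mixing
#'   weights drawn once per segment.
#' @param seed integer seed.
#' @return a list of class `"CouplingSpec"`.
#' @export
couplingSpec <- function(nChannels = 23, fs = 256, nSources = 5,
                         bandCenters = c(2, 6, 11.5, 22, 40),
                         couplingStrength = 0.2, driftRate = 0,
                         noiseSd = 1, sourceScale = 0.4,
                         mixingRange = c(0.2, 1), seed = 1L) {
  stopifnot(couplingStrength >= 0, couplingStrength <= 1, noiseSd > 0,
            all(bandCenters > 0), all(bandCenters < fs / 2),
            length(bandCenters) == nSources)
  structure(list(
    nChannels = nChannels, fs = fs, nSources = nSources,
    bandCenters = bandCenters, couplingStrength = couplingStrength,
    driftRate = driftRate, noiseSd = noiseSd, sourceScale = sourceScale,
    mixingRange = mixingRange, seed = as.integer(seed)
  ), class = "CouplingSpec")
}

# One unit-variance narrowband source: a random-phase sinusoid at the center
# frequency plus noise band-limited to center +/- 1 Hz.
makeSource <- function(n, fs, center) {
  t <- (seq_len(n) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  sine <- sqrt(2) * sin(2 * pi * center * t + phase)
  lo <- max(center - 1, 0.1)
  hi <- min(center + 1, fs / 2)
  nb <- eegData(fftBandpass(EegSegment(matrix(stats::rnorm(n), 1), fs = fs),
                            fLo = lo, fHi = hi))[1, ]
  nbsd <- stats::sd(nb)
  if (nbsd > 0) nb <- nb / nbsd
  (sine + nb) / sqrt(2)
}

#' Generate one synthetic EEG segment
#'
#' Each channel is `noiseSd * eps_c(t) + sourceScale * sum_s m_cs * g(t) *
#' source_s(t)` where the mixing weights `m` are drawn once per segment under
#' the spec seed and the coupling envelope `g(t)` is the clamped linear drift
#' `couplingStrength + driftRate * t`. The whole matrix is then scaled into a
#' +/- 95 microvolt range (a global gain, so correlations are untouched) to
#' exercise realistic EDF quantization.
#'
#' @param spec a [couplingSpec()].
#' @param durationS segment length in seconds; must cover at least one
#'   analysis window (`minDurationS`).
#' @param label class label: 1 (inter-ictal) or 2 (pre-ictal).
#' @param minDurationS shortest admissible duration (default 8 s, one
#'   correlation window).
#' @return an [EegSegment-class] with `chbChannels()`-style row names when
#'   `nChannels` is 23.
#' @export
generateSegment <- function(spec, durationS, label, minDurationS = 8) {
  stopifnot(inherits(spec, "CouplingSpec"))
  if (durationS < minDurationS) {
    stop(sprintf("durationS=%g s is shorter than one %g-s window",
                 durationS, minDurationS))
  }
  n <- round(durationS * spec$fs)
  withSeed(spec$seed, {
    m <- matrix(stats::runif(spec$nChannels * spec$nSources,
                             spec$mixingRange[1], spec$mixingRange[2]),
                spec$nChannels, spec$nSources)
    sources <- vapply(spec$bandCenters,
                      function(f) makeSource(n, spec$fs, f), numeric(n))
    tSec <- (seq_len(n) - 1) / spec$fs
    env <- pmin(pmax(spec$couplingStrength + spec$driftRate * tSec, 0), 1)
    shared <- m %*% t(sources * env)  # envelope applied samplewise
    x <- shared * spec$sourceScale +
      matrix(stats::rnorm(spec$nChannels * n, sd = spec$noiseSd),
             spec$nChannels, n)
    x <- x * (95 / max(abs(x)))
    rownames(x) <- if (spec$nChannels == 23) chbChannels() else
      sprintf("CH%02d", seq_len(spec$nChannels))
    EegSegment(x, fs = spec$fs, label = as.integer(label))
  })
}

#' Generate a labeled catalog of synthetic EDF segments
#'
#' Writes `2 * nPerClass` EDF files (balanced inter-ictal / pre-ictal) plus a
#' `catalog.csv`, with per-segment seeds derived deterministically from
#' `seed`.
#'
#' @param nPerClass segments per class (>= 1).
#' @param specInter,specPre [couplingSpec()]s for the inter-ictal and
#'   pre-ictal classes (their `seed` fields are overridden per segment).
#' @param durationS segment length in seconds.
#' @param outDir output directory (created if needed).
#' @param seed master seed for segment-seed derivation.
#' @return the catalog data frame (columns `file_path`, `start_s`,
#'   `duration_s`, `label`), invisibly also written to
#'   `file.path(outDir, "catalog.csv")`.
#' @export
generateCatalog <- function(nPerClass, specInter, specPre, durationS,
                            outDir, seed = 1L) {
  stopifnot(nPerClass >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0L
  for (i in seq_len(nPerClass)) {
    for (label in c(1L, 2L)) {
      k <- k + 1L
      spec <- if (label == 1L) specInter else specPre
      spec$seed <- childSeed(seed, k)
      seg <- generateSegment(spec, durationS, label)
      path <- file.path(outDir, sprintf("seg_%03d_label%d.edf", k, label))
      writeEdf(seg, path)
      rows[[k]] <- data.frame(file_path = path, start_s = 0,
                              duration_s = durationS, label = label,
                              stringsAsFactors = FALSE)
    }
  }
  catalog <- do.call(rbind, rows)
  writeCatalog(catalog, file.path(outDir, "catalog.csv"))
  dfnLog("catalog: %d segments of %g s in %s", nrow(catalog), durationS,
         outDir)
  catalog
}
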