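# Minimal EDF (European Data Format) writer and reader.
#
# EDF stores an ASCII header (256 bytes + 256 bytes per signal) followed by
# fixed-duration data records of 2-byte little-endian integers, one block per
# signal per record. Physical values are mapped linearly onto the 16-bit
# digital range, so a write/read round trip is exact up to the quantization
# step (physMax - physMin) / (digMax - digMin).

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

# 8-char ASCII numeric field. The value the reader parses is exactly the
# written string, so scaling is self-consistent by construction.
edfNum <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  edfPad(s, width)
}

#' Write an EEG segment to an EDF file
#'
#' Writes one data record per second (samples-per-record = `fs`). Each
#' channel gets a symmetric physical range covering its extrema, mapped onto
#' the full signed 16-bit digital range.
#'
#' @param segment an [EegSegment-class]; duration must be a whole number of
#'   seconds and all samples finite.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readEdf()], [readSegment()]
#' @export
writeEdf <- function(segment, path) {
  stopifnot(is(segment, "EegSegment"))
  x <- eegData(segment)
  fs <- samplingRate(segment)
  if (!all(is.finite(x))) {
    stop("segment contains non-finite sample values; refusing to write EDF")
  }
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  if (ncol(x) %% fs != 0) {
    stop("EDF writer requires a whole number of 1-s records (samples %% fs == 0)")
  }
  ns <- nrow(x)
  nrec <- ncol(x) %/% fs
  digMin <- -32768L; digMax <- 32767L
  physMax <- pmax(apply(abs(x), 1L, max), 1e-6)
  physMin <- -physMax
  # re-parse the header strings so writer and reader share the same range
  pminS <- vapply(physMin, edfNum, "")
  pmaxS <- vapply(physMax, edfNum, "")
  physMin <- as.numeric(pminS); physMax <- as.numeric(pmaxS)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8),
    edfPad("X X X X", 80),
    edfPad("Startdate X X X X", 80),
    edfPad("01.01.00", 8),
    edfPad("00.00.00", 8),
    edfPad(256L * (ns + 1L), 8),
    edfPad("", 44),
    edfPad(nrec, 8),
    edfPad("1", 8),
    edfPad(ns, 4))
  labels <- rownames(x)
  sigHdr <- paste0(
    paste(vapply(labels, edfPad, "", width = 16), collapse = ""),
    paste(rep(edfPad("", 80), ns), collapse = ""),
    paste(rep(edfPad("uV", 8), ns), collapse = ""),
    paste(pminS, collapse = ""),
    paste(pmaxS, collapse = ""),
    paste(rep(edfPad(digMin, 8), ns), collapse = ""),
    paste(rep(edfPad(digMax, 8), ns), collapse = ""),
    paste(rep(edfPad("", 80), ns), collapse = ""),
    paste(rep(edfPad(fs, 8), ns), collapse = ""),
    paste(rep(edfPad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sigHdr), con, eos = NULL)

  scale <- (digMax - digMin) / (physMax - physMin)
  dig <- round((x - physMin) * scale + digMin)
  dig <- pmin(pmax(dig, digMin), digMax)
  # interleave: per record, all samples of signal 1, then signal 2, ...
  idx <- integer(0)
  out <- matrix(0L, nrow = ns * fs, ncol = nrec)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    out[, r] <- as.integer(t(dig[, cols, drop = FALSE]))
  }
  writeBin(as.vector(out), con, size = 2L, endian = "little")
  dfnLog("wrote EDF %s: %d channels, %d records @ %g Hz", path, ns, nrec, fs)
  invisible(path)
}

# Parse the EDF header into a list.
readEdfHeader <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdrBytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) trimws(vapply(seq_len(ns), function(i) rd(w), ""))
  labels <- fld(16); fld(80); fld(8)
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  list(version = trimws(ver), headerBytes = hdrBytes, nRecords = nrec,
       recordDuration = recDur, nSignals = ns, labels = labels,
       physMin = physMin, physMax = physMax, digMin = digMin,
       digMax = digMax, samplesPerRecord = spr)
}

#' Read channels from an EDF file
#'
#' @param path EDF file.
#' @param channels character vector of channel labels to extract, in the
#'   desired row order; `NULL` reads all channels in file order.
#' @param startS offset of the first sample to keep, in seconds.
#' @param durationS length to keep, in seconds; `NULL` reads to the end.
#' @param label optional class label attached to the result.
#' @param band band tag for the result (default "raw").
#' @return an [EegSegment-class] holding the requested window.
#' @export
readEdf <- function(path, channels = NULL, startS = 0, durationS = NULL,
                    label = NA_integer_, band = "raw") {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readEdfHeader(con)
  if (is.null(channels)) channels <- h$labels
  sel <- match(channels, h$labels)
  if (anyNA(sel)) {
    stop("channel(s) not present in ", path, ": ",
         paste(channels[is.na(sel)], collapse = ", "))
  }
  fsAll <- h$samplesPerRecord / h$recordDuration
  fs <- fsAll[sel[1]]
  if (any(fsAll[sel] != fs)) {
    stop("selected channels have differing sampling rates")
  }
  totalRaw <- sum(h$samplesPerRecord) * h$nRecords
  dat <- readBin(con, "integer", n = totalRaw, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(dat) < totalRaw) stop("truncated EDF file: ", path)
  offs <- cumsum(c(0L, h$samplesPerRecord))
  recLen <- sum(h$samplesPerRecord)
  nTotal <- h$samplesPerRecord[sel[1]] * h$nRecords
  if (is.null(durationS)) durationS <- nTotal / fs - startS
  i0 <- round(startS * fs); n <- round(durationS * fs)
  if (n <= 0) stop("requested duration must be positive")
  if (i0 + n > nTotal) {
    stop(sprintf("requested window [%g, %g) s exceeds recording length %g s",
                 startS, startS + durationS, nTotal / fs))
  }
  out <- matrix(NA_real_, length(sel), n, dimnames = list(channels, NULL))
  for (j in seq_along(sel)) {
    s <- sel[j]; spr <- h$samplesPerRecord[s]
    pick <- as.vector(outer(seq_len(spr), (seq_len(h$nRecords) - 1L) * recLen,
                            `+`) + offs[s])
    sig <- dat[pick][(i0 + 1L):(i0 + n)]
    gain <- (h$physMax[s] - h$physMin[s]) / (h$digMax[s] - h$digMin[s])
    out[j, ] <- (sig - h$digMin[s]) * gain + h$physMin[s]
  }
  dfnLog("read EDF %s: %d channels x %d samples @ %g Hz", path,
         nrow(out), ncol(out), fs)
  EegSegment(out, fs = fs, label = label, band = band)
}

#' Read the segment described by one catalog record
#'
#' A segment catalog is a data frame with columns `file_path`, `start_s`,
#' `duration_s` and `label` (1 = inter-ictal, 2 = pre-ictal); see
#' [readCatalog()]. The configured channel list fixes both the montage and
#' the row order of the returned matrix.
#'
#' @param record one-row data frame (or list) with the catalog fields.
#' @param channels character vector of required channel names.
#' @param fs expected sampling rate in Hz; a mismatch is an error.
#' @return an [EegSegment-class].
#' @export
readSegment <- function(record, channels, fs = 256) {
  stopifnot(record$duration_s > 0, record$label %in% c(1, 2))
  seg <- readEdf(record$file_path, channels = channels,
                 startS = record$start_s, durationS = record$duration_s,
                 label = as.integer(record$label))
  if (samplingRate(seg) != fs) {
    stop(sprintf("sampling rate mismatch in %s: found %g Hz, expected %g Hz",
                 record$file_path, samplingRate(seg), fs))
  }
  seg
}

#' Read / write a segment catalog CSV
#'
#' @param path CSV file with columns `file_path`, `start_s`, `duration_s`,
#'   `label`.
#' @return `readCatalog`: a data frame of segment records.
#' @export
readCatalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file_path", "start_s", "duration_s", "label")
  if (!all(need %in% names(cat))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  }
  cat
}

#' @rdname readCatalog
#' @param catalog data frame of segment records.
#' @export
writeCatalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE)
  invisible(path)
}
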