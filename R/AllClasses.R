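#' @import methods
NULL

#' EegSegment: one multichannel EEG recording segment
#'
#' A channels x samples real matrix with its sampling rate, an optional class
#' label (1 = inter-ictal, 2 = pre-ictal) and a band tag recording which
#' frequency band the signal has been restricted to ("raw" for unfiltered).
#' Channel names are the matrix row names.
#'
#' @slot data numeric matrix, channels in rows, samples in columns.
#' @slot fs sampling rate in Hz.
#' @slot label integer, 1 (inter-ictal), 2 (pre-ictal) or NA when unlabeled.
#' @slot band character tag, one of the names returned by [bandDefinitions()].
#'
#' @seealso [EegSegment()] for construction, [fftBandpass()], [splitBands()],
#'   [slidingWindows()].
#' @export
setClass("EegSegment",
  representation(
    data = "matrix",
    fs = "numeric",
    label = "integer",
    band = "character"
  )
)

setValidity("EegSegment", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) {
    msg <- c(msg, "data must be a numeric matrix")
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (length(object@label) != 1L ||
      (!is.na(object@label) && !object@label %in% c(1L, 2L))) {
    msg <- c(msg, "label must be 1, 2 or NA")
  }
  if (length(object@band) != 1L) {
    msg <- c(msg, "band must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EegSegment
#'
#' @param data channels x samples numeric matrix; row names are channel names.
#' @param fs sampling rate in Hz.
#' @param label class label: 1 (inter-ictal), 2 (pre-ictal) or NA.
#' @param band band tag; "raw" for unfiltered data.
#' @return an [EegSegment-class] object.
#' @examples
#' seg <- EegSegment(matrix(rnorm(23 * 256), 23), fs = 256)
#' nChannels(seg)
#' @export
EegSegment <- function(data, fs, label = NA_integer_, band = "raw") {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (is.null(rownames(data))) {
    rownames(data) <- sprintf("CH%02d", seq_len(nrow(data)))
  }
  new("EegSegment", data = data, fs = as.numeric(fs),
      label = as.integer(label), band = as.character(band))
}

#' @describeIn EegSegment-class signal matrix (channels x samples)
#' @param object,x an `EegSegment`
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @rdname EegSegment-class
#' @export
setMethod("eegData", "EegSegment", function(object) object@data)

#' @describeIn EegSegment-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EegSegment-class
#' @export
setMethod("samplingRate", "EegSegment", function(object) object@fs)

#' @describeIn EegSegment-class class label (1, 2 or NA)
#' @export
setGeneric("segmentLabel", function(object) standardGeneric("segmentLabel"))
#' @rdname EegSegment-class
#' @export
setMethod("segmentLabel", "EegSegment", function(object) object@label)

#' @describeIn EegSegment-class band tag
#' @export
setGeneric("bandTag", function(object) standardGeneric("bandTag"))
#' @rdname EegSegment-class
#' @export
setMethod("bandTag", "EegSegment", function(object) object@band)

#' @describeIn EegSegment-class number of channels
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname EegSegment-class
#' @export
setMethod("nChannels", "EegSegment", function(object) nrow(object@data))

#' @describeIn EegSegment-class number of samples per channel
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname EegSegment-class
#' @export
setMethod("nSamples", "EegSegment", function(object) ncol(object@data))

#' @describeIn EegSegment-class duration in seconds
#' @export
setGeneric("durationS", function(object) standardGeneric("durationS"))
#' @rdname EegSegment-class
#' @export
setMethod("durationS", "EegSegment",
          function(object) ncol(object@data) / object@fs)

#' @describeIn EegSegment-class channel names
#' @export
setMethod("rownames", "EegSegment", function(x) rownames(x@data))

setMethod("show", "EegSegment", function(object) {
  cat(sprintf(
    "EegSegment: %d channels x %d samples (%.1f s @ %g Hz), band=%s, label=%s\n",
    nrow(object@data), ncol(object@data), durationS(object), object@fs,
    object@band,
    if (is.na(object@label)) "NA" else as.character(object@label)))
})

#' CpFactors: the result of a CP (CANDECOMP/PARAFAC) decomposition
#'
#' Holds factor matrices `A` (I x R), `B` (J x R), `C` (K x R) and the weight
#' vector `lambda` (length R) of the model
#' \eqn{X \approx \sum_{r=1}^R \lambda_r\, a_r \circ b_r \circ c_r}
#' where the columns of A, B, C carry unit 2-norm wherever the corresponding
#' weight is nonzero.
#'
#' @slot A,B,C factor matrices with R columns each.
#' @slot lambda nonnegative weights, one per component.
#' @slot R number of rank-one components.
#' @slot seed integer seed used for the random initialization.
#' @slot errTrace relative reconstruction error after each ALS sweep.
#'
#' @seealso [cpAls()], [selectRank()], [cpRelativeError()]
#' @export
setClass("CpFactors",
  representation(
    A = "matrix", B = "matrix", C = "matrix",
    lambda = "numeric", R = "integer", seed = "integer",
    errTrace = "numeric"
  )
)

setValidity("CpFactors", function(object) {
  msg <- character()
  R <- object@R
  if (ncol(object@A) != R || ncol(object@B) != R || ncol(object@C) != R) {
    msg <- c(msg, "A, B, C must each have R columns")
  }
  if (length(object@lambda) != R) {
    msg <- c(msg, "lambda must have length R")
  }
  if (any(object@lambda < -1e-12)) {
    msg <- c(msg, "lambda must be nonnegative")
  }
  nz <- which(object@lambda > 1e-10)
  for (M in list(object@A, object@B, object@C)) {
    if (length(nz) && any(abs(sqrt(colSums(M[, nz, drop = FALSE]^2)) - 1) > 1e-6)) {
      msg <- c(msg, "factor columns with positive weight must have unit 2-norm")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CpFactors-class channel-mode factor matrix A
#' @param object a `CpFactors`
#' @export
setGeneric("factorA", function(object) standardGeneric("factorA"))
#' @rdname CpFactors-class
#' @export
setMethod("factorA", "CpFactors", function(object) object@A)

#' @describeIn CpFactors-class channel-mode factor matrix B
#' @export
setGeneric("factorB", function(object) standardGeneric("factorB"))
#' @rdname CpFactors-class
#' @export
setMethod("factorB", "CpFactors", function(object) object@B)

#' @describeIn CpFactors-class time-mode factor matrix C
#' @export
setGeneric("factorC", function(object) standardGeneric("factorC"))
#' @rdname CpFactors-class
#' @export
setMethod("factorC", "CpFactors", function(object) object@C)

#' @describeIn CpFactors-class component weights
#' @export
setGeneric("cpWeights", function(object) standardGeneric("cpWeights"))
#' @rdname CpFactors-class
#' @export
setMethod("cpWeights", "CpFactors", function(object) object@lambda)

#' @describeIn CpFactors-class number of components R
#' @export
setGeneric("cpRank", function(object) standardGeneric("cpRank"))
#' @rdname CpFactors-class
#' @export
setMethod("cpRank", "CpFactors", function(object) object@R)

setMethod("show", "CpFactors", function(object) {
  cat(sprintf(
    "CpFactors: R=%d, modes %dx%dx%d, final relative error %.4g\n",
    object@R, nrow(object@A), nrow(object@B), nrow(object@C),
    if (length(object@errTrace)) utils::tail(object@errTrace, 1) else NA_real_))
})

#' ElmModel: a trained extreme learning machine
#'
#' A single-hidden-layer feedforward network whose input weights `W` and
#' biases `b` are drawn randomly once and never trained; the output weights
#' `beta` solve the regularized least-squares problem
#' \eqn{\hat\beta = (H^\top H + E I)^{-1} H^\top Y} (or its M > N dual form)
#' where `H` is the hidden-layer output matrix on the standardized training
#' features.
#'
#' @slot W M x d input weight matrix.
#' @slot b length-M hidden bias vector.
#' @slot beta M x l output weight matrix.
#' @slot activation activation function name (only "sigmoid" implemented).
#' @slot M number of hidden neurons.
#' @slot E regularization parameter used in the ridge solve.
#' @slot trainMean,trainSd per-feature standardization statistics from the
#'   training data.
#' @slot classes class labels in output-column order.
#' @slot seed integer seed for the random hidden layer.
#'
#' @seealso [elmTrain()], [elmPredict()], [selectRegularization()]
#' @export
setClass("ElmModel",
  representation(
    W = "matrix", b = "numeric", beta = "matrix",
    activation = "character", M = "integer", E = "numeric",
    trainMean = "numeric", trainSd = "numeric",
    classes = "integer", seed = "integer"
  )
)

setValidity("ElmModel", function(object) {
  msg <- character()
  if (nrow(object@W) != object@M) msg <- c(msg, "W must have M rows")
  if (length(object@b) != object@M) msg <- c(msg, "b must have length M")
  if (nrow(object@beta) != object@M) msg <- c(msg, "beta must have M rows")
  if (length(object@E) != 1L || object@E <= 0) {
    msg <- c(msg, "E must be a single positive number")
  }
  if (length(object@trainMean) != ncol(object@W) ||
      length(object@trainSd) != ncol(object@W)) {
    msg <- c(msg, "standardization statistics must match input dimension d")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ElmModel", function(object) {
  cat(sprintf(
    "ElmModel: %d hidden neurons (%s), d=%d, E=%g, classes {%s}\n",
    object@M, object@activation, ncol(object@W), object@E,
    paste(object@classes, collapse = ",")))
})
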