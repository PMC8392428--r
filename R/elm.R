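# Regularized extreme learning machine with PRESS leave-one-out selection of
# the regularization parameter.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Hidden-layer output matrix for raw weights (no standardization applied).
hiddenRaw <- function(W, b, X) {
  H <- X %*% t(W)
  sweep(H, 2L, b, "+") |> sigmoid()
}

standardizeApply <- function(X, mu, sd) {
  sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
}

drawHidden <- function(M, d, seed) {
  withSeed(seed, list(
    W = matrix(stats::runif(M * d, -1, 1), M, d),
    b = stats::runif(M, 0, 1)))
}

oneHot <- function(labels, classes = c(1L, 2L)) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Hidden-layer output matrix of an ELM
#'
#' `H[i, j] = g(w_j . x_i + b_j)` with the logistic sigmoid activation. The
#' rows of `X` are used as given (no standardization), matching the model
#' definition; [elmPredict()] standardizes internally before calling this.
#'
#' @param model an [ElmModel-class].
#' @param X N x d feature matrix.
#' @return N x M matrix.
#' @export
hiddenMatrix <- function(model, X) {
  stopifnot(is(model, "ElmModel"))
  if (ncol(X) != ncol(model@W)) {
    stop(sprintf("feature dimension %d does not match model d=%d",
                 ncol(X), ncol(model@W)))
  }
  hiddenRaw(model@W, model@b, X)
}

#' Train a regularized extreme learning machine
#'
#' Labels (1 = inter-ictal, 2 = pre-ictal) are one-hot encoded; features are
#' standardized by the training mean and standard deviation; the input
#' weights are drawn uniformly on \[-1, 1\] (biases on \[0, 1\]) under `seed`
#' and never trained. The output weights solve the ridge problem
#' `beta = (H'H + E I)^{-1} H'Y` when `M <= N`, or the dual form
#' `beta = H'(HH' + E I)^{-1} Y` when `M > N`.
#'
#' @param X N x d feature matrix.
#' @param labels length-N vector over \{1, 2\}; both classes required.
#' @param M number of hidden neurons (default 100).
#' @param E regularization parameter (> 0).
#' @param seed integer seed for the random hidden layer.
#' @return an [ElmModel-class].
#' @export
elmTrain <- function(X, labels, M = 100L, E = 1, seed = 1L) {
  X <- as.matrix(X)
  N <- nrow(X)
  stopifnot(N >= 2, length(labels) == N)
  if (!all(labels %in% c(1, 2))) stop("labels must be 1 or 2")
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes")
  }
  if (E <= 0) stop("regularization parameter E must be positive")
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  Xs <- standardizeApply(X, mu, sd)
  hl <- drawHidden(M, ncol(X), seed)
  H <- hiddenRaw(hl$W, hl$b, Xs)
  Y <- oneHot(labels)
  beta <- if (M <= N) {
    solvePsd(crossprod(H) + E * diag(M), crossprod(H, Y))
  } else {
    t(H) %*% solvePsd(tcrossprod(H) + E * diag(N), Y)
  }
  new("ElmModel", W = hl$W, b = hl$b, beta = beta, activation = "sigmoid",
      M = as.integer(M), E = E, trainMean = mu, trainSd = sd,
      classes = c(1L, 2L), seed = as.integer(seed))
}

#' Predict class labels with a trained ELM
#'
#' `Yhat = H beta`; the label is the argmax over the output columns, mapped
#' back to \{1, 2\}. Ties break toward the lower class index (label 1).
#'
#' @param model an [ElmModel-class].
#' @param X N x d feature matrix.
#' @return integer labels in \{1, 2\}.
#' @export
elmPredict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@W)) {
    stop(sprintf("feature dimension %d does not match model d=%d",
                 ncol(X), ncol(model@W)))
  }
  Xs <- standardizeApply(X, model@trainMean, model@trainSd)
  Yhat <- hiddenMatrix(model, Xs) %*% model@beta
  model@classes[max.col(Yhat, ties.method = "first")]
}

#' Closed-form (PRESS) leave-one-out selection of the regularization
#' parameter
#'
#' For every `E` in the grid the leave-one-out residuals of the ridge output
#' layer are obtained without retraining, from the hat matrix
#' `HAT = H (H'H + E I)^{-1} H'`: `loo_i = residual_i / (1 - HAT_ii)`. The
#' chosen `E` minimizes the mean squared leave-one-out residual pooled over
#' both output columns; ties break toward the smaller `E`. Grid values for
#' which any `1 - HAT_ii` falls below 1e-12 are skipped (logged).
#'
#' @param X N x d feature matrix.
#' @param labels length-N vector over \{1, 2\}.
#' @param M number of hidden neurons.
#' @param Egrid candidate regularization values (default `2^seq(-10, 10, 2)`).
#' @param seed seed for the random hidden layer; use the same seed as the
#'   subsequent [elmTrain()] call so the selection applies to the same
#'   hidden layer.
#' @return the selected `E`, with the per-grid mean squared LOO residuals
#'   attached as attribute `"press"`.
#' @export
selectRegularization <- function(X, labels, M = 100L,
                                 Egrid = 2^seq(-10, 10, 2), seed = 1L) {
  if (length(Egrid) == 0) stop("Egrid must be non-empty")
  X <- as.matrix(X)
  N <- nrow(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  Xs <- standardizeApply(X, mu, sd)
  hl <- drawHidden(M, ncol(X), seed)
  H <- hiddenRaw(hl$W, hl$b, Xs)
  Y <- oneHot(labels)
  Egrid <- sort(Egrid)
  press <- rep(NA_real_, length(Egrid))
  for (k in seq_along(Egrid)) {
    E <- Egrid[k]
    S <- crossprod(H) + E * diag(M)
    HS <- H %*% solvePsd(S, diag(M))
    hat <- rowSums(HS * H)
    if (any(1 - hat < 1e-12)) {
      dfnLog("E=%g skipped: leverage 1 - HAT_ii below 1e-12", E)
      next
    }
    beta <- solvePsd(S, crossprod(H, Y))
    res <- Y - H %*% beta
    press[k] <- mean((res / (1 - hat))^2)
  }
  if (all(is.na(press))) stop("all regularization values were skipped")
  best <- Egrid[which.min(press)]  # which.min takes the first (smallest E)
  dfnLog("selected E=%g (PRESS MSE %.4g)", best, min(press, na.rm = TRUE))
  attr(best, "press") <- stats::setNames(press, Egrid)
  best
}
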