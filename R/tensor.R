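# Dynamic functional brain network tensors and their CP decomposition.
#
# A dynamic network is the third-order binary array obtained by stacking
# consecutive adjacency matrices along the time axis. Features are extracted
# with a CP (CANDECOMP/PARAFAC) model fitted by alternating least squares;
# after one reference decomposition the two channel-mode factor matrices are
# frozen, so every later tensor needs only a closed-form solve for its
# time-mode factor.

#' Stack adjacency matrices into network tensors
#'
#' Tensor t holds slices `[(t-1)*stride + 1, (t-1)*stride + num]`; trailing
#' matrices that do not fill a tensor are dropped, giving
#' `floor((len - num) / stride) + 1` tensors.
#'
#' @param adjSeries list of J x J binary adjacency matrices in time order.
#' @param num number of networks stacked per tensor (3, 4, 5 or 6 in the
#'   reference protocol).
#' @param stride offset between consecutive tensors; default `num`
#'   (disjoint stacks).
#' @return list of J x J x num arrays.
#' @export
stackTensors <- function(adjSeries, num, stride = num) {
  stopifnot(num >= 1, stride >= 1)
  len <- length(adjSeries)
  if (len < num) {
    stop(sprintf("need at least num=%d adjacency matrices, got %d", num, len))
  }
  nT <- (len - num) %/% stride + 1L
  J <- nrow(adjSeries[[1]])
  lapply(seq_len(nT), function(t) {
    i0 <- (t - 1L) * stride
    array(unlist(adjSeries[(i0 + 1L):(i0 + num)]), dim = c(J, J, num))
  })
}

# Khatri-Rao (columnwise Kronecker) product: column r is u_r (x) v_r with
# the U index varying slowest.
khatriRao <- function(U, V) {
  stopifnot(ncol(U) == ncol(V))
  out <- matrix(0, nrow(U) * nrow(V), ncol(U))
  for (r in seq_len(ncol(U))) out[, r] <- kronecker(U[, r], V[, r])
  out
}

# Mode-n unfoldings (columns ordered with earlier remaining modes fastest).
unfold1 <- function(X) matrix(X, dim(X)[1], dim(X)[2] * dim(X)[3])
unfold2 <- function(X) matrix(aperm(X, c(2, 1, 3)), dim(X)[2],
                              dim(X)[1] * dim(X)[3])
unfold3 <- function(X) matrix(aperm(X, c(3, 1, 2)), dim(X)[3],
                              dim(X)[1] * dim(X)[2])

# Exact least-squares factor update via the Moore-Penrose pseudoinverse of
# the (Hadamard-product) Gram matrix; any normal-equation solution minimizes
# the subproblem, which is what ALS monotonicity relies on.
alsUpdate <- function(Xn, Z, G) {
  (Xn %*% Z) %*% pracma::pinv(G)
}

normalizeCols <- function(M) {
  nrm <- sqrt(colSums(M^2))
  scl <- ifelse(nrm > 0, nrm, 1)
  list(M = sweep(M, 2L, scl, "/"), norms = nrm)
}

#' CP decomposition by alternating least squares
#'
#' Fits \eqn{X \approx \sum_{r=1}^R \lambda_r a_r \circ b_r \circ c_r} by
#' cycling exact least-squares updates of A, B and C through the mode-n
#' unfoldings and Khatri-Rao products, until the change in relative
#' reconstruction error drops below `tol` or `maxIter` sweeps. Factors are
#' initialized uniformly on \[0, 1) under `seed` (binary network tensors are
#' nonnegative); on return all columns are normalized to unit 2-norm with the
#' weights absorbed into `lambda`.
#'
#' @param X numeric I x J x K array.
#' @param R number of rank-one components.
#' @param seed integer seed for the random initialization.
#' @param tol stop when the relative error decreases by less than this
#'   between sweeps.
#' @param maxIter maximum number of ALS sweeps.
#' @param init optional list(A, B, C) of starting factors (overrides the
#'   random initialization; used by the warm-started rank search).
#' @return a [CpFactors-class]; slot `errTrace` holds the relative error
#'   after every sweep.
#' @export
cpAls <- function(X, R, seed = 1L, tol = 1e-6, maxIter = 200L, init = NULL) {
  stopifnot(is.array(X), length(dim(X)) == 3, R >= 1)
  d <- dim(X)
  normX <- sqrt(sum(X^2))
  if (normX == 0) {
    U <- matrix(rep(diag(1, d[1])[, 1], R), d[1], R)
    V <- matrix(rep(diag(1, d[2])[, 1], R), d[2], R)
    W <- matrix(rep(diag(1, d[3])[, 1], R), d[3], R)
    return(new(Class = "CpFactors", A = U, B = V, C = W, lambda = rep(0, R),
               R = as.integer(R), seed = as.integer(seed), errTrace = 0))
  }
  X1 <- unfold1(X); X2 <- unfold2(X); X3 <- unfold3(X)
  if (is.null(init)) {
    fac <- withSeed(seed, list(
      A = matrix(stats::runif(d[1] * R), d[1], R),
      B = matrix(stats::runif(d[2] * R), d[2], R),
      C = matrix(stats::runif(d[3] * R), d[3], R)))
  } else {
    fac <- init
  }
  A <- fac$A; B <- fac$B; C <- fac$C
  errTrace <- numeric(0)
  errPrev <- Inf
  for (it in seq_len(maxIter)) {
    GB <- crossprod(B); GC <- crossprod(C)
    A <- alsUpdate(X1, khatriRao(C, B), GC * GB)
    GA <- crossprod(A)
    B <- alsUpdate(X2, khatriRao(C, A), GC * GA)
    GB <- crossprod(B)
    C <- alsUpdate(X3, khatriRao(B, A), GB * GA)
    if (!all(is.finite(A), is.finite(B), is.finite(C))) {
      stop("non-finite values in ALS at iteration ", it)
    }
    # keep scales balanced: push column norms of A and B into C
    nA <- normalizeCols(A); nB <- normalizeCols(B)
    A <- nA$M; B <- nB$M
    C <- sweep(C, 2L, ifelse(nA$norms > 0, nA$norms, 1) *
                 ifelse(nB$norms > 0, nB$norms, 1), "*")
    err <- sqrt(sum((X1 - A %*% t(khatriRao(C, B)))^2)) / normX
    errTrace <- c(errTrace, err)
    if (is.finite(errPrev) && abs(errPrev - err) < tol) break
    errPrev <- err
  }
  nC <- normalizeCols(C)
  lambda <- nC$norms
  new(Class = "CpFactors", A = A, B = B, C = nC$M, lambda = lambda,
      R = as.integer(R), seed = as.integer(seed), errTrace = errTrace)
}

#' Relative reconstruction error of a CP model
#'
#' `||X - Xhat||_F / ||X||_F` with
#' \eqn{\hat X = \sum_r \lambda_r a_r \circ b_r \circ c_r}. A zero tensor
#' with a zero reconstruction has error 0 by convention (and `Inf` against a
#' nonzero reconstruction).
#'
#' @param X numeric 3-way array.
#' @param factors a [CpFactors-class].
#' @return scalar error, >= 0.
#' @export
cpRelativeError <- function(X, factors) {
  stopifnot(is(factors, "CpFactors"))
  d <- dim(X)
  if (nrow(factorA(factors)) != d[1] || nrow(factorB(factors)) != d[2] ||
      nrow(factorC(factors)) != d[3]) {
    stop("tensor and factor shapes do not agree")
  }
  A <- factorA(factors)
  Z <- khatriRao(sweep(factorC(factors), 2L, cpWeights(factors), "*"),
                 factorB(factors))
  res <- sqrt(sum((unfold1(X) - A %*% t(Z))^2))
  normX <- sqrt(sum(X^2))
  if (normX == 0) return(if (res == 0) 0 else Inf)
  res / normX
}

#' Error-driven CP rank selection
#'
#' Starting from R = 1, increases the number of components until the relative
#' reconstruction error of the ALS fit falls below `errThresh`. Successive
#' fits are warm-started: the R-component search is initialized with the
#' accepted (R-1)-component factors plus one fresh random column (weighted
#' zero in the time mode), so the error trace over R is non-increasing.
#'
#' @inheritParams cpAls
#' @param errThresh relative-error target in (0, 1); default 0.05.
#' @param Rmax largest rank tried before the search fails.
#' @return list with elements `R` (selected rank), `factors`
#'   (the accepted [CpFactors-class]) and `errByRank` (error per tried rank).
#' @export
selectRank <- function(X, errThresh = 0.05, seed = 1L, Rmax = 100L,
                       tol = 1e-6, maxIter = 200L) {
  if (!(errThresh > 0 && errThresh < 1)) stop("errThresh must lie in (0, 1)")
  errByRank <- numeric(0)
  prev <- NULL
  for (R in seq_len(Rmax)) {
    init <- NULL
    if (!is.null(prev)) {
      rs <- childSeed(seed, R)
      # the fresh component enters with a small (nonzero) time-mode weight:
      # a zero column would be a degenerate ALS fixed point, while the first
      # factor update can always fall back on the previous solution, so the
      # error trace over R remains non-increasing
      eps <- 1e-2 * max(cpWeights(prev), 1)
      newcols <- withSeed(rs, list(
        a = stats::runif(nrow(factorA(prev))),
        b = stats::runif(nrow(factorB(prev))),
        c = eps * stats::runif(nrow(factorC(prev)))))
      init <- list(
        A = cbind(factorA(prev), newcols$a),
        B = cbind(factorB(prev), newcols$b),
        C = cbind(sweep(factorC(prev), 2L, cpWeights(prev), "*"), newcols$c))
    }
    f <- cpAls(X, R, seed = childSeed(seed, R), tol = tol,
               maxIter = maxIter, init = init)
    err <- cpRelativeError(X, f)
    errByRank <- c(errByRank, err)
    dfnLog("rank search: R=%d relative error %.4g", R, err)
    if (err < errThresh) {
      return(list(R = R, factors = f, errByRank = errByRank))
    }
    prev <- f
  }
  stop(sprintf(
    "rank search failed: error %.4g at Rmax=%d still >= %.3g (trace: %s)",
    utils::tail(errByRank, 1), Rmax, errThresh,
    paste(sprintf("%.3g", errByRank), collapse = " ")))
}

#' Fit the reference decomposition and freeze the channel factors
#'
#' Runs the rank search on the reference tensor (the first tensor of the
#' training set, in catalog order) and returns the two channel-mode factor
#' matrices, which stay fixed for every subsequent feature extraction.
#'
#' @inheritParams selectRank
#' @param X0 the reference tensor.
#' @return list with `A`, `B` (unit-norm columns), `R`, and the full
#'   `factors`.
#' @export
fitReference <- function(X0, errThresh = 0.05, seed = 1L, Rmax = 100L,
                         tol = 1e-6, maxIter = 200L) {
  sel <- selectRank(X0, errThresh = errThresh, seed = seed, Rmax = Rmax,
                    tol = tol, maxIter = maxIter)
  dfnLog("reference decomposition: R=%d", sel$R)
  list(A = factorA(sel$factors), B = factorB(sel$factors), R = sel$R,
       factors = sel$factors)
}

# Precomputed solve operator for the frozen-factor least squares: with
# Z = B (.) A (Khatri-Rao), the minimizing time factor of any tensor is
# C = X_(3) Z (Z^T Z)^+, so P = Z (Z^T Z)^+ is shared by all tensors.
fixedFactorOperator <- function(Afixed, Bfixed) {
  Z <- khatriRao(Bfixed, Afixed)
  G <- crossprod(Z)
  if (qr(G)$rank < ncol(G)) {
    dfnLog("frozen Khatri-Rao product is rank deficient; using pseudoinverse")
  }
  Z %*% pracma::pinv(G)
}

#' Extract the partially-fixed CP feature of one tensor
#'
#' With the channel factors A and B frozen, the best time factor in the
#' Frobenius sense has the closed form `C = X_(3) (B (.) A) ((B (.) A)^T
#' (B (.) A))^+` -- no iteration is needed. The weights are
#' `lambda_r = ||C[, r]||_2`; the matrix F scales the normalized columns of C
#' back by lambda (i.e. F equals the unnormalized solution), and the feature
#' is the column mean of F, a length-R vector.
#'
#' @param X tensor whose channel dimensions match the reference.
#' @param Afixed,Bfixed frozen factor matrices from [fitReference()].
#' @param op optional precomputed operator from repeated calls (internal).
#' @return numeric feature vector of length R, with the weights attached as
#'   attribute `lambda`.
#' @export
extractFeature <- function(X, Afixed, Bfixed, op = NULL) {
  stopifnot(dim(X)[1] == nrow(Afixed), dim(X)[2] == nrow(Bfixed),
            ncol(Afixed) == ncol(Bfixed))
  if (is.null(op)) op <- fixedFactorOperator(Afixed, Bfixed)
  Fmat <- unfold3(X) %*% op            # time x R, lambda-scaled columns
  v <- colMeans(Fmat)
  attr(v, "lambda") <- sqrt(colSums(Fmat^2))
  v
}

#' Feature matrix for a list of tensors
#'
#' @param tensors list of I x J x K arrays (K may vary).
#' @inheritParams extractFeature
#' @return tensors x R numeric matrix, rows in input order.
#' @export
featureMatrix <- function(tensors, Afixed, Bfixed) {
  stopifnot(length(tensors) > 0)
  op <- fixedFactorOperator(Afixed, Bfixed)
  out <- t(vapply(tensors, function(X) {
    as.numeric(extractFeature(X, Afixed, Bfixed, op = op))
  }, numeric(ncol(Afixed))))
  dfnLog("feature matrix: %d x %d", nrow(out), ncol(out))
  out
}
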