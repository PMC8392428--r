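# Extreme learning machine: hidden layer, ridge solution, PRESS selection.

blobs <- function(n = 200, sep = 6, seed = 50) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n), n / 2, 2), matrix(rnorm(n, sep), n / 2, 2))
  list(X = X, y = rep(c(1L, 2L), each = n / 2))
}

test_that("hidden matrix evaluates the sigmoid of w.x + b", {
  model <- elmTrain(matrix(rnorm(20), 10, 2), rep(c(1L, 2L), 5), M = 4,
                    E = 1, seed = 1)
  # zero weights -> g(0) = 0.5 everywhere
  model@W[] <- 0; model@b[] <- 0
  H <- hiddenMatrix(model, matrix(rnorm(6), 3, 2))
  expect_equal(H, matrix(0.5, 3, 4), ignore_attr = TRUE)
  # hand-evaluated entries
  model@W <- matrix(c(1, -2, 0.5, 3), 2, 2)
  model@b <- c(0.25, -1)
  x <- c(0.3, -0.7)
  H2 <- hiddenMatrix(model, matrix(x, 1))
  expect_equal(H2[1, 1], 1 / (1 + exp(-(1 * 0.3 + 0.5 * -0.7 + 0.25))))
  expect_equal(H2[1, 2], 1 / (1 + exp(-(-2 * 0.3 + 3 * -0.7 - 1))))
  expect_equal(dim(hiddenMatrix(model, matrix(rnorm(14), 7, 2))), c(7, 2))
})

test_that("both ridge branches agree through the push-through identity", {
  set.seed(51)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(1L, 2L), 10)
  for (E in c(1e-3, 1, 100)) {
    mP <- elmTrain(X, y, M = 10, E = E, seed = 3)   # M <= N: primal branch
    # dual evaluation of the same problem
    Xs <- scale(X)
    hl <- dfntensor:::drawHidden(10, 2, 3)
    H <- dfntensor:::hiddenRaw(hl$W, hl$b, Xs)
    Y <- dfntensor:::oneHot(y)
    betaDual <- t(H) %*% solve(tcrossprod(H) + E * diag(20), Y)
    expect_equal(mP@beta, betaDual, tolerance = 1e-8, ignore_attr = TRUE)
    # and beta satisfies the normal equations
    res <- (crossprod(H) + E * diag(10)) %*% mP@beta - crossprod(H, Y)
    expect_lt(max(abs(res)) / max(abs(crossprod(H, Y))), 1e-8)
  }
})

test_that("separable blobs and XOR are fit to 100% training accuracy", {
  d <- blobs()
  m <- elmTrain(d$X, d$y, M = 100, E = 1e-6, seed = 4)
  expect_equal(mean(elmPredict(m, d$X) == d$y), 1)

  xorX <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  xorY <- c(1L, 1L, 2L, 2L)
  mx <- elmTrain(xorX, xorY, M = 50, E = 1e-8, seed = 5)  # M > N branch
  expect_equal(elmPredict(mx, xorX), xorY)
})

test_that("prediction is deterministic, tie-broken toward label 1", {
  d <- blobs(n = 40, seed = 52)
  m <- elmTrain(d$X, d$y, M = 20, E = 1, seed = 6)
  p1 <- elmPredict(m, d$X)
  expect_identical(p1, elmPredict(m, d$X))
  expect_identical(elmPredict(m, d$X[c(3, 3), ]),
                   rep(elmPredict(m, d$X[3, , drop = FALSE]), 2))
  # force an exact tie via equal output columns
  m@beta <- cbind(m@beta[, 1], m@beta[, 1])
  expect_true(all(elmPredict(m, d$X) == 1L))
  # errors
  expect_error(elmTrain(d$X, rep(1L, 40), M = 10, E = 1), "both classes")
  expect_error(elmTrain(d$X, d$y, M = 10, E = -1), "positive")
  expect_error(elmPredict(m, matrix(0, 2, 5)), "dimension")
})

test_that("PRESS residuals equal explicitly retrained leave-one-out residuals", {
  set.seed(53)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(1L, 2L), 10)
  M <- 8; seedH <- 7
  Xs <- scale(X)
  hl <- dfntensor:::drawHidden(M, 2, seedH)
  H <- dfntensor:::hiddenRaw(hl$W, hl$b, Xs)
  Y <- dfntensor:::oneHot(y)
  for (E in c(0.01, 1)) {
    S <- crossprod(H) + E * diag(M)
    hat <- rowSums((H %*% solve(S)) * H)
    beta <- solve(S, crossprod(H, Y))
    press <- (Y - H %*% beta) / (1 - hat)
    # oracle: retrain the ridge output layer without row i, predict row i
    looOracle <- matrix(0, 20, 2)
    for (i in 1:20) {
      Hi <- H[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
      bi <- solve(crossprod(Hi) + E * diag(M), crossprod(Hi, Yi))
      looOracle[i, ] <- Y[i, ] - H[i, , drop = FALSE] %*% bi
    }
    expect_equal(press, looOracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("regularization selection minimizes PRESS with ties to smaller E", {
  d <- blobs(n = 60, seed = 54)
  E <- selectRegularization(d$X, d$y, M = 20, Egrid = c(1, 0.01, 100),
                            seed = 8)
  press <- attr(E, "press")
  expect_equal(as.numeric(E),
               as.numeric(names(press)[which.min(press)]))
  single <- selectRegularization(d$X, d$y, M = 20, Egrid = 0.5, seed = 8)
  expect_equal(as.numeric(single), 0.5)
  expect_error(selectRegularization(d$X, d$y, Egrid = numeric(0)), "non-empty")
})

test_that("under pure-noise labels the selected E is usually not the smallest", {
  set.seed(55)
  hits <- 0
  for (rep in 1:20) {
    X <- matrix(rnorm(60), 30, 2)
    y <- sample(rep(c(1L, 2L), 15))
    E <- selectRegularization(X, y, M = 25, Egrid = 2^seq(-10, 10, 2),
                              seed = rep)
    if (as.numeric(E) > 2^-10) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("training accuracy does not increase with stronger regularization", {
  d <- blobs(n = 100, seed = 56)
  accs <- vapply(c(1e-6, 1e-2, 1, 100, 1e4), function(E) {
    m <- elmTrain(d$X, d$y, M = 40, E = E, seed = 9)
    mean(elmPredict(m, d$X) == d$y)
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-12))
})
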