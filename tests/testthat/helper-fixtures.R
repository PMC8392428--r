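# Fixtures and independent oracles used across the suite. Oracles are kept
# deliberately naive (triple loops, explicit retraining, direct counter
# simulation) so they never share code with the implementation they check.

# sine-mixture test segment: one sinusoid per channel at the given
# frequencies (Hz), unit amplitude, with optional noise
sineSegment <- function(freqs, fs = 256, durS = 8, noiseSd = 0, seed = 1) {
  n <- round(durS * fs)
  t <- (seq_len(n) - 1) / fs
  set.seed(seed)
  x <- t(vapply(freqs, function(f) sin(2 * pi * f * t + runif(1, 0, 2 * pi)),
                numeric(n)))
  if (noiseSd > 0) x <- x + matrix(rnorm(length(x), sd = noiseSd), nrow(x))
  EegSegment(x, fs = fs)
}

# random symmetric binary adjacency with zero diagonal
randomAdjacency <- function(n = 23, p = 0.3) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a + t(a)
}

# oracle: degree by explicit neighbor counting
oracleDegree <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) sum(a[i, -i] != 0), numeric(1))
}

# oracle: clustering coefficient by triple enumeration
oracleClustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- setdiff(which(a[i, ] != 0), i)
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (u in seq_along(nb)) {
      for (v in seq_along(nb)) {
        if (u < v && a[nb[u], nb[v]] != 0) e <- e + 1
      }
    }
    2 * e / (k * (k - 1))
  }, numeric(1))
}

# oracle: first index at which `alarmLen` consecutive 2s have been seen,
# by direct counter simulation
oracleAlarm <- function(stream, alarmLen) {
  counter <- 0
  for (i in seq_along(stream)) {
    counter <- if (stream[i] == 2) counter + 1 else 0
    if (counter == alarmLen) return(i)
  }
  NA_integer_
}

# rank-one 3-way tensor from given mode vectors
rankOneTensor <- function(a, b, c) {
  array(outer(outer(a, b), c), dim = c(length(a), length(b), length(c)))
}

# sum of k rank-one tensors whose mode vectors have disjoint support, so the
# construction has CP rank exactly k and rank-(k-1) fits stay far from it
disjointRankK <- function(k, I = 23, J = 23, K = 6, seed = 1) {
  set.seed(seed)
  X <- array(0, c(I, J, K))
  blkI <- split(seq_len(I), ceiling(seq_len(I) * k / I))
  blkJ <- split(seq_len(J), ceiling(seq_len(J) * k / J))
  parts <- vector("list", k)
  for (r in seq_len(k)) {
    a <- numeric(I); a[blkI[[r]]] <- runif(length(blkI[[r]]), 0.5, 1)
    b <- numeric(J); b[blkJ[[r]]] <- runif(length(blkJ[[r]]), 0.5, 1)
    cc <- runif(K, 0.5, 1)
    X <- X + rankOneTensor(a, b, cc)
    parts[[r]] <- list(a = a, b = b, c = cc)
  }
  attr(X, "parts") <- parts
  X
}

# oracle: full CP reconstruction from factors, by explicit summation
oracleReconstruct <- function(A, B, C, lambda = rep(1, ncol(A))) {
  X <- array(0, c(nrow(A), nrow(B), nrow(C)))
  for (r in seq_len(ncol(A))) {
    X <- X + lambda[r] * rankOneTensor(A[, r], B[, r], C[, r])
  }
  X
}

# small synthetic catalog on disk (written once per test run)
makeTestCatalog <- function(nPerClass, durationS, dir, seed = 101,
                            couplingInter = 0.2, couplingPre = 0.8,
                            driftPre = 5e-4) {
  specI <- couplingSpec(couplingStrength = couplingInter)
  specP <- couplingSpec(couplingStrength = couplingPre,
                        driftRate = driftPre)
  generateCatalog(nPerClass, specI, specP, durationS = durationS,
                  outDir = dir, seed = seed)
}
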