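# Internal helpers shared across modules.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; kept strictly below 2^31.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

#' Package-level logging
#'
#' Stages of the pipeline report their parameterization and output shapes
#' through this hook. Logging is off by default; enable with
#' `options(dfntensor.verbose = TRUE)`.
#'
#' @param fmt `sprintf` format string.
#' @param ... values for `fmt`.
#' @return invisibly, the formatted message.
#' @export
dfnLog <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (isTRUE(getOption("dfntensor.verbose", FALSE))) {
    message("[dfntensor] ", msg)
  }
  invisible(msg)
}

# Ridge-free least-squares solve of  G %*% X = Bmat  for symmetric PSD G,
# falling back to the Moore-Penrose pseudoinverse when G is singular.
solvePsd <- function(G, Bmat) {
  out <- tryCatch(solve(G, Bmat), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) {
    out <- pracma::pinv(G) %*% Bmat
  }
  out
}
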