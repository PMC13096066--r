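# Internal helpers shared across modules.

# Evaluate expr with a local RNG state. NULL seed leaves the global stream
# untouched (and uses it), so callers embedded in larger seeded pipelines
# still draw reproducibly.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assertProbability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a probability in [0, 1]")
  invisible(x)
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop("'", name, "' must be an integer >= ", min)
  invisible(as.integer(x))
}

assertPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop("'", name, "' must be a single positive number")
  invisible(x)
}

# FFT-based analytic signal (one real vector in, complex vector out).
analyticSignal <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
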