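#' Estimate the NDTE model order from the autocorrelation first minimum
#'
#' For every region of every trial the sample autocorrelation function is
#' scanned for its first local minimum (the first lag tau with
#' ACF(tau) < ACF(tau + 1) after the initial descent); when no local
#' minimum occurs before `maxLag` the first lag with ACF below 1/e is used
#' instead. The model order is the rounded mean of these per-unit lags --
#' pass a list of `EpochSet`s (e.g. both conditions of all participants) to
#' average across them.
#'
#' @param epochs an [EpochSet-class] or a list of them.
#' @param maxLag largest lag scanned; must be below half the epoch length.
#' @return a [ModelOrder-class].
#' @export
estimateModelOrder <- function(epochs, maxLag = 50L) {
  if (!is.list(epochs)) epochs <- list(epochs)
  maxLag <- assertCount(maxLag, "maxLag", min = 2L)
  if (maxLag >= nSamples(epochs[[1L]]) / 2)
    stop("maxLag must be below half the epoch length")
  lags <- unlist(lapply(epochs, function(es) {
    d <- epochData(es)
    apply(d, c(1L, 2L), function(v) firstAcfMinimum(v, maxLag))
  }))
  fs <- samplingRate(epochs[[1L]])
  lag <- max(1L, as.integer(round(mean(lags))))
  new("ModelOrder", lagSamples = lag, lagMs = lag * 1000 / fs,
      perUnitLags = as.numeric(lags))
}

firstAcfMinimum <- function(x, maxLag) {
  if (stats::sd(x) == 0)
    stop("constant signal: autocorrelation is undefined")
  # unbiased (1/(n - tau)) sample ACF so the taper of the biased estimator
  # does not shift the first minimum of oscillatory signals
  n <- length(x)
  xc <- x - mean(x)
  v <- mean(xc^2)
  a <- vapply(seq_len(maxLag), function(tau)
    sum(xc[seq_len(n - tau)] * xc[(tau + 1L):n]) / ((n - tau) * v),
    numeric(1L))
  for (tau in seq_len(maxLag - 1L)) if (a[tau] < a[tau + 1L]) return(tau)
  below <- which(a < exp(-1))
  if (length(below)) below[1L] else maxLag
}

#' Differential entropy of a multivariate Gaussian from its covariance
#'
#' Returns `n/2 * log(2 * pi * e) + log(det(cov)) / 2` in nats, using a
#' Cholesky factorization with a relative jitter floor for near-singular
#' covariances (eigenvalues are effectively clipped at -1e-10).
#'
#' @param cov symmetric positive-semidefinite matrix.
#' @return entropy in nats.
#' @examples
#' gaussianEntropy(matrix(1))            # 0.5 * log(2 * pi * e)
#' @export
gaussianEntropy <- function(cov) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) stop("covariance must be square")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  n <- nrow(cov)
  n / 2 * log(2 * pi * exp(1)) + 0.5 * logDetPsd(cov)
}

# log-determinant with jitter floor; tolerates tiny negative eigenvalues.
logDetPsd <- function(S) {
  S <- (S + t(S)) / 2
  jit <- 1e-10 * max(mean(diag(S)), .Machine$double.eps)
  ch <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
  if (!is.null(ch)) return(2 * sum(log(diag(ch))))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop("covariance has substantially negative eigenvalues")
  sum(log(pmax(ev, jit)))
}

# Lag-embedded joint covariance of (Y_future, Y_past(1..T), X_past(1..T)).
# Biased (1/m) normalization over the m = n - T usable rows.
ndteEmbedCov <- function(x, y, lag) {
  n <- length(y)
  m <- n - lag
  idx <- (lag + 1L):n
  E <- matrix(0, m, 2L * lag + 1L)
  E[, 1L] <- y[idx]
  for (k in seq_len(lag)) {
    E[, 1L + k] <- y[idx - k]
    E[, 1L + lag + k] <- x[idx - k]
  }
  E <- sweep(E, 2L, colMeans(E))
  crossprod(E) / m
}

#' Normalized directed transfer entropy between two time series
#'
#' Computes the NDTE flow from source `x` to target `y`: the conditional
#' mutual information between the source past and the one-sample future of
#' the target given the target past, normalized by the total information
#' that the joint past of both signals carries about that future,
#'
#' \deqn{F_{X \to Y} = \frac{I(Y_{t}; X^{past} \mid Y^{past})}
#'                          {I(Y_{t}; X^{past}, Y^{past})},}
#'
#' with all (conditional) entropies evaluated under a Gaussian model from
#' the empirical covariance of the lag-embedded data. The value is clipped
#' to [0, 1]; a degenerate denominator (below `denomFloor`, e.g. a
#' white-noise target) returns 0.
#'
#' @param x source series (numeric vector).
#' @param y target series, same length.
#' @param lag embedding length: a [ModelOrder-class] or positive integer.
#' @param denomFloor smallest admissible denominator (default 1e-12).
#' @return the NDTE flow in [0, 1].
#' @export
ndtePair <- function(x, y, lag, denomFloor = 1e-12) {
  if (is(lag, "ModelOrder")) lag <- lag@lagSamples
  lag <- assertCount(lag, "lag")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(y) <= 3L * lag)
    stop("series length (", length(y), ") must exceed 3 * lag = ", 3L * lag)
  S <- ndteEmbedCov(x, y, lag)
  ndteFromCov(S, lag, denomFloor)
}

ndteFromCov <- function(S, lag, denomFloor = 1e-12) {
  f <- 1L
  yp <- 1L + seq_len(lag)
  xp <- 1L + lag + seq_len(lag)
  hYp <- logDetPsd(S[yp, yp, drop = FALSE])
  hFYp <- logDetPsd(S[c(f, yp), c(f, yp), drop = FALSE])
  hPast <- logDetPsd(S[c(yp, xp), c(yp, xp), drop = FALSE])
  hAll <- logDetPsd(S)
  hF <- logDetPsd(S[f, f, drop = FALSE])
  num <- 0.5 * (hFYp - hYp - hAll + hPast)
  den <- 0.5 * (hF + hPast - hAll)
  if (!is.finite(den) || den < denomFloor) return(0)
  min(1, max(0, num / den))
}

#' NDTE flow matrix of a single epoch
#'
#' Applies [ndtePair()] to every ordered region pair of one trial. The
#' result follows the package-wide orientation: entry (i, j) is the flow
#' from source region j into target region i.
#'
#' @param epoch an [EpochSet-class]/[DifferenceEpochSet-class] (with
#'   `trial` selecting the epoch) or a regions x samples numeric matrix.
#' @param lag a [ModelOrder-class] or positive integer.
#' @param trial trial index when `epoch` is an `EpochSet` (default 1).
#' @return a [FlowMatrix-class].
#' @export
ndteMatrix <- function(epoch, lag, trial = 1L) {
  m <- epochTraceMatrix(epoch, trial)
  if (nrow(m) < 2L) stop("need at least 2 regions")
  if (is(lag, "ModelOrder")) mo <- lag
  else mo <- new("ModelOrder", lagSamples = as.integer(lag),
                 lagMs = NA_real_, perUnitLags = numeric())
  R <- nrow(m)
  F <- matrix(0, R, R, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(R)) for (j in seq_len(R)) if (i != j)
    F[i, j] <- ndtePair(m[j, ], m[i, ], mo@lagSamples)
  new("FlowMatrix", flow = F, lag = mo)
}

# Extract one trial as a labelled regions x samples matrix.
epochTraceMatrix <- function(epoch, trial = 1L) {
  if (is(epoch, "EpochSet")) {
    d <- epochData(epoch)
    m <- matrix(d[trial, , ], nrow = dim(d)[2L])
    rownames(m) <- regionLabels(epoch)
    m
  } else as.matrix(epoch)
}

#' Write a raw flow matrix as TSV
#'
#' Region labels form the header row and first column; a leading comment
#' line states the orientation (`# M[i,j] = flow j -> i`).
#'
#' @param x a [FlowMatrix-class] or plain matrix.
#' @param file output path.
#' @export
writeFlowMatrix <- function(x, file) {
  M <- if (is(x, "FlowMatrix")) flows(x) else as.matrix(x)
  if (is.null(rownames(M)))
    dimnames(M) <- list(paste0("R", seq_len(nrow(M))),
                        paste0("R", seq_len(ncol(M))))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# M[i,j] = flow j -> i", con)
  utils::write.table(M, con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}
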