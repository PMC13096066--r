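#' Welch bandpower per channel, optionally baseline-normalized
#'
#' Power spectral density by Welch's method: Hann-windowed segments with
#' the given overlap, zero-padded so the FFT bin spacing equals
#' `binSpacingHz` (the segment length itself defaults to the full epoch, so
#' for short epochs the zero-padding sets the bin spacing, not the true
#' spectral resolution). PSD is scaled so that its integral over frequency
#' equals the signal variance; band power is the mean PSD over the bins
#' inside `band`. When `baseline` epochs are supplied the returned value is
#' the post/baseline power ratio per channel.
#'
#' @param epochs an [EpochSet-class].
#' @param band numeric length 2, band edges in Hz within (0, fs/2).
#' @param overlap segment overlap fraction (default 0.5).
#' @param binSpacingHz FFT bin spacing after zero padding (default 0.12).
#' @param segmentLength segment length in samples (default: full epoch).
#' @param baseline optional [EpochSet-class] used for normalization.
#' @return named numeric vector: band power (or power ratio) per channel.
#' @export
welchBandpower <- function(epochs, band, overlap = 0.5, binSpacingHz = 0.12,
                           segmentLength = NULL, baseline = NULL) {
  fs <- samplingRate(epochs)
  if (band[1L] <= 0 || band[2L] >= fs / 2 || band[1L] >= band[2L])
    stop("band must lie within (0, fs/2) = (0, ", fs / 2, ") Hz")
  post <- welchBandpowerRaw(epochs, band, overlap, binSpacingHz,
                            segmentLength)
  if (is.null(baseline)) return(post)
  base <- welchBandpowerRaw(baseline, band, overlap, binSpacingHz,
                            segmentLength)
  post / base
}

welchBandpowerRaw <- function(epochs, band, overlap, binSpacingHz,
                              segmentLength) {
  d <- epochData(epochs)
  fs <- samplingRate(epochs)
  n <- dim(d)[3L]
  L <- if (is.null(segmentLength)) n else min(segmentLength, n)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  nfft <- max(L, round(fs / binSpacingHz))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  U <- fs * sum(w^2)
  freqs <- (seq_len(nfft %/% 2 + 1L) - 1L) * fs / nfft
  inBand <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(inBand)) stop("no FFT bins inside the requested band")
  pw <- vapply(seq_len(dim(d)[2L]), function(ch) {
    acc <- numeric(sum(inBand)); cnt <- 0L
    for (k in seq_len(dim(d)[1L])) for (s0 in starts) {
      seg <- d[k, ch, s0:(s0 + L - 1L)]
      seg <- (seg - mean(seg)) * w
      X <- stats::fft(c(seg, numeric(nfft - L)))
      psd <- (Mod(X[seq_len(nfft %/% 2 + 1L)])^2) / U
      psd[-c(1L, nfft %/% 2 + 1L)] <- 2 * psd[-c(1L, nfft %/% 2 + 1L)]
      acc <- acc + psd[inBand]; cnt <- cnt + 1L
    }
    mean(acc / cnt)
  }, numeric(1L))
  stats::setNames(pw, regionLabels(epochs))
}

#' Phase-clustering primitives
#'
#' `itpcFromPhases` is the intertrial phase clustering of a set of phases:
#' the magnitude of the mean unit phase vector, `|mean(exp(i phi))|`.
#' `plvFromPhases` is the phase-locking value of two instantaneous phase
#' time courses: the magnitude of the time-averaged complex phase
#' difference. Both lie in [0, 1] and equal 1 iff the phases (phase
#' differences) all coincide.
#'
#' @param phases numeric vector of phases (radians), one per trial.
#' @return a scalar in [0, 1].
#' @examples
#' itpcFromPhases(c(0, 0, 0, pi))      # |(3 - 1)/4| = 0.5
#' plvFromPhases(c(0, 0), c(0, -pi/2)) # |mean(1, i)| = sqrt(2)/2
#' @export
itpcFromPhases <- function(phases) Mod(mean(exp(1i * phases)))

#' @rdname itpcFromPhases
#' @param phiA,phiB instantaneous phase time courses (radians).
#' @export
plvFromPhases <- function(phiA, phiB) {
  stopifnot(length(phiA) == length(phiB))
  Mod(mean(exp(1i * (phiA - phiB))))
}

#' Intertrial phase clustering from Morlet wavelet phases
#'
#' Convolves each trial with complex Morlet wavelets at `nFreqs`
#' logarithmically spaced center frequencies and computes, per channel,
#' frequency and time sample, the magnitude of the trial-averaged unit
#' phase vector, `ITPC = |mean_trials exp(i phi)|`. Time samples within 3
#' wavelet standard deviations of either epoch edge are set to NA.
#'
#' @param epochs an [EpochSet-class] with >= 2 trials.
#' @param fMin,fMax frequency range (Hz); `fMax` must be below fs/2.
#' @param nFreqs number of log-spaced center frequencies (default 20).
#' @param cycles Morlet width in cycles (default 7).
#' @return array channels x freqs x time in [0, 1]; frequencies are in
#'   `dimnames`.
#' @export
morletItpc <- function(epochs, fMin = 0.5, fMax = 80, nFreqs = 20L,
                       cycles = 7) {
  fs <- samplingRate(epochs)
  if (fMax >= fs / 2) stop("fMax must be below the Nyquist frequency")
  if (nTrials(epochs) < 2L) stop("need at least 2 trials")
  freqs <- exp(seq(log(fMin), log(fMax), length.out = nFreqs))
  d <- epochData(epochs)
  nT <- dim(d)[1L]; nC <- dim(d)[2L]; n <- dim(d)[3L]
  out <- array(NA_real_, c(nC, nFreqs, n),
               dimnames = list(regionLabels(epochs), signif(freqs, 6), NULL))
  for (fi in seq_len(nFreqs)) {
    f <- freqs[fi]
    sdT <- cycles / (2 * pi * f)                    # seconds
    half <- min(ceiling(3 * sdT * fs), n - 1L)
    tK <- (-half:half) / fs
    kern <- exp(2i * pi * f * tK) * exp(-tK^2 / (2 * sdT^2))
    N <- stats::nextn(n + length(kern) - 1L, 2L)
    kF <- stats::fft(c(kern, complex(real = numeric(N - length(kern)))))
    for (ch in seq_len(nC)) {
      ph <- matrix(0, nT, n)
      for (k in seq_len(nT)) {
        x <- d[k, ch, ]
        xF <- stats::fft(c(x - mean(x), numeric(N - n)))
        conv <- stats::fft(xF * kF, inverse = TRUE) / N
        ph[k, ] <- Arg(conv[half + seq_len(n)])     # centered 'same' part
      }
      itpc <- apply(ph, 2L, itpcFromPhases)
      if (half >= 1L) itpc[c(seq_len(half), n - seq_len(half) + 1L)] <- NA
      out[ch, fi, ] <- itpc
    }
  }
  out
}

#' Whole-head phase-locking value per epoch
#'
#' Band-passes every channel, extracts instantaneous phases from the
#' analytic (Hilbert) signal and computes, per unordered channel pair, the
#' magnitude of the time-averaged complex phase difference
#' `PLV = |1/T sum_t exp(i (phi_a(t) - phi_b(t)))|`. The whole-head value
#' is the mean over all pairs; one value per epoch is returned.
#'
#' @param epochs an [EpochSet-class] with >= 2 channels.
#' @param band numeric length 2 band edges in Hz (default c(0.85, 4),
#'   matching a 1.2 s post-cue window).
#' @param filter apply the band-pass before phase extraction (default
#'   TRUE; set FALSE if the data are already filtered).
#' @param edgeTrim fraction of samples discarded at each end of the epoch
#'   before averaging phase differences (default 0.1), where the
#'   finite-window analytic signal is unreliable.
#' @return numeric vector, whole-head PLV per trial (in [0, 1]).
#' @export
hilbertPlv <- function(epochs, band = c(0.85, 4), filter = TRUE,
                       edgeTrim = 0.1) {
  if (nRegions(epochs) < 2L) stop("PLV needs at least 2 channels")
  if (filter) epochs <- bandpassEpochs(epochs, band)
  d <- epochData(epochs)
  nT <- dim(d)[1L]; nC <- dim(d)[2L]; n <- dim(d)[3L]
  tr <- floor(edgeTrim * n)
  keep <- (tr + 1L):(n - tr)
  pairs <- utils::combn(nC, 2L)
  vapply(seq_len(nT), function(k) {
    ph <- vapply(seq_len(nC), function(ch)
      Arg(analyticSignal(d[k, ch, ]))[keep], numeric(length(keep)))
    mean(vapply(seq_len(ncol(pairs)), function(q)
      plvFromPhases(ph[, pairs[1L, q]], ph[, pairs[2L, q]]), numeric(1L)))
  }, numeric(1L))
}

#' Paired permutation test on scalar summaries
#'
#' Statistic: mean paired difference. The null is generated by random sign
#' flips of the per-participant differences; the two-sided p-value follows
#' the add-one rule. When `nPerm >= 2^n - 1` the full sign-flip
#' distribution is enumerated instead and the exact p-value is returned.
#'
#' @param valsA,valsB paired numeric vectors (n >= 2).
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `p`, `statistic` (mean difference) and `exact`.
#' @export
permutationTestScalar <- function(valsA, valsB, nPerm = 1000L, seed = NULL) {
  nPerm <- assertCount(nPerm, "nPerm")
  stopifnot(length(valsA) == length(valsB))
  n <- length(valsA)
  if (n < 2L) stop("need at least 2 pairs")
  D <- valsA - valsB
  obs <- mean(D)
  if (n <= 20L && nPerm >= 2^n - 1L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- as.numeric(signs %*% D) / n
    p <- mean(abs(null) >= abs(obs) - 1e-12)
    return(list(p = p, statistic = obs, exact = TRUE))
  }
  null <- withSeed(seed, vapply(seq_len(nPerm), function(k)
    mean(sample(c(-1, 1), n, replace = TRUE) * D), numeric(1L)))
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (nPerm + 1)
  list(p = p, statistic = obs, exact = FALSE)
}
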