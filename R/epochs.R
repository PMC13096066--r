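#' Reject epochs on within-epoch amplitude change
#'
#' An epoch is removed when the peak-to-peak amplitude (max minus min over
#' time) of any single region's trace reaches `threshold`. This is the
#' standard per-channel reading of an "amplitude change" criterion; set
#' `perRegion = FALSE` to evaluate max - min jointly across regions.
#'
#' @param epochs an [EpochSet-class].
#' @param threshold rejection threshold in signal units (> 0).
#' @param perRegion evaluate the peak-to-peak per region (default TRUE).
#'
#' @return a list with `epochs` (the retained trials) and
#'   `rejectedFraction`. When everything is rejected the returned set has
#'   zero trials and a warning is raised.
#' @export
rejectAmplitude <- function(epochs, threshold, perRegion = TRUE) {
  assertPositive(threshold, "threshold")
  d <- epochData(epochs)
  bad <- vapply(seq_len(dim(d)[1L]), function(k) {
    tr <- d[k, , , drop = FALSE][1, , , drop = TRUE]
    if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1L)
    if (perRegion) {
      p2p <- apply(tr, 1L, function(v) max(v) - min(v))
      any(p2p >= threshold)
    } else (max(tr) - min(tr)) >= threshold
  }, logical(1L))
  if (all(bad))
    warning("all ", length(bad), " epochs rejected at threshold ", threshold)
  list(epochs = epochs[!bad], rejectedFraction = mean(bad))
}

#' Equalize epoch counts by random subsampling
#'
#' Randomly removes trials from the larger set so both condition sets hold
#' the same number of epochs, preserving trial order in the retained subset.
#'
#' @param larger the [EpochSet-class] with at least as many trials.
#' @param smaller the reference set.
#' @param seed RNG seed.
#' @return `larger` restricted to a random subset of `nTrials(smaller)`
#'   trials.
#' @export
equalizeEpochCounts <- function(larger, smaller, seed = NULL) {
  nL <- nTrials(larger); nS <- nTrials(smaller)
  if (nL < nS)
    stop("'larger' has fewer trials (", nL, ") than 'smaller' (", nS,
         "); swap the arguments")
  if (nL == nS) return(larger)
  keep <- withSeed(seed, sort(sample.int(nL, nS)))
  larger[keep]
}

#' Randomly pair epochs across conditions and form difference waveforms
#'
#' Draws a random bijection between the trials of the two equally sized
#' sets and returns single-trial difference waveforms, fixed by convention
#' as 50\% predictable minus 80\% predictable.
#'
#' @param set50 epochs of the non-predictive (50\%) condition.
#' @param set80 epochs of the predictive (80\%) condition; same trial count.
#' @param seed RNG seed.
#' @return a [DifferenceEpochSet-class]; `pairMap(x)` records the pairing.
#' @export
pairAndDifference <- function(set50, set80, seed = NULL) {
  n <- nTrials(set50)
  if (nTrials(set80) != n)
    stop("condition sets must have equal trial counts ",
         "(run equalizeEpochCounts first): ", n, " vs ", nTrials(set80))
  if (samplingRate(set50) != samplingRate(set80) ||
      nSamples(set50) != nSamples(set80) ||
      !identical(regionLabels(set50), regionLabels(set80)))
    stop("condition sets must share sampling rate, samples and regions")
  perm <- withSeed(seed, sample.int(n))
  dat <- epochData(set50) - epochData(set80)[perm, , , drop = FALSE]
  new("DifferenceEpochSet",
      data = dat, fsHz = samplingRate(set50), t0Ms = epochStartMs(set50),
      regionLabels = regionLabels(set50),
      condition = rep("difference_50_minus_80", n),
      participantId = participantId(set50),
      pairMap = cbind(index50 = seq_len(n), index80 = perm))
}

#' Extract a time window from an EpochSet
#'
#' Keeps samples with time in the half-open interval `[startMs, endMs)`
#' relative to cue onset, updating the epoch start time. At a 1 kHz
#' sampling rate a 900--1300 ms window therefore yields exactly 400 samples.
#'
#' @param epochs an [EpochSet-class].
#' @param startMs,endMs window bounds in ms relative to cue onset.
#' @return the windowed `EpochSet`.
#' @export
extractWindow <- function(epochs, startMs, endMs) {
  if (startMs >= endMs) stop("startMs must be below endMs")
  t <- epochTimesMs(epochs)
  fs <- samplingRate(epochs)
  span <- c(t[1L], t[length(t)] + 1000 / fs)
  if (startMs < span[1L] - 1e-9 || endMs > span[2L] + 1e-9)
    stop("window [", startMs, ", ", endMs, ") outside the epoch span [",
         span[1L], ", ", span[2L], ") ms")
  keep <- which(t >= startMs - 1e-9 & t < endMs - 1e-9)
  replaceEpochData(epochs, epochData(epochs)[, , keep, drop = FALSE],
                   t0Ms = t[keep[1L]])
}

#' Zero-phase FIR filtering of epochs
#'
#' High-, low- or band-pass filters every region trace of every trial with
#' a Hamming-windowed linear-phase FIR filter applied forward and backward
#' (`signal::filtfilt`), so the output is zero-phase and length-preserving.
#' The default filter order is three cycles of the (lowest) cutoff period,
#' capped so the filter fits the data length.
#'
#' @param epochs an [EpochSet-class].
#' @param cutoffHz scalar cutoff (high/low-pass) or length-2 band edges.
#' @param type "high", "low" or "pass".
#' @param order FIR order; default `3 * fs / min(cutoffHz)`, made even and
#'   capped at `floor((nSamples - 1) / 3)`.
#' @return the filtered `EpochSet`.
#' @export
filterEpochs <- function(epochs, cutoffHz, type = c("high", "low", "pass"),
                         order = NULL) {
  type <- match.arg(type)
  fs <- samplingRate(epochs)
  if (any(cutoffHz <= 0) || any(cutoffHz >= fs / 2))
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         fs / 2, " Hz)")
  if (type == "pass" && length(cutoffHz) != 2L)
    stop("band-pass needs two cutoff frequencies")
  n <- nSamples(epochs)
  if (is.null(order)) {
    order <- round(3 * fs / min(cutoffHz))
    order <- min(order, n - 2L)
  }
  if (order %% 2 == 1L) order <- order - 1L
  if (order < 4L) stop("epoch too short for the requested filter")
  w <- cutoffHz / (fs / 2)
  b <- switch(type,
    high = signal::fir1(order, w, type = "high"),
    low  = signal::fir1(order, w, type = "low"),
    pass = signal::fir1(order, w, type = "pass"))
  d <- epochData(epochs)
  out <- d
  p <- min(order, n - 1L)   # odd-reflection padding absorbs edge transients
  for (k in seq_len(dim(d)[1L]))
    for (r in seq_len(dim(d)[2L])) {
      x <- d[k, r, ]
      xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
      y <- signal::filtfilt(filt = b, a = 1, x = xp)
      out[k, r, ] <- y[p + seq_len(n)]
    }
  replaceEpochData(epochs, out)
}

#' @rdname filterEpochs
#' @export
highpassEpochs <- function(epochs, cutoffHz, order = NULL)
  filterEpochs(epochs, cutoffHz, "high", order)

#' @rdname filterEpochs
#' @export
lowpassEpochs <- function(epochs, cutoffHz, order = NULL)
  filterEpochs(epochs, cutoffHz, "low", order)

#' @rdname filterEpochs
#' @export
bandpassEpochs <- function(epochs, cutoffHz, order = NULL)
  filterEpochs(epochs, cutoffHz, "pass", order)

# Rebuild an EpochSet (or subclass) with new data, preserving metadata.
replaceEpochData <- function(epochs, data, t0Ms = epochStartMs(epochs)) {
  if (is(epochs, "DifferenceEpochSet"))
    new("DifferenceEpochSet", data = data, fsHz = samplingRate(epochs),
        t0Ms = t0Ms, regionLabels = regionLabels(epochs),
        condition = conditions(epochs),
        participantId = participantId(epochs), pairMap = pairMap(epochs))
  else
    new("EpochSet", data = data, fsHz = samplingRate(epochs), t0Ms = t0Ms,
        regionLabels = regionLabels(epochs), condition = conditions(epochs),
        participantId = participantId(epochs))
}

#' Write / read an EpochSet as float32 binary with a JSON sidecar
#'
#' The container is one little-endian float32 binary file (sample index
#' fastest, then region, then trial) plus a JSON sidecar holding the shape,
#' sampling rate, epoch start, region labels, per-trial conditions and
#' participant id. The round trip is lossless at float32 precision. A
#' delimited-text fallback (`format = "tsv"`) stores the flattened data as
#' one trial-region trace per row.
#'
#' @param epochs an [EpochSet-class].
#' @param path base path without extension; `<path>.f32`/`<path>.tsv` and
#'   `<path>.json` are written.
#' @param format "binary" (default) or "tsv".
#' @return `writeEpochSet` returns `path` invisibly; `readEpochSet` the
#'   reconstructed `EpochSet`.
#' @export
writeEpochSet <- function(epochs, path, format = c("binary", "tsv")) {
  format <- match.arg(format)
  d <- epochData(epochs)
  meta <- list(shape = dim(d), fs_hz = samplingRate(epochs),
               t0_ms = epochStartMs(epochs),
               region_labels = regionLabels(epochs),
               condition = conditions(epochs),
               participant_id = participantId(epochs),
               format = format)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- aperm(d, c(3L, 2L, 1L))  # sample fastest
  if (format == "binary") {
    con <- file(paste0(path, ".f32"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(flat), con, size = 4L, endian = "little")
  } else {
    m <- matrix(as.numeric(flat), nrow = dim(d)[1L] * dim(d)[2L],
                byrow = TRUE)
    utils::write.table(m, paste0(path, ".tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeEpochSet
#' @param path base path used by `writeEpochSet`.
#' @export
readEpochSet <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  flat <- if (identical(meta$format, "tsv")) {
    m <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
    as.numeric(t(m))
  } else {
    con <- file(paste0(path, ".f32"), "rb")
    on.exit(close(con))
    readBin(con, numeric(), n = n, size = 4L, endian = "little")
  }
  d <- aperm(array(flat, shape[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
  EpochSet(d, fsHz = meta$fs_hz, t0Ms = meta$t0_ms,
           regionLabels = meta$region_labels, condition = meta$condition,
           participantId = meta$participant_id)
}
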