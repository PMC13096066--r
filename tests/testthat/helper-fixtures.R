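# Shared fixture builders; all synthetic, generated at test time.

# Single-trial, single-region EpochSet from a numeric vector.
epochFromVector <- function(v, fs = 1000, t0 = 0) {
  EpochSet(array(v, c(1L, 1L, length(v))), fsHz = fs, t0Ms = t0)
}

# Multi-trial EpochSet from a trials x samples matrix (one region) or a
# trials x regions x samples array.
epochsFromArray <- function(a, fs = 1000, t0 = 0, condition = NULL) {
  if (length(dim(a)) == 2L) a <- array(a, c(nrow(a), 1L, ncol(a)))
  if (is.null(condition)) condition <- rep("unspecified", dim(a)[1L])
  EpochSet(a, fsHz = fs, t0Ms = t0, condition = condition)
}

# Amplitude of frequency f in a single-trial epoch, by FFT.
fftAmplitude <- function(epochs, f) {
  v <- epochData(epochs)[1, 1, ]
  n <- length(v)
  X <- abs(stats::fft(v)) / n * 2
  X[round(f * n / samplingRate(epochs)) + 1L]
}

# Diagonal-self VAR spec with one optional planted directed coupling.
chainSpec <- function(nRois, self = 0.5, pairs = NULL, weight = 0.4,
                      fs = 1000, effectWindowMs = c(0, Inf), delta = FALSE) {
  A <- array(0, c(nRois, nRois, 1L))
  for (r in seq_len(nRois)) A[r, r, 1L] <- self
  D <- array(0, dim(A))
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      if (delta) D[pairs[k, 1L], pairs[k, 2L], 1L] <- weight
      else A[pairs[k, 1L], pairs[k, 2L], 1L] <- weight
    }
  }
  groundTruthSpec(nRois, fsHz = fs, baseCoupling = A, conditionDelta = D,
                  effectWindowMs = effectWindowMs)
}

# Plain trial table for generateVarEpochs, bypassing the full design.
quickTrials <- function(nPerCondition, participant = 1L,
                        conditions = c("nonpredictive_50", "predictive_80")) {
  data.frame(participant_id = participant,
             condition = rep(conditions, each = nPerCondition),
             stringsAsFactors = FALSE)
}

# Tiny end-to-end config for pipeline tests.
tinyConfig <- function(seed = 1L) {
  cfg <- defaultConfig(seed)
  cfg$nParticipants <- 4L
  cfg$trialsPerBlock <- 10L
  cfg$nRois <- 3L
  cfg$fsHz <- 250
  cfg$nSurrogates <- 29L
  cfg$fricNMc <- 200L
  cfg$erpNPerm <- 100L
  cfg$nPermScalar <- 200L
  cfg$maxLag <- 6L
  cfg$deltaCoupling <- 0.6
  cfg
}
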