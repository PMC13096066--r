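#' Simulate the trial sequence of the cued target-detection design
#'
#' Builds the trial table of a cued auditory target-detection experiment:
#' on each trial a 100 ms cue is followed, after a cue-target interval of
#' 1200 ms (early target) or 2400 ms (late target), by a target tone. After
#' a predictive cue the early interval occurs with probability 0.8; after a
#' non-predictive cue with probability 0.5. Each participant completes
#' `blocksPerCondition` blocks of `trialsPerBlock` trials per condition and
#' trial order is randomized within participant. The inter-trial interval is
#' drawn uniformly between 200 and 1000 ms. Cue-target intervals are
#' measured from cue offset to target onset.
#'
#' @param nParticipants number of participants.
#' @param blocksPerCondition blocks per condition (default 3).
#' @param trialsPerBlock trials per block (default 50).
#' @param pEarlyPredictive probability of an early target after a predictive
#'   cue (default 0.8).
#' @param pEarlyNonpredictive probability of an early target after a
#'   non-predictive cue (default 0.5).
#' @param itiRangeMs inter-trial interval range in ms (default c(200, 1000)).
#' @param cueDurationMs cue duration in ms (default 100).
#' @param seed RNG seed (NULL uses the current stream).
#'
#' @return a data.frame (trial table) with columns `trial_id`,
#'   `participant_id`, `block`, `condition` (`predictive_80` /
#'   `nonpredictive_50`), `cue_onset_ms`, `cue_duration_ms`,
#'   `target_latency` (`early` / `late`), `cue_target_interval_ms`,
#'   `iti_ms`, `rt_ms` (NA until filled by [generateRtTable()]).
#'
#' @examples
#' tt <- simulateTrialSequence(1, seed = 1)
#' table(tt$condition)
#' @export
simulateTrialSequence <- function(nParticipants = 20L,
                                  blocksPerCondition = 3L,
                                  trialsPerBlock = 50L,
                                  pEarlyPredictive = 0.8,
                                  pEarlyNonpredictive = 0.5,
                                  itiRangeMs = c(200, 1000),
                                  cueDurationMs = 100,
                                  seed = NULL) {
  nParticipants <- assertCount(nParticipants, "nParticipants")
  blocksPerCondition <- assertCount(blocksPerCondition, "blocksPerCondition")
  trialsPerBlock <- assertCount(trialsPerBlock, "trialsPerBlock")
  assertProbability(pEarlyPredictive, "pEarlyPredictive")
  assertProbability(pEarlyNonpredictive, "pEarlyNonpredictive")
  withSeed(seed, {
    perPart <- lapply(seq_len(nParticipants), function(p) {
      condition <- rep(c("predictive_80", "nonpredictive_50"),
                       each = blocksPerCondition * trialsPerBlock)
      block <- rep(rep(seq_len(blocksPerCondition), each = trialsPerBlock), 2L)
      pEarly <- ifelse(condition == "predictive_80",
                       pEarlyPredictive, pEarlyNonpredictive)
      early <- stats::runif(length(condition)) < pEarly
      ord <- sample.int(length(condition))
      condition <- condition[ord]; block <- block[ord]; early <- early[ord]
      iti <- stats::runif(length(condition), itiRangeMs[1L], itiRangeMs[2L])
      cti <- ifelse(early, 1200, 2400)
      # cue onsets accumulate: previous trial spans cue + CTI + 100 ms target
      span <- cueDurationMs + cti + 100
      onset <- cumsum(c(iti[1L], span[-length(span)] + iti[-1L]))
      data.frame(
        trial_id = seq_along(condition),
        participant_id = p,
        block = block,
        condition = condition,
        cue_onset_ms = onset,
        cue_duration_ms = cueDurationMs,
        target_latency = ifelse(early, "early", "late"),
        cue_target_interval_ms = cti,
        iti_ms = iti,
        rt_ms = NA_real_,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, perPart)
  })
}

#' Spectral radius of a VAR companion matrix
#'
#' A vector-autoregressive process with coefficient array `coupling`
#' (regions x regions x lags) is stationary iff the spectral radius of its
#' companion matrix is below 1.
#'
#' @param coupling numeric array regions x regions x lags (a matrix is
#'   treated as a single lag).
#' @return the largest eigenvalue modulus of the companion matrix.
#' @export
companionSpectralRadius <- function(coupling) {
  if (is.matrix(coupling)) coupling <- array(coupling, c(dim(coupling), 1L))
  r <- dim(coupling)[1L]; p <- dim(coupling)[3L]
  comp <- matrix(0, r * p, r * p)
  for (k in seq_len(p))
    comp[seq_len(r), (k - 1L) * r + seq_len(r)] <- coupling[, , k]
  if (p > 1L)
    comp[r + seq_len(r * (p - 1L)), seq_len(r * (p - 1L))] <-
      diag(r * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Ground-truth specification for the VAR epoch generator
#'
#' Bundles the parameters of a stationary vector-autoregressive network used
#' to simulate region time series with known directed couplings. Coupling
#' orientation matches the flow matrices: `baseCoupling[i, j, p]` is the
#' effect of region j at lag p on region i (flow j -> i).
#'
#' @param nRois number of regions.
#' @param fsHz sampling rate.
#' @param baseCoupling array nRois x nRois x lags of AR coefficients.
#' @param conditionDelta same-shape array of coupling differences applied in
#'   the `predictive_80` condition inside the effect window (default all 0).
#' @param effectWindowMs numeric length 2, window relative to cue onset in
#'   which `conditionDelta` is active.
#' @param noiseSd innovation standard deviation (default 1).
#' @param plantedClub integer indices (1-based) of regions forming a planted
#'   hub set, recorded for downstream recovery checks (default none).
#'
#' @return a list with class `"GroundTruthSpec"`.
#' @export
groundTruthSpec <- function(nRois, fsHz = 1000, baseCoupling,
                            conditionDelta = NULL,
                            effectWindowMs = c(0, Inf),
                            noiseSd = 1, plantedClub = integer()) {
  nRois <- assertCount(nRois, "nRois")
  assertPositive(noiseSd, "noiseSd")
  if (is.matrix(baseCoupling))
    baseCoupling <- array(baseCoupling, c(dim(baseCoupling), 1L))
  if (is.null(conditionDelta))
    conditionDelta <- array(0, dim(baseCoupling))
  if (is.matrix(conditionDelta))
    conditionDelta <- array(conditionDelta, c(dim(conditionDelta), 1L))
  stopifnot(identical(dim(baseCoupling)[1:2], c(nRois, nRois)),
            identical(dim(baseCoupling), dim(conditionDelta)))
  if (!all(plantedClub %in% seq_len(nRois)))
    stop("plantedClub must be a subset of 1..nRois")
  for (nm in c("base", "base+delta")) {
    cc <- if (nm == "base") baseCoupling else baseCoupling + conditionDelta
    sr <- companionSpectralRadius(cc)
    if (sr >= 1)
      stop("non-stationary coupling (", nm, "): companion spectral radius = ",
           signif(sr, 5), " >= 1")
  }
  structure(list(nRois = nRois, fsHz = fsHz, varOrder = dim(baseCoupling)[3L],
                 baseCoupling = baseCoupling, conditionDelta = conditionDelta,
                 effectWindowMs = effectWindowMs, noiseSd = noiseSd,
                 plantedClub = as.integer(plantedClub)),
            class = "GroundTruthSpec")
}

# Simulate one VAR epoch. deltaActive marks, per output sample, whether the
# condition delta is switched on.
simulateVarEpoch <- function(spec, nSamples, deltaActive, burnIn) {
  r <- spec$nRois; p <- spec$varOrder
  total <- burnIn + nSamples
  y <- matrix(0, r, total + p)
  eps <- matrix(stats::rnorm(r * total, sd = spec$noiseSd), r, total)
  A0 <- spec$baseCoupling
  A1 <- spec$baseCoupling + spec$conditionDelta
  active <- c(rep(FALSE, burnIn), deltaActive)
  for (t in seq_len(total)) {
    A <- if (active[t]) A1 else A0
    acc <- eps[, t]
    for (k in seq_len(p)) acc <- acc + A[, , k] %*% y[, p + t - k]
    y[, p + t] <- acc
  }
  y[, p + burnIn + seq_len(nSamples), drop = FALSE]
}

#' Generate VAR epochs with condition-dependent directed couplings
#'
#' Simulates one epoch per trial of `trials` from the stationary VAR network
#' in `spec`. Outside the spec's effect window every trial follows the base
#' coupling; inside it, trials of the `predictive_80` condition follow base
#' plus delta. Innovations are i.i.d. Gaussian and a burn-in precedes every
#' epoch so that the process is observed in its stationary regime.
#'
#' @param spec a [groundTruthSpec()].
#' @param trials a trial table (see [simulateTrialSequence()]); may contain
#'   several participants.
#' @param epochWindowMs numeric length 2: epoch window relative to cue onset
#'   in ms, half-open at the sample grid.
#' @param burnIn burn-in samples before each epoch (default 100).
#' @param seed RNG seed.
#'
#' @return an [EpochSet-class] when `trials` holds a single participant,
#'   otherwise a list of `EpochSet`s named by participant id.
#' @export
generateVarEpochs <- function(spec, trials, epochWindowMs,
                              burnIn = 100L, seed = NULL) {
  stopifnot(inherits(spec, "GroundTruthSpec"))
  burnIn <- assertCount(burnIn, "burnIn", min = 0L)
  if (epochWindowMs[2L] <= epochWindowMs[1L])
    stop("epochWindowMs must be an increasing (start, end) pair")
  fs <- spec$fsHz
  nSamples <- round((epochWindowMs[2L] - epochWindowMs[1L]) * fs / 1000)
  tMs <- epochWindowMs[1L] + (seq_len(nSamples) - 1L) * 1000 / fs
  inEffect <- tMs >= spec$effectWindowMs[1L] & tMs < spec$effectWindowMs[2L]
  withSeed(seed, {
    out <- lapply(split(trials, trials$participant_id), function(tp) {
      dat <- array(0, c(nrow(tp), spec$nRois, nSamples))
      for (k in seq_len(nrow(tp))) {
        act <- if (tp$condition[k] == "predictive_80") inEffect
               else rep(FALSE, nSamples)
        dat[k, , ] <- simulateVarEpoch(spec, nSamples, act, burnIn)
      }
      EpochSet(dat, fsHz = fs, t0Ms = epochWindowMs[1L],
               condition = tp$condition,
               participantId = tp$participant_id[1L])
    })
    if (length(out) == 1L) out[[1L]] else out
  })
}

#' Plant a rich-club structure in a directed connectivity matrix
#'
#' Builds an nRois x nRois flow matrix (entry [i, j] = flow j -> i) in which
#' every connection whose target is a club member carries `inWeight`, every
#' connection from a club member to a non-member carries `outWeight`, and
#' all remaining connections carry `background`; the diagonal is zero.
#' Optionally a small uniform jitter (`jitterScale * background`) perturbs
#' every connection. The default is no jitter: downstream hub detection
#' breaks ranking ties deterministically by label order, and exact value
#' ties are what make the surrogate-club comparison well calibrated for an
#' exchangeable planted structure -- entry-level jitter would be read by
#' the Monte-Carlo test as genuine heterogeneity.
#'
#' @param nRois number of regions.
#' @param club integer vector of club member indices (1-based).
#' @param inWeight weight of within-club and into-club connections; must
#'   exceed `background`.
#' @param outWeight weight of club-to-outside connections; must be below
#'   `inWeight`.
#' @param background weight of connections among non-members (> 0).
#' @param jitterScale jitter amplitude as a fraction of `background`
#'   (default 0: exact ties).
#' @param seed RNG seed (only used when `jitterScale > 0`).
#'
#' @return a numeric matrix with zero diagonal.
#' @examples
#' M <- plantRichClub(10, club = 1:3, inWeight = 5, outWeight = 1,
#'                    background = 1, seed = 3)
#' @export
plantRichClub <- function(nRois, club, inWeight, outWeight, background,
                          jitterScale = 0, seed = NULL) {
  nRois <- assertCount(nRois, "nRois", min = 2L)
  club <- as.integer(club)
  if (length(club) >= nRois || !all(club %in% seq_len(nRois)))
    stop("club must be a proper subset of 1..nRois")
  if (!(inWeight > background) || background <= 0)
    stop("need inWeight > background > 0")
  if (!(outWeight < inWeight)) stop("need outWeight < inWeight")
  withSeed(seed, {
    M <- matrix(background, nRois, nRois)
    M[club, ] <- inWeight                       # target in club
    M[setdiff(seq_len(nRois), club), club] <- outWeight  # club -> outside
    if (jitterScale > 0)
      M <- M + matrix(stats::runif(nRois^2, 0, jitterScale * background),
                      nRois, nRois)
    diag(M) <- 0
    dimnames(M) <- list(paste0("R", seq_len(nRois)),
                        paste0("R", seq_len(nRois)))
    M
  })
}

#' Fill reaction times into a trial table
#'
#' Reaction time per trial = a Gaussian participant offset (sd
#' `betweenSd`) + the condition mean + Gaussian trial noise (sd
#' `withinSd`), truncated below at 50 ms. By default the non-predictive
#' condition is slower than the predictive one.
#'
#' @param trials trial table from [simulateTrialSequence()].
#' @param mean80 mean RT (ms) in the predictive (80\%) condition.
#' @param mean50 mean RT (ms) in the non-predictive (50\%) condition.
#' @param withinSd within-participant trial noise sd (ms).
#' @param betweenSd between-participant offset sd (ms).
#' @param seed RNG seed.
#'
#' @return the trial table with `rt_ms` filled.
#' @export
generateRtTable <- function(trials, mean80 = 330, mean50 = 360,
                            withinSd = 40, betweenSd = 20, seed = NULL) {
  assertPositive(mean80, "mean80"); assertPositive(mean50, "mean50")
  assertPositive(withinSd, "withinSd"); assertPositive(betweenSd, "betweenSd")
  withSeed(seed, {
    parts <- unique(trials$participant_id)
    offs <- stats::rnorm(length(parts), 0, betweenSd)
    names(offs) <- as.character(parts)
    mu <- ifelse(trials$condition == "predictive_80", mean80, mean50)
    rt <- offs[as.character(trials$participant_id)] + mu +
      stats::rnorm(nrow(trials), 0, withinSd)
    trials$rt_ms <- pmax(rt, 50)
    trials
  })
}

#' Generate phase-locked sinusoidal epochs
#'
#' Fixture generator for phase-measure checks: every trial is a sinusoid at
#' `f0` whose per-trial phase is drawn from a wrapped Gaussian with sd
#' `phaseJitterSd`, plus white noise. With zero jitter and zero noise all
#' trials are identical.
#'
#' @param nTrials number of trials.
#' @param fs sampling rate (Hz).
#' @param f0 sinusoid frequency (Hz); must be below fs/2.
#' @param phaseJitterSd sd of the per-trial phase (radians).
#' @param durationMs epoch duration (default 1000 ms).
#' @param noiseSd white-noise sd (default 0).
#' @param uniformPhase draw phases uniformly on (-pi, pi] instead of the
#'   wrapped Gaussian (default FALSE).
#' @param seed RNG seed.
#'
#' @return a single-region [EpochSet-class].
#' @export
generatePhaseLockedEpochs <- function(nTrials, fs, f0, phaseJitterSd,
                                      durationMs = 1000, noiseSd = 0,
                                      uniformPhase = FALSE, seed = NULL) {
  nTrials <- assertCount(nTrials, "nTrials")
  if (f0 >= fs / 2)
    stop("f0 = ", f0, " Hz aliases at fs = ", fs, " Hz (Nyquist ", fs / 2, ")")
  withSeed(seed, {
    n <- round(durationMs * fs / 1000)
    t <- (seq_len(n) - 1L) / fs
    phases <- if (uniformPhase) stats::runif(nTrials, -pi, pi)
              else stats::rnorm(nTrials, 0, phaseJitterSd)
    dat <- array(0, c(nTrials, 1L, n))
    for (k in seq_len(nTrials))
      dat[k, 1L, ] <- cos(2 * pi * f0 * t + phases[k]) +
        if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
    EpochSet(dat, fsHz = fs, t0Ms = 0, regionLabels = "R1")
  })
}
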