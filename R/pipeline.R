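#' Desk-scale default configuration for an end-to-end run
#'
#' Returns the full parameter list consumed by [runAll()], populated with
#' the task design of the cued auditory target-detection paradigm (100 ms
#' cue, 1200/2400 ms cue-target intervals measured cue offset to target
#' onset, 0.8 / 0.5 early-target probabilities, 200--1000 ms ITI) and
#' desk-scale analysis sizes: 8 regions, 10 participants, 20 trials per
#' condition, 50 surrogates, 1000 Monte-Carlo club draws and 500
#' permutations. Paper-scale values (100 surrogates, 1000 permutations,
#' 100000 Monte-Carlo draws, 62 regions, 3 x 50 trials) can be set by
#' overriding the corresponding entries.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return a named list; see the entries themselves for units.
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    nParticipants = 10L,
    blocksPerCondition = 1L,
    trialsPerBlock = 20L,
    pEarlyPredictive = 0.8,
    pEarlyNonpredictive = 0.5,
    fsHz = 250,
    epochWindowMs = c(-500, 1800),
    nRois = 8L,
    selfCoupling = 0.4,
    deltaCoupling = 0.35,
    deltaPair = c(2L, 1L),          # target, source: planted 1 -> 2 flow
    effectWindowMs = c(900, 1800),
    noiseSd = 1,
    burnIn = 100L,
    rtMean80 = 330, rtMean50 = 360, rtWithinSd = 40, rtBetweenSd = 20,
    rtCutoffMs = 1000,
    rejectionThreshold = 100,
    postCueWindowMs = c(900, 1300),
    postTargetWindowMs = c(100, 500),  # relative to target onset
    cueDurationMs = 100,
    earlyCueTargetIntervalMs = 1200,
    highpassHz = 2.5,
    maxLag = 20L,
    nSurrogates = 50L,
    fdrQ = 0.05,
    fricAlpha = 0.05,
    fricNMc = 1000L,
    erpNPerm = 500L,
    erpThresholdP = 0.05,
    erpMinNeighbors = 0L,
    entrainBand = c(0.85, 4),
    entrainWindowMs = c(100, 1300),
    baselineWindowMs = c(-200, 0),
    psdBinSpacingHz = 0.12,
    itpcNFreqs = 10L,
    itpcFMax = 40,
    nPermScalar = 1000L,
    topK = 20L
  )
}

#' Read / write a run configuration as YAML
#'
#' `readConfig` loads a YAML file and overlays it on [defaultConfig()], so
#' a config file only needs the entries that differ from the defaults;
#' unknown keys are rejected. `writeConfig` serializes a config so that
#' `readConfig(writeConfig(cfg))` round-trips losslessly.
#'
#' @param path YAML file path.
#' @param seed master seed for the defaults being overlaid.
#' @return `readConfig`: a config list; `writeConfig`: `path`, invisibly.
#' @export
readConfig <- function(path, seed = 1L) {
  cfg <- defaultConfig(seed)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    tmpl <- cfg[[nm]]
    val <- user[[nm]]
    cfg[[nm]] <- if (is.integer(tmpl)) as.integer(val) else
      if (is.numeric(tmpl)) as.numeric(val) else val
  }
  cfg
}

#' @rdname readConfig
#' @param config a config list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Target onset relative to cue onset for early targets.
targetOnsetMs <- function(config)
  config$cueDurationMs + config$earlyCueTargetIntervalMs

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, from a single config: trial-design and reaction-time
#' simulation, VAR epoch generation with a planted condition-dependent
#' directed coupling, amplitude rejection, epoch-count equalization,
#' windowing and 2.5 Hz high-pass filtering, NDTE estimation with
#' circular-shift surrogate inference for the 50\% condition, the 80\%
#' condition and the single-trial difference waveforms in both the
#' post-cue and post-target windows (six masked matrices), FRIC hub
#' detection on each group matrix, an ERP cluster permutation test,
#' entrainment measures (baseline-normalized bandpower with per-channel
#' permutation tests and FDR correction, whole-head PLV with a paired
#' permutation test) and the correlation of RT differences with the
#' strongest inflow connections.
#'
#' Stage outputs are pure functions of (config, seed); a manifest with
#' the package version, config and derived stage seeds is written so any
#' artifact can be reproduced. On failure the stage name is reported and
#' artifacts written so far are retained.
#'
#' @param config list as produced by [defaultConfig()].
#' @param outDir output directory (created); default a fresh tempdir
#'   subdirectory.
#' @return (invisibly) a list with all in-memory results plus `outDir`.
#' @export
runAll <- function(config = defaultConfig(), outDir = NULL) {
  if (is.null(outDir))
    outDir <- file.path(tempfile("ndteflow_run_"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(design = config$seed, rt = config$seed + 1e4,
                epochs = config$seed + 2e4, equalize = config$seed + 3e4,
                pairing = config$seed + 4e4, surrogates = config$seed + 5e4,
                fric = config$seed + 6e4, erp = config$seed + 7e4,
                entrain = config$seed + 8e4)
  stage <- "init"
  result <- list(outDir = outDir)
  tryCatch({
    stage <- "simulate-design"
    design <- simulateTrialSequence(
      config$nParticipants, config$blocksPerCondition, config$trialsPerBlock,
      config$pEarlyPredictive, config$pEarlyNonpredictive,
      cueDurationMs = config$cueDurationMs, seed = seeds$design)
    stage <- "simulate-rt"
    design <- generateRtTable(design, config$rtMean80, config$rtMean50,
                              config$rtWithinSd, config$rtBetweenSd,
                              seed = seeds$rt)
    utils::write.table(design, file.path(outDir, "trials.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    result$design <- design

    stage <- "simulate-epochs"
    base <- array(0, c(config$nRois, config$nRois, 1L))
    for (r in seq_len(config$nRois)) base[r, r, 1L] <- config$selfCoupling
    delta <- array(0, dim(base))
    delta[config$deltaPair[1L], config$deltaPair[2L], 1L] <-
      config$deltaCoupling
    gt <- groundTruthSpec(config$nRois, fsHz = config$fsHz,
                          baseCoupling = base, conditionDelta = delta,
                          effectWindowMs = config$effectWindowMs,
                          noiseSd = config$noiseSd)
    early <- design[design$target_latency == "early", ]
    epochsAll <- generateVarEpochs(gt, early, config$epochWindowMs,
                                   burnIn = config$burnIn,
                                   seed = seeds$epochs)
    if (is(epochsAll, "EpochSet")) epochsAll <- list(epochsAll)

    stage <- "epochs-clean"
    tOn <- targetOnsetMs(config)
    windows <- list(
      post_cue = config$postCueWindowMs,
      post_target = tOn + config$postTargetWindowMs)
    perParticipant <- lapply(epochsAll, function(es) {
      kept <- rejectAmplitude(es, config$rejectionThreshold)$epochs
      s50 <- kept[conditions(kept) == "nonpredictive_50"]
      s80 <- kept[conditions(kept) == "predictive_80"]
      if (nTrials(s80) >= nTrials(s50))
        s80 <- equalizeEpochCounts(s80, s50, seed = seeds$equalize)
      else s50 <- equalizeEpochCounts(s50, s80, seed = seeds$equalize)
      diffSet <- pairAndDifference(s50, s80, seed = seeds$pairing +
                                     participantId(es))
      list(s50 = s50, s80 = s80, diff = diffSet)
    })

    stage <- "model-order"
    orderInputs <- unlist(lapply(perParticipant, function(pp) list(
      extractWindow(pp$s50, windows$post_cue[1L], windows$post_cue[2L]),
      extractWindow(pp$s80, windows$post_cue[1L], windows$post_cue[2L]))),
      recursive = FALSE)
    lag <- estimateModelOrder(orderInputs, maxLag = config$maxLag)
    result$modelOrder <- lag

    stage <- "ndte-inference"
    inputs <- c("s50", "s80", "diff")
    ndte <- list()
    for (w in names(windows)) {
      for (inp in inputs) {
        parts <- lapply(seq_along(perParticipant), function(pi) {
          es <- highpassEpochs(perParticipant[[pi]][[inp]],
                               config$highpassHz)
          es <- extractWindow(es, windows[[w]][1L], windows[[w]][2L])
          lapply(seq_len(nTrials(es)), function(k)
            surrogatePvalues(es, lag, config$nSurrogates, trial = k,
                             seed = seeds$surrogates + 1000L * pi + k))
        })
        key <- paste(w, inp, sep = ".")
        ndte[[key]] <- standardizeAndMask(parts, q = config$fdrQ)
        writeNDTEMatrix(ndte[[key]], file.path(outDir, key),
                        extra = list(lag = lag@lagSamples,
                                     nSurrogates = config$nSurrogates))
      }
    }
    result$ndte <- ndte

    stage <- "fric"
    fric <- lapply(names(ndte), function(key) {
      M <- flows(ndte[[key]])
      M[is.na(M)] <- 0
      fr <- findFric(M, alpha = config$fricAlpha, nMc = config$fricNMc,
                     seed = seeds$fric)
      writeFricResult(fr, file.path(outDir, paste0(key, "_fric.json")))
      fr
    })
    names(fric) <- names(ndte)
    result$fric <- fric

    stage <- "erp-cluster"
    erpArrays <- lapply(c("s50", "s80"), function(inp) {
      arrs <- lapply(perParticipant, function(pp) {
        d <- epochData(pp[[inp]])
        apply(d, c(2L, 3L), mean)           # ERP: channels x time
      })
      arr <- array(0, c(length(arrs), dim(arrs[[1L]])))
      for (i in seq_along(arrs)) arr[i, , ] <- arrs[[i]]
      arr
    })
    adj <- completeAdjacency(config$nRois)
    result$erp <- clusterPermutationTest(
      erpArrays[[1L]], erpArrays[[2L]], adj, nPerm = config$erpNPerm,
      thresholdP = config$erpThresholdP,
      minNeighbors = config$erpMinNeighbors, seed = seeds$erp)

    stage <- "entrainment"
    entrain <- entrainmentStage(perParticipant, config, seeds$entrain)
    result$entrainment <- entrain

    stage <- "behavior-link"
    deltas <- rtConditionDifference(design, config$rtCutoffMs)
    key <- "post_target.diff"
    Zp <- participantFlows(ndte[[key]])
    nMasked <- sum(significanceMask(ndte[[key]]))
    if (nMasked >= 1L) {
      k <- min(config$topK, nMasked)
      top <- topKConnections(ndte[[key]], k)
      labs <- rownames(flows(ndte[[key]]))
      nP <- dim(Zp)[1L]
      conn <- vapply(seq_len(nrow(top)), function(j)
        Zp[, match(top$target[j], labs), match(top$source[j], labs)],
        numeric(nP))
      conn <- matrix(conn, nrow = nP)
      colnames(conn) <- paste(top$target, top$source, sep = "<-")
      pids <- vapply(perParticipant, function(pp)
        participantId(pp$s50), integer(1L))
      keep <- match(as.character(pids), names(deltas))
      ok <- !is.na(keep)
      res <- correlateRtFc(deltas[keep[ok]],
                           conn[ok, , drop = FALSE], q = config$fdrQ)
      res <- cbind(top, res[, c("r", "p_raw", "p_corrected", "significant")])
      utils::write.table(res, file.path(outDir, "rt_fc_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      result$behavior <- res
    } else result$behavior <- NULL

    stage <- "manifest"
    manifest <- list(package = "ndteflow",
                     version = as.character(utils::packageVersion("ndteflow")),
                     config = config, stage_seeds = seeds,
                     model_order = lag@lagSamples,
                     windows = windows,
                     n_matrices = length(ndte),
                     masked_pairs = vapply(ndte, function(m)
                       sum(significanceMask(m)), numeric(1L)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
    invisible(result)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs retained in ", outDir, ")", call. = FALSE)
  })
}

#' Complete (all-to-all) channel adjacency
#'
#' @param n number of channels.
#' @return neighbor list where every channel neighbors every other.
#' @export
completeAdjacency <- function(n) {
  adj <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  names(adj) <- paste0("R", seq_len(n))
  adj
}

entrainmentStage <- function(perParticipant, config, seed) {
  band <- config$entrainBand
  win <- config$entrainWindowMs
  base <- config$baselineWindowMs
  nP <- length(perParticipant)
  plv <- bp50 <- bp80 <- NULL
  plvByCond <- matrix(NA_real_, nP, 2L,
                      dimnames = list(NULL, c("s50", "s80")))
  bpRatio <- array(NA_real_, c(nP, 2L, config$nRois))
  for (pi in seq_len(nP)) {
    for (ci in 1:2) {
      inp <- c("s50", "s80")[ci]
      es <- perParticipant[[pi]][[inp]]
      post <- extractWindow(es, win[1L], win[2L])
      bl <- extractWindow(es, base[1L], base[2L])
      bpRatio[pi, ci, ] <- welchBandpower(
        post, band, binSpacingHz = config$psdBinSpacingHz, baseline = bl)
      plvByCond[pi, ci] <- mean(hilbertPlv(post, band))
    }
  }
  plvTest <- permutationTestScalar(plvByCond[, "s80"], plvByCond[, "s50"],
                                   nPerm = config$nPermScalar, seed = seed)
  bpP <- vapply(seq_len(config$nRois), function(ch)
    permutationTestScalar(bpRatio[, 2L, ch], bpRatio[, 1L, ch],
                          nPerm = config$nPermScalar,
                          seed = seed + ch)$p, numeric(1L))
  list(plvByCondition = plvByCond, plvTest = plvTest,
       bandpowerRatio = bpRatio, bandpowerP = bpP,
       bandpowerMask = bhFdr(bpP, config$fdrQ))
}
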