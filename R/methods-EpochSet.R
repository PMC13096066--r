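#' Construct an EpochSet
#'
#' @param data numeric array, trials x regions x samples.
#' @param fsHz sampling rate (samples/second).
#' @param t0Ms time of the first sample relative to cue onset (ms).
#' @param regionLabels character vector of unique region labels; defaults to
#'   `R1..Rn`.
#' @param condition per-trial condition labels; recycled if length 1.
#' @param participantId integer participant identifier.
#'
#' @return an [EpochSet-class] object.
#' @examples
#' es <- EpochSet(array(rnorm(2 * 3 * 10), c(2, 3, 10)), fsHz = 100,
#'                t0Ms = -50)
#' nTrials(es)
#' @export
EpochSet <- function(data, fsHz, t0Ms,
                     regionLabels = paste0("R", seq_len(dim(data)[2L])),
                     condition = rep("unspecified", dim(data)[1L]),
                     participantId = 1L) {
  if (length(condition) == 1L) condition <- rep(condition, dim(data)[1L])
  new("EpochSet", data = data, fsHz = as.numeric(fsHz),
      t0Ms = as.numeric(t0Ms), regionLabels = as.character(regionLabels),
      condition = as.character(condition),
      participantId = as.integer(participantId))
}

#' Accessors for EpochSet objects
#'
#' `epochData` returns the trials x regions x samples array; `samplingRate`
#' the sampling rate in Hz; `epochStartMs` the time of the first sample
#' relative to cue onset; `epochTimesMs` the full per-sample time axis;
#' `conditions` the per-trial condition labels.
#'
#' @param x an `EpochSet`.
#' @name EpochSet-accessors
#' @aliases epochData samplingRate epochStartMs regionLabels conditions
#'   participantId nTrials nRegions nSamples epochTimesMs
NULL

#' @rdname EpochSet-accessors
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fsHz)

#' @rdname EpochSet-accessors
#' @export
setMethod("epochStartMs", "EpochSet", function(x) x@t0Ms)

#' @rdname EpochSet-accessors
#' @export
setMethod("regionLabels", "EpochSet", function(x) x@regionLabels)

#' @rdname EpochSet-accessors
#' @export
setMethod("conditions", "EpochSet", function(x) x@condition)

#' @rdname EpochSet-accessors
#' @export
setMethod("participantId", "EpochSet", function(x) x@participantId)

#' @rdname EpochSet-accessors
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])

#' @rdname EpochSet-accessors
#' @export
setMethod("nRegions", "EpochSet", function(x) dim(x@data)[2L])

#' @rdname EpochSet-accessors
#' @export
setMethod("nSamples", "EpochSet", function(x) dim(x@data)[3L])

#' @rdname EpochSet-accessors
#' @export
setMethod("epochTimesMs", "EpochSet", function(x)
  x@t0Ms + (seq_len(dim(x@data)[3L]) - 1L) * 1000 / x@fsHz)

#' @rdname DifferenceEpochSet-class
#' @export
setMethod("pairMap", "DifferenceEpochSet", function(x) x@pairMap)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(class(object), ": ", d[1L], " trials x ", d[2L], " regions x ",
      d[3L], " samples\n", sep = "")
  cat("  fs = ", object@fsHz, " Hz, t0 = ", object@t0Ms,
      " ms relative to cue onset\n", sep = "")
  cat("  participant ", object@participantId, "; conditions: ",
      paste(unique(object@condition), collapse = ", "), "\n", sep = "")
})

#' Subset trials of an EpochSet
#'
#' @param x an `EpochSet`.
#' @param i trial indices (integer or logical).
#' @param j,...,drop ignored.
#' @return an `EpochSet` with the selected trials.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochSet", data = x@data[i, , , drop = FALSE], fsHz = x@fsHz,
      t0Ms = x@t0Ms, regionLabels = x@regionLabels,
      condition = x@condition[i], participantId = x@participantId)
})

setMethod("show", "ModelOrder", function(object) {
  cat("ModelOrder: lag = ", object@lagSamples, " samples (",
      signif(object@lagMs, 4), " ms), averaged over ",
      length(object@perUnitLags), " region/trial ACF minima\n", sep = "")
})

#' @rdname ModelOrder-class
#' @export
setMethod("lagSamples", "ModelOrder", function(x) x@lagSamples)

#' @rdname FlowMatrix-class
#' @export
setMethod("flows", "FlowMatrix", function(x) x@flow)

#' @rdname ModelOrder-class
#' @export
setMethod("lagSamples", "FlowMatrix", function(x) x@lag@lagSamples)

setMethod("show", "FlowMatrix", function(object) {
  cat("FlowMatrix: ", nrow(object@flow), " x ", ncol(object@flow),
      " raw NDTE flows (entry [i, j] = flow j -> i), lag = ",
      object@lag@lagSamples, " samples\n", sep = "")
})

#' @rdname NDTEMatrix-class
#' @export
setMethod("flows", "NDTEMatrix", function(x) x@Z)

#' @rdname NDTEMatrix-class
#' @export
setMethod("significanceMask", "NDTEMatrix", function(x) x@mask)

#' @rdname NDTEMatrix-class
#' @export
setMethod("groupPvalues", "NDTEMatrix", function(x) x@pGroup)

#' @rdname NDTEMatrix-class
#' @export
setMethod("participantFlows", "NDTEMatrix", function(x) x@ZParticipant)

setMethod("show", "NDTEMatrix", function(object) {
  cat("NDTEMatrix: ", nrow(object@Z), " regions, ", sum(object@mask),
      " significant directed pairs at FDR q = ", object@q,
      "\n  (entry [i, j] = standardized flow j -> i)\n", sep = "")
})

#' @rdname FRICResult-class
#' @export
setMethod("clubMembers", "FRICResult", function(x) x@club)

#' @rdname FRICResult-class
#' @export
setMethod("inflowRanking", "FRICResult", function(x) x@ranking)

setMethod("show", "FRICResult", function(object) {
  cat("FRICResult: ", if (object@significant) "" else "no significant club; ",
      "club of size ", length(object@club), " {",
      paste(object@club, collapse = ", "), "}\n", sep = "")
  cat("  tested sizes k = ", paste(names(object@pValues), collapse = ", "),
      "; alpha = ", object@alpha, ", nMc = ", object@nMc, "\n", sep = "")
})

#' @rdname ClusterResult-class
#' @export
setMethod("clusterPvalues", "ClusterResult", function(x) x@pValues)

#' @rdname ClusterResult-class
#' @export
setMethod("tMap", "ClusterResult", function(x) x@tMap)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: ", length(object@clusters), " cluster(s), ",
      sum(object@pValues < 0.05), " with p < 0.05 (",
      object@nPerm, " permutations, |t| threshold ",
      signif(object@threshold, 4), ")\n", sep = "")
})
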