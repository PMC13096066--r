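#' @import methods
NULL

#' EpochSet: epoched multi-region time series
#'
#' The universal data container of the pipeline: a trials x regions x
#' samples numeric array together with the sampling rate, the time of the
#' first sample relative to cue onset, region labels, a per-trial condition
#' label and the participant the epochs belong to.
#'
#' @slot data numeric array, trials x regions x samples, in signal units
#'   (microvolts for channel data, source units for ROI data).
#' @slot fsHz sampling rate in samples/second.
#' @slot t0Ms time of the first sample relative to cue onset, milliseconds.
#' @slot regionLabels character vector, one unique label per region.
#' @slot condition character vector, one condition label per trial.
#' @slot participantId integer scalar identifying the participant.
#'
#' @seealso [EpochSet()] for the user-facing constructor.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    fsHz = "numeric",
    t0Ms = "numeric",
    regionLabels = "character",
    condition = "character",
    participantId = "integer"
  )
)

setValidity("EpochSet", function(object) {
  d <- object@data
  msg <- character()
  if (length(dim(d)) != 3L)
    msg <- c(msg, "'data' must be a 3-D array (trials x regions x samples)")
  else {
    if (length(object@regionLabels) != dim(d)[2L])
      msg <- c(msg, "length(regionLabels) must equal the number of regions")
    if (length(object@condition) != dim(d)[1L])
      msg <- c(msg, "length(condition) must equal the number of trials")
  }
  if (anyDuplicated(object@regionLabels))
    msg <- c(msg, "regionLabels must be unique")
  if (length(object@fsHz) != 1L || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a single positive number")
  if (length(object@t0Ms) != 1L)
    msg <- c(msg, "t0Ms must be a single number")
  if (length(msg)) msg else TRUE
})

#' DifferenceEpochSet: paired condition-difference epochs
#'
#' An [EpochSet] whose trials are single-trial difference waveforms
#' (50\% predictable minus 80\% predictable), plus the random pairing that
#' produced them.
#'
#' @slot pairMap integer matrix with two columns: the trial index in the
#'   50\%-condition set and the paired trial index in the 80\%-condition set.
#'
#' @exportClass DifferenceEpochSet
setClass("DifferenceEpochSet",
  contains = "EpochSet",
  representation(pairMap = "matrix")
)

setValidity("DifferenceEpochSet", function(object) {
  pm <- object@pairMap
  msg <- character()
  if (ncol(pm) != 2L)
    msg <- c(msg, "pairMap must have two columns (index50, index80)")
  if (nrow(pm) != dim(object@data)[1L])
    msg <- c(msg, "pairMap must have one row per difference trial")
  if (anyDuplicated(pm[, 1L]) || anyDuplicated(pm[, 2L]))
    msg <- c(msg, "each source trial may be used at most once")
  if (length(msg)) msg else TRUE
})

#' ModelOrder: NDTE embedding lag
#'
#' The maximum lag (model order) of the NDTE embedding, estimated from the
#' first minimum of the sample autocorrelation function.
#'
#' @slot lagSamples embedding length in samples.
#' @slot lagMs the same lag expressed in milliseconds.
#' @slot perUnitLags numeric vector of the per-region/trial first-minimum
#'   lags that were averaged to obtain `lagSamples`.
#'
#' @exportClass ModelOrder
setClass("ModelOrder",
  representation(lagSamples = "integer", lagMs = "numeric",
                 perUnitLags = "numeric")
)

setValidity("ModelOrder", function(object) {
  if (object@lagSamples < 1L) "lagSamples must be >= 1" else TRUE
})

#' FlowMatrix: raw NDTE flows for one epoch
#'
#' Raw (unstandardized) NDTE flow values between all ordered region pairs of
#' a single epoch. Orientation convention: `flows(x)[i, j]` is the flow from
#' source region `j` into target region `i` (inflow targets along rows,
#' outflow sources along columns).
#'
#' @slot flow numeric regions x regions matrix of NDTE values in [0, 1],
#'   zero diagonal.
#' @slot lag the [ModelOrder] used.
#'
#' @exportClass FlowMatrix
setClass("FlowMatrix",
  representation(flow = "matrix", lag = "ModelOrder")
)

setValidity("FlowMatrix", function(object) {
  f <- object@flow
  msg <- character()
  if (nrow(f) != ncol(f)) msg <- c(msg, "flow matrix must be square")
  if (any(diag(f) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(f < -1e-12 | f > 1 + 1e-12))
    msg <- c(msg, "NDTE values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' NDTEMatrix: standardized, significance-masked flows
#'
#' Group-level inference result: standardized NDTE flows (z relative to the
#' circular-shift surrogate distribution), the shared binary significance
#' mask and the aggregated group p-values. Orientation as in [FlowMatrix]:
#' entry (i, j) is flow from source j into target i.
#'
#' @slot Z regions x regions matrix of standardized flows (group mean over
#'   participants of the per-participant trial-averaged z); NA off-mask.
#' @slot ZParticipant 3-D array participants x regions x regions of
#'   per-participant trial-averaged standardized flows (NA off-mask).
#' @slot mask logical regions x regions matrix, TRUE for significant pairs;
#'   shared across participants; FALSE diagonal.
#' @slot pGroup regions x regions matrix of Stouffer-aggregated group
#'   p-values (NA diagonal).
#' @slot q the FDR level used for the mask.
#'
#' @exportClass NDTEMatrix
setClass("NDTEMatrix",
  representation(Z = "matrix", ZParticipant = "array", mask = "matrix",
                 pGroup = "matrix", q = "numeric")
)

setValidity("NDTEMatrix", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (any(diag(object@mask))) msg <- c(msg, "mask diagonal must be FALSE")
  if (any(object@mask & !is.finite(object@Z)))
    msg <- c(msg, "Z must be finite wherever mask is TRUE")
  if (length(msg)) msg else TRUE
})

#' FRICResult: functional rich-club detection result
#'
#' @slot ranking character vector of region labels sorted by total inflow,
#'   descending (ties broken by label order).
#' @slot club character vector: the detected club (a prefix of `ranking`);
#'   length 1 with `significant = FALSE` when no club size reached
#'   significance.
#' @slot fricValues named numeric vector of FRIC values per tested club
#'   size k (names are the k values).
#' @slot pValues named numeric vector of Monte-Carlo p-values per tested k.
#' @slot nMc number of Monte-Carlo surrogate clubs per tested size.
#' @slot alpha significance level used by the growth rule.
#' @slot significant logical: TRUE when at least one tested size passed.
#'
#' @exportClass FRICResult
setClass("FRICResult",
  representation(ranking = "character", club = "character",
                 fricValues = "numeric", pValues = "numeric",
                 nMc = "integer", alpha = "numeric", significant = "logical")
)

setValidity("FRICResult", function(object) {
  msg <- character()
  if (!all(object@club %in% object@ranking))
    msg <- c(msg, "club must be a subset of ranking")
  if (length(object@club) &&
      !identical(object@club, object@ranking[seq_along(object@club)]))
    msg <- c(msg, "club must be a prefix of the inflow ranking")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: spatiotemporal cluster permutation result
#'
#' @slot clusters list of clusters, each a list with elements `members`
#'   (two-column matrix of channel and time indices), `sign` (+1/-1) and
#'   `mass` (sum of t values).
#' @slot pValues numeric vector, one permutation p-value per cluster.
#' @slot tMap channels x time matrix of paired t statistics.
#' @slot nPerm number of permutations.
#' @slot threshold the cluster-forming t threshold used.
#'
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(clusters = "list", pValues = "numeric", tMap = "matrix",
                 nPerm = "integer", threshold = "numeric")
)
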