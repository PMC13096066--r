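#' @rdname EpochSet-accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochStartMs", function(x) standardGeneric("epochStartMs"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochTimesMs", function(x) standardGeneric("epochTimesMs"))

#' @rdname DifferenceEpochSet-class
#' @param x a `DifferenceEpochSet`.
#' @export
setGeneric("pairMap", function(x) standardGeneric("pairMap"))

#' @rdname FlowMatrix-class
#' @param x a `FlowMatrix` or `NDTEMatrix`.
#' @export
setGeneric("flows", function(x) standardGeneric("flows"))

#' @rdname ModelOrder-class
#' @param x a `ModelOrder` or `FlowMatrix`.
#' @export
setGeneric("lagSamples", function(x) standardGeneric("lagSamples"))

#' @rdname NDTEMatrix-class
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname NDTEMatrix-class
#' @export
setGeneric("groupPvalues", function(x) standardGeneric("groupPvalues"))

#' @rdname NDTEMatrix-class
#' @export
setGeneric("participantFlows", function(x) standardGeneric("participantFlows"))

#' @rdname FRICResult-class
#' @export
setGeneric("clubMembers", function(x) standardGeneric("clubMembers"))

#' @rdname FRICResult-class
#' @export
setGeneric("inflowRanking", function(x) standardGeneric("inflowRanking"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterPvalues", function(x) standardGeneric("clusterPvalues"))

#' @rdname ClusterResult-class
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))
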