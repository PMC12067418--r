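#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("sozMask", function(x) standardGeneric("sozMask"))

#' @rdname accessors
#' @export
setGeneric("onsetSample", function(x) standardGeneric("onsetSample"))

#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))

#' @rdname accessors
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))

#' @rdname accessors
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' @rdname accessors
#' @export
setGeneric("mvarCoefficients", function(x) standardGeneric("mvarCoefficients"))

#' @rdname accessors
#' @export
setGeneric("noiseCovariance", function(x) standardGeneric("noiseCovariance"))

#' @rdname accessors
#' @export
setGeneric("connMethod", function(x) standardGeneric("connMethod"))

#' @rdname accessors
#' @export
setGeneric("connWeights", function(x) standardGeneric("connWeights"))

#' @rdname accessors
#' @export
setGeneric("flowValues", function(x) standardGeneric("flowValues"))

#' @rdname accessors
#' @export
setGeneric("aucTable", function(x) standardGeneric("aucTable"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' Inflow (weighted in-strength) per channel
#'
#' Sum of incoming off-diagonal edge weights per channel: how much directed
#' influence a channel receives from the rest of the network.
#'
#' @param conn a [ConnectivityMatrix-class] (or bare square matrix).
#' @return numeric vector, one value per channel.
#' @export
setGeneric("inflow", function(conn) standardGeneric("inflow"))

#' Outflow (weighted out-strength) per channel
#'
#' Sum of outgoing off-diagonal edge weights per channel: how much directed
#' influence a channel exerts on the rest of the network.
#'
#' @param conn a [ConnectivityMatrix-class] (or bare square matrix).
#' @return numeric vector, one value per channel.
#' @export
setGeneric("outflow", function(conn) standardGeneric("outflow"))
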