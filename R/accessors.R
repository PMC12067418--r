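#' Accessors for ieegflow S4 classes
#'
#' Small accessor family: prefer these over direct slot access.
#'
#' @param x an ieegflow S4 object.
#' @return The requested slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nChannels", "IEEGRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("samplingRate", "IEEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "IEEGRecording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("sozMask", "IEEGRecording", function(x) x@sozMask)
#' @rdname accessors
setMethod("onsetSample", "IEEGRecording", function(x) x@onsetSample)
#' @rdname accessors
setMethod("recordingData", "IEEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("recordingMeta", "IEEGRecording", function(x) x@meta)

#' @rdname accessors
setMethod("samplingRate", "SegmentSet", function(x) x@fs)

#' @rdname accessors
setMethod("modelOrder", "MVARModel", function(x) x@order)
#' @rdname accessors
setMethod("mvarCoefficients", "MVARModel", function(x) x@coeffs)
#' @rdname accessors
setMethod("noiseCovariance", "MVARModel", function(x) x@noiseCov)
#' @rdname accessors
setMethod("nChannels", "MVARModel", function(x) dim(x@coeffs)[1])
#' @rdname accessors
setMethod("samplingRate", "MVARModel", function(x) x@fs)

#' @rdname accessors
setMethod("connMethod", "SpectralConnectivity", function(x) x@method)
#' @rdname accessors
setMethod("connMethod", "ConnectivityMatrix", function(x) x@method)
#' @rdname accessors
setMethod("connWeights", "ConnectivityMatrix", function(x) x@weights)
#' @rdname accessors
setMethod("nChannels", "ConnectivityMatrix", function(x) nrow(x@weights))

#' @rdname accessors
setMethod("flowValues", "FlowSeries", function(x) x@values)
#' @rdname accessors
setMethod("sozMask", "FlowSeries", function(x) x@sozMask)
#' @rdname accessors
setMethod("channelLabels", "FlowSeries", function(x) x@channelLabels)

#' @rdname accessors
setMethod("aucTable", "EvaluationResult", function(x) x@aucTable)
#' @rdname accessors
setMethod("groupLabel", "EvaluationResult", function(x) x@groupLabel)
#' @rdname accessors
setMethod("recordingMeta", "EvaluationResult", function(x) x@meta)

setMethod("show", "IEEGRecording", function(object) {
  cat(sprintf(
    "IEEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs))
  cat(sprintf("  onset at sample %d (%.1f s); %d SOZ / %d non-SOZ channels\n",
              as.integer(object@onsetSample), object@onsetSample / object@fs,
              sum(object@sozMask), sum(!object@sozMask)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "SegmentSet", function(object) {
  d <- dim(object@segments[[1]])
  cat(sprintf("SegmentSet: %d %s windows of %g s (%d channels x %d samples @ %g Hz)\n",
              length(object@segments), object@period, object@windowS,
              d[1], d[2], object@fs))
})

setMethod("show", "MVARModel", function(object) {
  cat(sprintf("MVARModel: order %d, %d channels, fs %g Hz, fitted on %d samples\n",
              object@order, dim(object@coeffs)[1], object@fs,
              object@nSamplesFit))
})

setMethod("show", "SpectralConnectivity", function(object) {
  cat(sprintf("SpectralConnectivity (%s): %d channels on %d frequencies [%g, %g] Hz\n",
              toupper(object@method), dim(object@values)[2],
              length(object@freqs), min(object@freqs), max(object@freqs)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix (%s, %g-%g Hz%s): %d channels, %s\n",
              toupper(object@method), object@band[1], object@band[2],
              if (isTRUE(object@thresholded)) ", surrogate-thresholded" else "",
              nrow(object@weights),
              if (is.na(object@period)) "unlabelled period"
              else sprintf("%s segment %d", object@period, object@segmentIndex)))
})

setMethod("show", "FlowSeries", function(object) {
  cat(sprintf("FlowSeries: %s %s (%s), %d segments x %d channels\n",
              toupper(object@method), object@measure, object@period,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult: %s (%d AUC entries)\n",
              object@groupLabel, nrow(object@aucTable)))
  if (nrow(object@aucTable)) {
    agg <- stats::aggregate(auc ~ method + measure + period,
                            data = object@aucTable, FUN = stats::median)
    print(agg, row.names = FALSE)
  }
})
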