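#' @import methods
NULL

#' Multichannel intracranial EEG recording
#'
#' Container for one seizure's worth of multichannel iEEG: a channels-by-samples
#' signal matrix, its sampling rate, the electrical seizure-onset boundary, the
#' clinician-annotated seizure-onset-zone (SOZ) channel set, and free-form
#' metadata (dataset, patient and seizure identifiers, implant type, lesional
#' status, ...).
#'
#' `onsetSample` is the number of samples preceding electrical onset: the
#' preictal period is `data[, 1:onsetSample]` and the ictal period starts at
#' column `onsetSample + 1`.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels unique channel names, one per row of `data`.
#' @slot onsetSample integer sample count before electrical seizure onset
#'   (0 <= onsetSample <= ncol(data)).
#' @slot sozMask logical vector flagging SOZ channels.
#' @slot meta named list of recording metadata.
#'
#' @seealso [IEEGRecording()] for the constructor, [validateRecording()],
#'   [segmentEpoch()].
#' @export
setClass("IEEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    onsetSample = "numeric",
    sozMask = "logical",
    meta = "list"
  )
)

setValidity("IEEGRecording", function(object) {
  msg <- character()
  n <- nrow(object@data)
  if (n < 2L) msg <- c(msg, "a recording needs at least 2 channels")
  if (length(object@channelLabels) != n)
    msg <- c(msg, "channelLabels length must equal nrow(data)")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@sozMask) != n)
    msg <- c(msg, "sozMask length must equal nrow(data)")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@onsetSample) != 1L || object@onsetSample < 0 ||
      object@onsetSample > ncol(object@data))
    msg <- c(msg, "onsetSample must lie in [0, n_samples]")
  if (length(msg)) msg else TRUE
})

#' Construct an IEEGRecording
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate (Hz).
#' @param channelLabels character vector of unique channel names; defaults to
#'   rownames of `data` or `"ch01"`, `"ch02"`, ...
#' @param onsetSample number of samples before electrical seizure onset.
#' @param sozMask logical vector marking seizure-onset-zone channels.
#' @param meta named list of metadata.
#' @return An [IEEGRecording-class] object.
#' @examples
#' x <- matrix(rnorm(4 * 1000), 4)
#' rec <- IEEGRecording(x, fs = 500, onsetSample = 500,
#'                      sozMask = c(TRUE, FALSE, FALSE, FALSE))
#' @export
IEEGRecording <- function(data, fs, channelLabels = NULL, onsetSample = 0L,
                          sozMask = logical(nrow(data)), meta = list()) {
  data <- as.matrix(data)
  if (is.null(channelLabels)) {
    channelLabels <- rownames(data)
    if (is.null(channelLabels))
      channelLabels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  rownames(data) <- channelLabels
  new("IEEGRecording", data = data, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels),
      onsetSample = as.numeric(onsetSample),
      sozMask = as.logical(sozMask), meta = meta)
}

#' Set of equally-sized non-overlapping analysis windows
#'
#' Result of partitioning a 28-s preictal or ictal epoch into contiguous 4-s
#' windows, each short enough for the quasi-stationarity that MVAR modelling
#' assumes.
#'
#' @slot segments list of channels x samples matrices, identical shapes.
#' @slot fs sampling rate in Hz.
#' @slot period `"preictal"` or `"ictal"`.
#' @slot windowS window length in seconds.
#' @slot origin identifier of the source recording.
#' @export
setClass("SegmentSet",
  representation(
    segments = "list",
    fs = "numeric",
    period = "character",
    windowS = "numeric",
    origin = "character"
  )
)

setValidity("SegmentSet", function(object) {
  msg <- character()
  if (!length(object@segments)) msg <- c(msg, "empty segment list")
  dims <- vapply(object@segments, dim, integer(2))
  if (length(object@segments) && any(dims != dims[, 1]))
    msg <- c(msg, "all segments must have identical shape")
  nWin <- round(object@windowS * object@fs)
  if (length(object@segments) && dims[2, 1] != nWin)
    msg <- c(msg, "segment width must equal windowS * fs")
  if (!object@period %in% c("preictal", "ictal"))
    msg <- c(msg, "period must be 'preictal' or 'ictal'")
  if (length(msg)) msg else TRUE
})

#' Fitted multivariate autoregressive model
#'
#' An order-p MVAR model x_t = sum_k A_k x_{t-k} + e_t fitted to one analysis
#' window. `coeffs[i, j, k]` is the effect of channel j at lag k on channel i;
#' `noiseCov` is the innovation covariance of e_t.
#'
#' @slot order model order p.
#' @slot coeffs numeric array n x n x p of lag coefficient matrices.
#' @slot noiseCov symmetric positive-semidefinite innovation covariance.
#' @slot fs sampling rate of the fitted data (Hz), needed to map lags to
#'   frequencies.
#' @slot nSamplesFit number of time samples the model was fitted on.
#' @export
setClass("MVARModel",
  representation(
    order = "integer",
    coeffs = "array",
    noiseCov = "matrix",
    fs = "numeric",
    nSamplesFit = "integer"
  )
)

setValidity("MVARModel", function(object) {
  msg <- character()
  d <- dim(object@coeffs)
  if (length(d) != 3L || d[1] != d[2])
    msg <- c(msg, "coeffs must be an n x n x p array")
  else if (d[3] != object@order)
    msg <- c(msg, "third coeffs dimension must equal order")
  if (!all(is.finite(object@coeffs)))
    msg <- c(msg, "coefficients must be finite")
  if (!isTRUE(all.equal(object@noiseCov, t(object@noiseCov),
                        tolerance = 1e-9, check.attributes = FALSE)))
    msg <- c(msg, "noiseCov must be symmetric (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Construct an MVARModel
#'
#' @param coeffs n x n x p array of lag coefficient matrices (a single n x n
#'   matrix is promoted to p = 1).
#' @param noiseCov innovation covariance (defaults to the identity).
#' @param fs sampling rate in Hz.
#' @param nSamplesFit number of samples the model was fitted on (0 for
#'   constructed models).
#' @return An [MVARModel-class] object.
#' @export
MVARModel <- function(coeffs, noiseCov = NULL, fs = 500, nSamplesFit = 0L) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(dim(coeffs), 1L))
  n <- dim(coeffs)[1]
  if (is.null(noiseCov)) noiseCov <- diag(n)
  new("MVARModel", order = as.integer(dim(coeffs)[3]), coeffs = coeffs,
      noiseCov = as.matrix(noiseCov), fs = as.numeric(fs),
      nSamplesFit = as.integer(nSamplesFit))
}

#' Frequency-resolved directed connectivity
#'
#' PDC or DTF magnitudes on a frequency grid. `values[f, i, j]` is the
#' directed influence of channel j on channel i at `freqs[f]`, in [0, 1].
#' PDC is column-normalized (for every frequency and source j the squared
#' magnitudes over targets sum to 1); DTF is row-normalized (for every
#' frequency and target i the squared magnitudes over sources sum to 1).
#'
#' @slot method `"pdc"` or `"dtf"`.
#' @slot freqs frequency grid in Hz.
#' @slot values numeric array n_freqs x n x n.
#' @export
setClass("SpectralConnectivity",
  representation(
    method = "character",
    freqs = "numeric",
    values = "array"
  )
)

setValidity("SpectralConnectivity", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L || d[1] != length(object@freqs) || d[2] != d[3])
    msg <- c(msg, "values must be n_freqs x n x n")
  if (!object@method %in% c("pdc", "dtf"))
    msg <- c(msg, "method must be 'pdc' or 'dtf'")
  if (any(object@values < -1e-12 | object@values > 1 + 1e-12))
    msg <- c(msg, "values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Band-aggregated directed connectivity matrix
#'
#' One directed weighted graph per analysis window: `weights[i, j]` is the
#' band-averaged influence of channel j on channel i (diagonal fixed at 0).
#' After surrogate pruning ([thresholdConnectivity()]) `thresholded` is TRUE
#' and non-significant edges are 0.
#'
#' @slot method `"pdc"` or `"dtf"`.
#' @slot band aggregation band `(low, high)` in Hz.
#' @slot weights n x n numeric matrix in [0, 1], zero diagonal.
#' @slot thresholded TRUE once surrogate-pruned.
#' @slot segmentIndex index of the source window within its epoch.
#' @slot period `"preictal"`, `"ictal"` or NA.
#' @export
setClass("ConnectivityMatrix",
  representation(
    method = "character",
    band = "numeric",
    weights = "matrix",
    thresholded = "logical",
    segmentIndex = "integer",
    period = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  if (nrow(object@weights) != ncol(object@weights))
    msg <- c(msg, "weights must be square")
  if (any(object@weights < -1e-12 | object@weights > 1 + 1e-12))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (length(object@band) != 2L || object@band[1] > object@band[2])
    msg <- c(msg, "band must be (low, high) with low <= high")
  if (length(msg)) msg else TRUE
})

#' Surrogate null distribution of edge weights
#'
#' Band-aggregated connectivity of `nSurrogates` phase-randomized copies of
#' one analysis window, forming the per-edge empirical null of no true
#' cross-channel interaction.
#'
#' @slot method `"pdc"` or `"dtf"`.
#' @slot nullWeights numeric array n_surrogates x n x n.
#' @slot alpha significance level the null was built for.
#' @export
setClass("SurrogateNull",
  representation(
    method = "character",
    nullWeights = "array",
    alpha = "numeric"
  )
)

setValidity("SurrogateNull", function(object) {
  msg <- character()
  d <- dim(object@nullWeights)
  if (length(d) != 3L || d[2] != d[3])
    msg <- c(msg, "nullWeights must be n_surrogates x n x n")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (d[1] * object@alpha < 1 && d[1] < 20)
    msg <- c(msg, "need >= 20 surrogates for the default alpha to resolve")
  if (length(msg)) msg else TRUE
})

#' Per-channel flow dynamics across analysis windows
#'
#' Normalized inflow or outflow of every channel in each of the (by default
#' seven) windows of one epoch: `values[s, c]` is the min-max normalized
#' in-/out-strength of channel c in window s.
#'
#' @slot method `"pdc"` or `"dtf"`.
#' @slot measure `"inflow"` or `"outflow"`.
#' @slot period `"preictal"` or `"ictal"`.
#' @slot values numeric matrix n_segments x n_channels in [0, 1].
#' @slot channelLabels channel names.
#' @slot sozMask logical SOZ flags.
#' @export
setClass("FlowSeries",
  representation(
    method = "character",
    measure = "character",
    period = "character",
    values = "matrix",
    channelLabels = "character",
    sozMask = "logical"
  )
)

setValidity("FlowSeries", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@sozMask))
    msg <- c(msg, "sozMask length must equal number of channels")
  if (ncol(object@values) != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must equal number of channels")
  if (!object@measure %in% c("inflow", "outflow"))
    msg <- c(msg, "measure must be 'inflow' or 'outflow'")
  if (any(object@values < -1e-12 | object@values > 1 + 1e-12))
    msg <- c(msg, "normalized values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Evaluation result for one seizure
#'
#' SOZ-discrimination AUCs per (method, measure, period), the statistical
#' tests behind the regime classification, and the assigned regime label.
#'
#' @slot aucTable data.frame with columns patient, seizure, method, measure,
#'   period, auc.
#' @slot groupLabel `"inflow_dominant"`, `"outflow_dominant"` or
#'   `"unclassified"`.
#' @slot tests data.frame with columns name, statistic, p_raw, p_adjusted,
#'   effect_size_d.
#' @slot meta recording metadata carried through (includes ground truth for
#'   synthetic data).
#' @export
setClass("EvaluationResult",
  representation(
    aucTable = "data.frame",
    groupLabel = "character",
    tests = "data.frame",
    meta = "list"
  )
)

setValidity("EvaluationResult", function(object) {
  msg <- character()
  if (!object@groupLabel %in%
      c("inflow_dominant", "outflow_dominant", "unclassified"))
    msg <- c(msg, "unknown groupLabel")
  if (nrow(object@aucTable) &&
      any(object@aucTable$auc < 0 | object@aucTable$auc > 1, na.rm = TRUE))
    msg <- c(msg, "AUC values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
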