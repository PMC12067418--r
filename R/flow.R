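#' @rdname inflow
setMethod("inflow", "ConnectivityMatrix", function(conn) {
  W <- conn@weights
  rowSums(W) - diag(W)
})

#' @rdname inflow
setMethod("inflow", "matrix", function(conn) {
  stopifnot(nrow(conn) == ncol(conn))
  rowSums(conn) - diag(conn)
})

#' @rdname outflow
setMethod("outflow", "ConnectivityMatrix", function(conn) {
  W <- conn@weights
  colSums(W) - diag(W)
})

#' @rdname outflow
setMethod("outflow", "matrix", function(conn) {
  stopifnot(nrow(conn) == ncol(conn))
  colSums(conn) - diag(conn)
})

#' Min-max normalize a score vector to [0, 1]
#'
#' `(x - min) / (max - min)` across channels; a constant vector maps to all
#' zeros (no channel stands out, so none should score). Applied per analysis
#' window so the 0-1 ROC threshold sweep is well-defined within each window.
#'
#' @param values numeric vector.
#' @return numeric vector in [0, 1].
#' @examples
#' normalizeScores(c(2, 4, 6)) # 0, 0.5, 1
#' @export
normalizeScores <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Assemble per-channel flow dynamics across an epoch's windows
#'
#' Reduces each window's connectivity matrix to per-channel in- or
#' out-strength, min-max normalizes within the window, and stacks the windows
#' into a segments x channels matrix.
#'
#' @param conns list of [ConnectivityMatrix-class], one per window, identical
#'   channel sets, method and period.
#' @param measure `"inflow"` or `"outflow"`.
#' @param sozMask logical SOZ flags (one per channel).
#' @param channelLabels optional channel names.
#' @return A [FlowSeries-class].
#' @export
assembleFlowSeries <- function(conns, measure = c("inflow", "outflow"),
                               sozMask, channelLabels = NULL) {
  measure <- match.arg(measure)
  stopifnot(length(conns) >= 1, all(vapply(conns, is, TRUE, "ConnectivityMatrix")))
  n <- nrow(conns[[1]]@weights)
  if (any(vapply(conns, function(cm) nrow(cm@weights), 0L) != n))
    stop("segments have inconsistent channel sets")
  if (length(unique(vapply(conns, function(cm) cm@method, ""))) != 1L)
    stop("segments mix connectivity methods")
  if (length(sozMask) != n) stop("sozMask length must equal channel count")
  if (is.null(channelLabels)) channelLabels <- sprintf("ch%02d", seq_len(n))
  fn <- if (measure == "inflow") inflow else outflow
  vals <- t(vapply(conns, function(cm) normalizeScores(fn(cm)), numeric(n)))
  period <- conns[[1]]@period
  new("FlowSeries", method = conns[[1]]@method, measure = measure,
      period = if (is.na(period)) "preictal" else period,
      values = vals, channelLabels = as.character(channelLabels),
      sozMask = as.logical(sozMask))
}

#' Export a FlowSeries as a tidy long-format data.frame
#'
#' One row per (segment, channel) with the normalized value and SOZ flag;
#' convenient for CSV export and plotting.
#'
#' @param flow a [FlowSeries-class].
#' @return data.frame with columns segment, channel, method, measure, period,
#'   normalized_value, is_soz.
#' @export
flowSeriesToLong <- function(flow) {
  stopifnot(is(flow, "FlowSeries"))
  nSeg <- nrow(flow@values)
  n <- ncol(flow@values)
  data.frame(
    segment = rep(seq_len(nSeg), times = n),
    channel = rep(flow@channelLabels, each = nSeg),
    method = flow@method,
    measure = flow@measure,
    period = flow@period,
    normalized_value = as.vector(flow@values),
    is_soz = rep(flow@sozMask, each = nSeg),
    stringsAsFactors = FALSE
  )
}
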