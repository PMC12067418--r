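#' Screen a recording against the cohort inclusion rules
#'
#' A recording is rejected when its sampling rate is below `minFs` (too low
#' for reliable MVAR modelling) or when less than `minPreictalS` seconds of
#' signal precede electrical onset. This is a total function: it never
#' errors, it reports.
#'
#' @param rec an [IEEGRecording-class].
#' @param minFs minimum acceptable sampling rate in Hz (default 500).
#' @param minPreictalS minimum preictal duration in seconds (default 30).
#' @return A list with `accepted` (logical) and `reason` (character,
#'   `NA` when accepted; semicolon-separated when several rules fail).
#' @examples
#' rec <- IEEGRecording(matrix(rnorm(500), 2), fs = 250, onsetSample = 200)
#' validateRecording(rec)$reason
#' @export
validateRecording <- function(rec, minFs = 500, minPreictalS = 30) {
  stopifnot(is(rec, "IEEGRecording"))
  reasons <- character()
  if (rec@fs < minFs)
    reasons <- c(reasons, sprintf("sampling rate below %g Hz", minFs))
  if (rec@onsetSample / rec@fs < minPreictalS)
    reasons <- c(reasons, sprintf("<%g s of preictal activity", minPreictalS))
  list(accepted = length(reasons) == 0L,
       reason = if (length(reasons)) paste(reasons, collapse = "; ")
                else NA_character_)
}

# RBJ audio-EQ-cookbook notch biquad at f0 Hz with quality factor Q.
.notchCoefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase band-pass and power-line notch filtering
#'
#' Applies, per channel, a forward-backward (zero-phase) Butterworth band-pass
#' realized as a cascade of a 4th-order high-pass and a 3rd-order low-pass,
#' followed by a zero-phase second-order notch (Q = 30). The asymmetric
#' orders are deliberate: the high-pass side can be steep (next to no signal
#' lives below 3 Hz), while the low-pass side is kept as gentle as the
#' stop-band requirement allows, because hard band-limiting makes the
#' filtered process nearly non-invertible and that corrupts the MVAR fits
#' the directed-connectivity estimates rest on.
#'
#' @param rec an [IEEGRecording-class].
#' @param low,high band-pass corner frequencies in Hz (defaults 3 and 45).
#' @param notch power-line notch frequency in Hz (default 60); `NA` disables
#'   the notch (useful when it sits outside the retained band anyway).
#' @return The filtered recording; shape and metadata unchanged.
#' @export
bandpassNotch <- function(rec, low = 3, high = 45, notch = 60) {
  stopifnot(is(rec, "IEEGRecording"))
  nyq <- rec@fs / 2
  if (high >= nyq)
    stop(sprintf("band-pass upper edge (%g Hz) must be below Nyquist (%g Hz)",
                 high, nyq))
  if (low <= 0 || low >= high)
    stop("need 0 < low < high")
  hp <- signal::butter(4, low / nyq, type = "high")
  lp <- signal::butter(3, high / nyq, type = "low")
  nt <- if (!is.na(notch) && notch < nyq) .notchCoefficients(notch, rec@fs)
  out <- rec@data
  for (i in seq_len(nrow(out))) {
    y <- signal::filtfilt(lp, signal::filtfilt(hp, out[i, ]))
    if (!is.null(nt)) y <- signal::filtfilt(signal::Arma(b = nt$b, a = nt$a), y)
    out[i, ] <- y
  }
  initialize(rec, data = out)
}

#' Downsample a recording to a target rate
#'
#' Polyphase resampling (FIR anti-alias filtering) per channel. Upsampling is
#' refused; the onset boundary is rescaled by `round(onset * targetFs / fs)`.
#'
#' @param rec an [IEEGRecording-class].
#' @param targetFs target sampling rate in Hz (default 500); must not exceed
#'   the current rate.
#' @return The resampled recording.
#' @export
resampleTo <- function(rec, targetFs = 500) {
  stopifnot(is(rec, "IEEGRecording"))
  if (targetFs > rec@fs)
    stop(sprintf("target rate %g Hz exceeds recording rate %g Hz (no upsampling)",
                 targetFs, rec@fs))
  if (targetFs == rec@fs) return(rec)
  if (rec@fs %% 1 != 0 || targetFs %% 1 != 0)
    stop("resampling requires integer sampling rates")
  g <- .gcd(targetFs, rec@fs)
  p <- targetFs / g
  q <- rec@fs / g
  out <- t(apply(rec@data, 1, function(x) signal::resample(x, p, q)))
  initialize(rec, data = out, fs = as.numeric(targetFs),
             onsetSample = round(rec@onsetSample * targetFs / rec@fs))
}

#' Standardize each channel to zero mean and unit variance
#'
#' Z-scoring is computed over the full retained recording (not per window) so
#' that amplitude differences between channels do not leak into the MVAR
#' coefficients while within-epoch dynamics are preserved.
#'
#' @param rec an [IEEGRecording-class].
#' @return The standardized recording.
#' @export
zscoreChannels <- function(rec) {
  stopifnot(is(rec, "IEEGRecording"))
  sds <- apply(rec@data, 1, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop(sprintf("constant channel(s) cannot be z-scored: %s",
                 paste(rec@channelLabels[bad], collapse = ", ")))
  initialize(rec, data = (rec@data - rowMeans(rec@data)) / sds)
}

#' Partition an epoch into non-overlapping analysis windows
#'
#' Extracts the `epochS`-second preictal epoch ending exactly at onset, or the
#' ictal epoch starting exactly at onset, and cuts it into contiguous
#' `windowS`-second windows (seven 4-s windows under the defaults). Epoch
#' lengths that are not an exact multiple of the window are refused.
#'
#' @param rec an [IEEGRecording-class].
#' @param period `"preictal"` or `"ictal"`.
#' @param epochS epoch length in seconds (default 28).
#' @param windowS window length in seconds (default 4).
#' @return A [SegmentSet-class] with `epochS / windowS` windows in temporal
#'   order.
#' @export
segmentEpoch <- function(rec, period = c("preictal", "ictal"),
                         epochS = 28, windowS = 4) {
  stopifnot(is(rec, "IEEGRecording"))
  period <- match.arg(period)
  if (abs(epochS / windowS - round(epochS / windowS)) > 1e-9)
    stop(sprintf("epoch (%g s) must be an exact multiple of the window (%g s)",
                 epochS, windowS))
  nEpoch <- round(epochS * rec@fs)
  nWin <- round(windowS * rec@fs)
  onset <- round(rec@onsetSample)
  if (period == "preictal") {
    if (onset < nEpoch)
      stop(sprintf("preictal epoch needs %d samples before onset, have %d",
                   nEpoch, onset))
    idx <- (onset - nEpoch + 1L):onset
  } else {
    if (ncol(rec@data) - onset < nEpoch)
      stop(sprintf("ictal epoch needs %d samples after onset, have %d",
                   nEpoch, ncol(rec@data) - onset))
    idx <- (onset + 1L):(onset + nEpoch)
  }
  block <- rec@data[, idx, drop = FALSE]
  k <- nEpoch %/% nWin
  segs <- lapply(seq_len(k), function(s)
    block[, ((s - 1L) * nWin + 1L):(s * nWin), drop = FALSE])
  origin <- if (!is.null(rec@meta$id)) as.character(rec@meta$id) else ""
  new("SegmentSet", segments = segs, fs = rec@fs, period = period,
      windowS = as.numeric(windowS), origin = origin)
}
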