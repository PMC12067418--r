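#' Write a recording in the plain-text fixture format
#'
#' The fixture format is a pair of files: `<stem>.tsv` holding the signal as
#' samples x channels with channel labels in the header, and `<stem>.json`
#' holding the sampling rate, onset sample, SOZ channel labels, any bad
#' channels to drop on load, and free metadata. Text-only, so fixtures diff
#' and version cleanly.
#'
#' @param rec an [IEEGRecording-class].
#' @param stem file path without extension.
#' @param badChannels optional labels to record as artifactual.
#' @return `stem`, invisibly.
#' @export
writeRecordingFixture <- function(rec, stem, badChannels = character()) {
  stopifnot(is(rec, "IEEGRecording"))
  df <- as.data.frame(t(rec@data))
  names(df) <- rec@channelLabels
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- list(fs = rec@fs, onset_sample = rec@onsetSample,
               soz_channels = rec@channelLabels[rec@sozMask],
               bad_channels = badChannels,
               meta = rec@meta[vapply(rec@meta, function(x)
                 is.atomic(x) && length(x) == 1, TRUE)])
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

.readSidecar <- function(path) {
  if (!file.exists(path)) stop(sprintf("sidecar not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.recordingFromParts <- function(data, labels, side, origin) {
  if (is.null(side$fs)) stop("missing sampling rate in sidecar: fs")
  if (is.null(side$onset_sample))
    stop("missing onset annotation: onset_sample")
  bad <- as.character(side$bad_channels %||% character())
  keep <- !(labels %in% bad)
  data <- data[keep, , drop = FALSE]
  labels <- labels[keep]
  soz <- labels %in% as.character(side$soz_channels %||% character())
  meta <- as.list(side$meta %||% list())
  meta$source <- origin
  IEEGRecording(data, fs = side$fs, channelLabels = labels,
                onsetSample = side$onset_sample, sozMask = soz, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a recording from disk
#'
#' Supported layouts:
#' \describe{
#'   \item{fixture}{`<stem>.tsv` + `<stem>.json`, see
#'     [writeRecordingFixture()].}
#'   \item{edf}{an EDF file plus a `<stem>.json` sidecar carrying
#'     `onset_sample` (or `onset_s`), `soz_channels` and `bad_channels` --
#'     EDF itself stores neither onset nor SOZ annotations.}
#'   \item{bids}{a BIDS-iEEG-style directory: one `*_ieeg.tsv` or
#'     `*_ieeg.edf` data file, `*_ieeg.json` (`SamplingFrequency`),
#'     `*_channels.tsv` (`name`, `status`, optional `soz`), `*_events.tsv`
#'     (`onset` in seconds, `trial_type` containing `"onset"`).}
#' }
#' Channels flagged bad/artifactual are dropped before return.
#'
#' @param path fixture stem, EDF file, or BIDS-style directory.
#' @param format `"auto"` (default; inferred from the path) or one of
#'   `"fixture"`, `"edf"`, `"bids"`.
#' @return An [IEEGRecording-class].
#' @export
loadRecording <- function(path, format = c("auto", "fixture", "edf", "bids")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "bids"
              else if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "fixture"
  }
  switch(format,
    fixture = {
      stem <- sub("\\.(tsv|json)$", "", path)
      tsv <- paste0(stem, ".tsv")
      if (!file.exists(tsv)) stop(sprintf("fixture not found: %s", tsv))
      df <- utils::read.table(tsv, header = TRUE, sep = "\t",
                              check.names = FALSE)
      side <- .readSidecar(paste0(stem, ".json"))
      .recordingFromParts(t(as.matrix(df)), names(df), side, tsv)
    },
    edf = {
      edf <- readEDF(path)
      stem <- sub("\\.edf$", "", path, ignore.case = TRUE)
      side <- .readSidecar(paste0(stem, ".json"))
      if (is.null(side$onset_sample) && !is.null(side$onset_s))
        side$onset_sample <- round(side$onset_s * edf$fs)
      side$fs <- side$fs %||% edf$fs
      .recordingFromParts(edf$data, edf$labels, side, path)
    },
    bids = .loadBIDS(path)
  )
}

.bidsFile <- function(dir, suffix) {
  hits <- list.files(dir, pattern = paste0(suffix, "$"), full.names = TRUE)
  if (length(hits) != 1L)
    stop(sprintf("expected exactly one *%s in %s, found %d",
                 suffix, dir, length(hits)))
  hits
}

.loadBIDS <- function(dir) {
  meta <- jsonlite::read_json(.bidsFile(dir, "_ieeg\\.json"),
                              simplifyVector = TRUE)
  fs <- meta$SamplingFrequency
  if (is.null(fs)) stop("missing SamplingFrequency in *_ieeg.json")
  chan <- utils::read.table(.bidsFile(dir, "_channels\\.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  ev <- utils::read.table(.bidsFile(dir, "_events\\.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  onsetRow <- if ("trial_type" %in% names(ev))
    which(grepl("onset", ev$trial_type, ignore.case = TRUE))[1] else 1L
  if (is.na(onsetRow) || !"onset" %in% names(ev))
    stop("missing onset annotation: events.tsv needs an 'onset' column with a seizure-onset row")
  dataTsv <- list.files(dir, pattern = "_ieeg\\.tsv$", full.names = TRUE)
  if (length(dataTsv) == 1L) {
    df <- utils::read.table(dataTsv, header = TRUE, sep = "\t",
                            check.names = FALSE)
    data <- t(as.matrix(df))
    labels <- names(df)
  } else {
    edf <- readEDF(.bidsFile(dir, "_ieeg\\.edf"))
    data <- edf$data
    labels <- edf$labels
  }
  bad <- if ("status" %in% names(chan))
    chan$name[tolower(chan$status) %in% c("bad", "artifact", "artifactual")]
    else character()
  soz <- if ("soz" %in% names(chan))
    chan$name[tolower(as.character(chan$soz)) %in% c("true", "1", "yes")]
    else character()
  side <- list(fs = fs, onset_sample = round(ev$onset[onsetRow] * fs),
               soz_channels = soz, bad_channels = bad, meta = list())
  .recordingFromParts(data, labels, side, dir)
}

#' Read a (minimal) EDF file
#'
#' Parses the classic 256-byte EDF header, the per-signal headers, and the
#' 16-bit little-endian sample records, applying the physical/digital
#' calibration. All signals must share one sampling rate (true of the iEEG
#' layouts this package targets); annotations channels are not supported.
#'
#' @param path EDF file path.
#' @return list with `data` (channels x samples), `labels`, `fs`.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  version <- rd(8)
  if (version != "0") stop(sprintf("not an EDF file (version '%s')", version))
  rd(80); rd(80); rd(8); rd(8)
  rd(8) # header length, recomputed below
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  field <- function(nc) vapply(seq_len(ns), function(i) rd(nc), "")
  labels <- field(16)
  field(80); field(8)
  physMin <- as.numeric(field(8))
  physMax <- as.numeric(field(8))
  digMin <- as.numeric(field(8))
  digMax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8)) # samples per record, per signal
  field(32)
  if (length(unique(spr / recDur)) != 1L)
    stop("signals with differing sampling rates are not supported")
  out <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
      out[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - digMin[i]) * gain + physMin[i]
    }
  }
  list(data = out, labels = labels, fs = spr[1] / recDur)
}

#' Write a matrix of signals as a (minimal) EDF file
#'
#' Single-record classic EDF with 16-bit quantization over each channel's
#' range. Intended for round-trip testing of [readEDF()] and for exporting
#' synthetic recordings; clinical metadata fields are left generic.
#'
#' @param data channels x samples matrix.
#' @param path output path.
#' @param fs sampling rate in Hz.
#' @param labels channel labels (truncated to EDF's 16 characters).
#' @return `path`, invisibly.
#' @export
writeEDF <- function(data, path, fs, labels = NULL) {
  data <- as.matrix(data)
  ns <- nrow(data)
  T <- ncol(data)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(ns))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, nc) {
    s <- substr(as.character(x), 1, nc)
    writeBin(charToRaw(formatC(s, width = -nc)), con)
  }
  recDur <- T / fs
  pad("0", 8); pad("X X X X", 80); pad("Startdate X X X X", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44); pad(1, 8)
  pad(format(recDur, digits = 8), 8); pad(ns, 4)
  physMin <- apply(data, 1, min)
  physMax <- apply(data, 1, max)
  flat <- physMax == physMin
  physMax[flat] <- physMin[flat] + 1
  for (l in labels) pad(l, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (v in physMin) pad(format(v, digits = 7), 8)
  for (v in physMax) pad(format(v, digits = 7), 8)
  for (i in seq_len(ns)) pad(-32768, 8)
  for (i in seq_len(ns)) pad(32767, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(T, 8)
  for (i in seq_len(ns)) pad("", 32)
  for (i in seq_len(ns)) {
    gain <- (physMax[i] - physMin[i]) / 65535
    dig <- round((data[i, ] - physMin[i]) / gain) - 32768
    writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
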