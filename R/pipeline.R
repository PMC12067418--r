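#' Pipeline configuration
#'
#' Single source of truth for every constant the analysis consumes: the
#' 3-45 Hz band, 60 Hz notch, 500 Hz target rate, 28-s epochs in 4-s
#' windows, SBC order selection, 100 surrogates at alpha = 0.05, both
#' estimators and both flow measures. All values are validated here, before
#' any computation.
#'
#' @param band connectivity aggregation band (Hz).
#' @param filterLow,filterHigh band-pass corners (Hz).
#' @param notch notch frequency (Hz); NA disables.
#' @param targetFs resampling target (Hz).
#' @param minFs exclusion threshold on the original sampling rate (Hz).
#' @param minPreictalS minimum preictal seconds required; defaults to
#'   `epochS` (the amount actually analysed). The clinical screening
#'   convention of 30 s can be requested explicitly.
#' @param epochS,windowS epoch and window lengths (s).
#' @param orderCriterion `"sbc"` (default) or `"aic"`.
#' @param pMin,pMax MVAR order search range.
#' @param nSurrogates surrogate replicates per window (default 100).
#' @param alpha edge-pruning and classification significance level.
#' @param methods connectivity estimators to run.
#' @param measures flow measures to score.
#' @param periods epochs to analyse (`"preictal"`, optionally `"ictal"`).
#' @param thresholding apply surrogate edge pruning (default TRUE).
#' @param freqStep spectral grid step (Hz).
#' @param masterSeed master seed for all stochastic stages.
#' @return A validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(band = c(3, 45), filterLow = 3, filterHigh = 45,
                           notch = 60, targetFs = 500, minFs = 500,
                           minPreictalS = epochS, epochS = 28, windowS = 4,
                           orderCriterion = c("sbc", "aic"), pMin = 1,
                           pMax = 20, nSurrogates = 100, alpha = 0.05,
                           methods = c("pdc", "dtf"),
                           measures = c("inflow", "outflow"),
                           periods = "preictal", thresholding = TRUE,
                           freqStep = 0.5, masterSeed = 1L) {
  orderCriterion <- match.arg(orderCriterion)
  methods <- match.arg(methods, c("pdc", "dtf"), several.ok = TRUE)
  measures <- match.arg(measures, c("inflow", "outflow"), several.ok = TRUE)
  periods <- match.arg(periods, c("preictal", "ictal"), several.ok = TRUE)
  if (abs(epochS / windowS - round(epochS / windowS)) > 1e-9)
    stop(sprintf("epochS (%g s) must be an exact multiple of windowS (%g s)",
                 epochS, windowS))
  if (filterHigh >= targetFs / 2 || band[2] >= targetFs / 2)
    stop("band must lie strictly below the target Nyquist frequency")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nSurrogates * alpha < 1)
    stop("nSurrogates too small to resolve alpha")
  cfg <- list(band = band, filterLow = filterLow, filterHigh = filterHigh,
              notch = notch, targetFs = targetFs, minFs = minFs,
              minPreictalS = minPreictalS, epochS = epochS,
              windowS = windowS, orderCriterion = orderCriterion,
              pMin = pMin, pMax = pMax, nSurrogates = nSurrogates,
              alpha = alpha, methods = methods, measures = measures,
              periods = periods, thresholding = isTRUE(thresholding),
              freqStep = freqStep, masterSeed = as.integer(masterSeed))
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Analyse one seizure recording end-to-end
#'
#' Runs the full per-seizure chain: inclusion screening, zero-phase
#' band-pass + notch, downsampling, z-scoring, windowing, per-window MVAR
#' order selection and fit, PDC/DTF band aggregation, surrogate edge
#' pruning, per-channel flow dynamics, per-(method, measure, period) AUCs,
#' and the inflow-/outflow-dominant classification of the preictal pattern.
#'
#' @param rec an [IEEGRecording-class].
#' @param config a [pipelineConfig()].
#' @param seed surrogate master seed for this recording (default derived
#'   from the config seed).
#' @return An [EvaluationResult-class]; its `meta` carries the selected MVAR
#'   orders per window, the flow series, and the recording metadata.
#' @export
analyzeRecording <- function(rec, config = pipelineConfig(), seed = NULL) {
  stopifnot(is(rec, "IEEGRecording"), inherits(config, "PipelineConfig"))
  if (is.null(seed)) seed <- config$masterSeed
  val <- validateRecording(rec, minFs = config$minFs,
                           minPreictalS = config$minPreictalS)
  if (!val$accepted) stop(sprintf("recording rejected: %s", val$reason))
  rec <- bandpassNotch(rec, config$filterLow, config$filterHigh, config$notch)
  rec <- resampleTo(rec, config$targetFs)
  rec <- zscoreChannels(rec)
  freqs <- seq(config$band[1], config$band[2], by = config$freqStep)
  flows <- list()
  orders <- list()
  aucRows <- list()
  unstable <- 0L
  for (period in config$periods) {
    segs <- segmentEpoch(rec, period, config$epochS, config$windowS)
    conns <- lapply(config$methods, function(m) vector("list",
                                                       length(segs@segments)))
    names(conns) <- config$methods
    for (s in seq_along(segs@segments)) {
      seg <- segs@segments[[s]]
      p <- selectOrder(seg, config$pMin, config$pMax,
                       criterion = config$orderCriterion, fs = rec@fs)
      fit <- fitMVAR(seg, p, fs = rec@fs)
      if (!isStable(fit)) {
        unstable <- unstable + 1L
        warning(sprintf("unstable MVAR fit (%s window %d); connectivity kept",
                        period, s), call. = FALSE)
      }
      orders[[period]] <- c(orders[[period]], p)
      nulls <- if (config$thresholding)
        .buildNullBoth(seg, p, band = config$band,
                       nSurrogates = config$nSurrogates,
                       seed = .deriveSeed(seed, match(period,
                                                      c("preictal", "ictal")) *
                                            1000L + s),
                       freqs = freqs, fs = rec@fs, methods = config$methods,
                       alpha = config$alpha)
      for (m in config$methods) {
        spec <- if (m == "pdc") pdc(fit, freqs) else dtf(fit, freqs)
        cm <- bandAggregate(spec, config$band, segmentIndex = s,
                            period = period)
        if (config$thresholding)
          cm <- thresholdConnectivity(cm, nulls[[m]], alpha = config$alpha)
        conns[[m]][[s]] <- cm
      }
    }
    for (m in config$methods) for (me in config$measures) {
      fl <- assembleFlowSeries(conns[[m]], me, rec@sozMask,
                               rec@channelLabels)
      flows[[paste(m, me, period, sep = "_")]] <- fl
      aucRows[[length(aucRows) + 1L]] <- data.frame(
        patient = as.character(rec@meta$patient %||% NA_character_),
        seizure = as.character(rec@meta$seizure %||% rec@meta$id %||% NA),
        method = m, measure = me, period = period,
        auc = if (any(rec@sozMask) && !all(rec@sozMask)) seizureAuc(fl)
              else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  aucTab <- do.call(rbind, aucRows)
  label <- "unclassified"
  tests <- data.frame()
  canClassify <- all(c("pdc", "dtf") %in% config$methods) &&
    all(c("inflow", "outflow") %in% config$measures) &&
    "preictal" %in% config$periods &&
    any(rec@sozMask) && !all(rec@sozMask)
  if (canClassify) {
    pre <- flows[paste(rep(c("pdc", "dtf"), each = 2),
                       c("inflow", "outflow"), "preictal", sep = "_")]
    cls <- classifyRecording(pre, alpha = config$alpha)
    label <- cls$label
    tests <- cls$tests
  }
  meta <- rec@meta
  meta$orders <- orders
  meta$flows <- flows
  meta$unstableFits <- unstable
  new("EvaluationResult", aucTable = aucTab, groupLabel = label,
      tests = tests, meta = meta)
}

#' Run the full pipeline over a cohort
#'
#' Applies [analyzeRecording()] to every recording (each with its own
#' derived surrogate seed, so reruns are reproducible and order-invariant),
#' skips recordings failing the inclusion rules with a message, summarizes
#' the cohort, and optionally writes the result artifacts (AUC table, group
#' labels, long-format flow CSV, cohort summary, run manifest) to a
#' directory.
#'
#' @param cohort list of [IEEGRecording-class] objects or of
#'   `list(recording, truth)` pairs as produced by [generateCohort()].
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory for artifacts.
#' @param stratifyBy optional metadata key for the stratified summary.
#' @return list with `results` (per-seizure [EvaluationResult-class]),
#'   `summary` (from [summarizeCohort()]), and `rejected` (data.frame of
#'   skipped recordings and reasons).
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outDir = NULL,
                        stratifyBy = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  results <- list()
  rejected <- list()
  t0 <- Sys.time()
  for (i in seq_along(cohort)) {
    item <- cohort[[i]]
    rec <- if (is(item, "IEEGRecording")) item else item$recording
    truth <- if (is(item, "IEEGRecording")) NULL else item$truth
    res <- tryCatch(
      analyzeRecording(rec, config, seed = .deriveSeed(config$masterSeed, i)),
      error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("skipping recording %d (%s): %s", i,
                      rec@meta$id %||% "?", conditionMessage(res)))
      rejected[[length(rejected) + 1L]] <- data.frame(
        index = i, id = as.character(rec@meta$id %||% NA),
        reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    if (!is.null(truth)) {
      res@meta$regime <- truth$regime
      res@meta$expectedDominant <- truth$expectedDominant
    }
    results[[length(results) + 1L]] <- res
  }
  summary <- if (length(results)) summarizeCohort(results, stratifyBy)
             else NULL
  rejected <- if (length(rejected)) do.call(rbind, rejected)
              else data.frame(index = integer(), id = character(),
                              reason = character())
  if (!is.null(outDir) && length(results)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary$aucLong, file.path(outDir, "auc_table.csv"),
                     row.names = FALSE)
    utils::write.csv(summary$summary, file.path(outDir, "cohort_summary.csv"),
                     row.names = FALSE)
    flowsLong <- do.call(rbind, lapply(seq_along(results), function(i) {
      fl <- do.call(rbind, lapply(results[[i]]@meta$flows, flowSeriesToLong))
      fl$recording <- results[[i]]@meta$id %||% i
      fl
    }))
    utils::write.csv(flowsLong, file.path(outDir, "flow_series.csv"),
                     row.names = FALSE)
    labels <- lapply(results, function(r)
      list(id = r@meta$id %||% NA, group = r@groupLabel,
           tests = r@tests))
    jsonlite::write_json(labels, file.path(outDir, "group_labels.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest <- list(
      config = unclass(config),
      nRecordings = length(cohort), nAnalysed = length(results),
      nRejected = nrow(rejected),
      packageVersion = as.character(utils::packageVersion("ieegflow")),
      rVersion = R.version.string,
      elapsedS = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = results, summary = summary, rejected = rejected)
}

#' Export a connectivity matrix as CSV with a JSON sidecar
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param stem output path without extension.
#' @param channelLabels optional channel names for header/index.
#' @return `stem`, invisibly.
#' @export
writeConnectivity <- function(conn, stem, channelLabels = NULL) {
  stopifnot(is(conn, "ConnectivityMatrix"))
  W <- conn@weights
  if (!is.null(channelLabels)) dimnames(W) <- list(channelLabels,
                                                   channelLabels)
  utils::write.csv(W, paste0(stem, ".csv"))
  jsonlite::write_json(
    list(method = conn@method, band = conn@band,
         segment_index = conn@segmentIndex, period = conn@period,
         thresholded = conn@thresholded),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
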