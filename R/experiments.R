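#' Regime-recovery experiment on single synthetic recordings
#'
#' Generates `nSeeds` ground-truth recordings per regime, runs the full
#' analysis chain on each, and collects the assigned group labels and the
#' per-(method, measure) AUCs. This is the package's own check of the
#' qualitative core of the analysis: on data where the SOZ genuinely is a
#' net sink (or source), do the flow measures and the classifier say so?
#'
#' @param regimes regimes to simulate.
#' @param nSeeds recordings per regime.
#' @param nChannels channels per recording (default 10; see the methods
#'   vignette for why simulations run on small networks).
#' @param config a [pipelineConfig()].
#' @param baseSeed master seed; results are a pure function of it.
#' @return list with `labels` (regime, seed, label) and `auc` (long AUC
#'   table with a regime column).
#' @export
regimeRecoveryExperiment <- function(regimes = c("inflow_dominant",
                                                 "outflow_dominant", "null"),
                                     nSeeds = 20, nChannels = 10,
                                     config = pipelineConfig(),
                                     baseSeed = 1L) {
  labels <- list()
  aucs <- list()
  for (rg in regimes) for (s in seq_len(nSeeds)) {
    recSeed <- .deriveSeed(baseSeed, 1000L * match(rg, regimes) + s)
    gen <- generateRecording(syntheticSpec(nChannels = nChannels,
                                           regime = rg, seed = recSeed))
    res <- suppressWarnings(
      analyzeRecording(gen$recording, config,
                       seed = .deriveSeed(baseSeed, 5000L + s)))
    tb <- aucTable(res)
    tb$regime <- rg
    tb$seed <- s
    aucs[[length(aucs) + 1L]] <- tb
    labels[[length(labels) + 1L]] <- data.frame(
      regime = rg, seed = s, label = groupLabel(res),
      stringsAsFactors = FALSE)
  }
  list(labels = do.call(rbind, labels), auc = do.call(rbind, aucs))
}

#' Pooled-versus-grouped AUC contrast on a mixed cohort
#'
#' Generates a 50/50 inflow-/outflow-dominant synthetic cohort, analyses
#' every seizure, and contrasts the pooled AUC medians (all seizures thrown
#' together, where the two opposing regimes should cancel to near-chance)
#' with the regime-grouped dominant-measure medians (where each group's own
#' measure should discriminate well).
#'
#' @param nPatients patients in the cohort (half per regime).
#' @param config a [pipelineConfig()].
#' @param baseSeed master seed.
#' @param nChannelsRange,seizuresRange per-patient ranges passed to
#'   [generateCohort()].
#' @return list with `pooledMedians` (per measure), `groupedMedians` (per
#'   regime, dominant measure), and the long AUC table.
#' @export
pooledContrastExperiment <- function(nPatients = 10,
                                     config = pipelineConfig(),
                                     baseSeed = 1L,
                                     nChannelsRange = c(10, 14),
                                     seizuresRange = c(2, 3)) {
  coh <- generateCohort(nPatients,
                        c(inflow_dominant = 0.5, outflow_dominant = 0.5),
                        baseSeed = baseSeed,
                        nChannelsRange = nChannelsRange,
                        seizuresRange = seizuresRange)
  out <- suppressWarnings(runPipeline(coh, config))
  auc <- out$summary$aucLong
  auc$regime <- unlist(lapply(out$results, function(r)
    rep(r@meta$regime, nrow(r@aucTable))))
  pooled <- vapply(c("inflow", "outflow"), function(me)
    stats::median(auc$auc[auc$measure == me]), 0)
  grouped <- vapply(c("inflow_dominant", "outflow_dominant"), function(rg) {
    dm <- sub("_dominant", "", rg)
    stats::median(auc$auc[auc$regime == rg & auc$measure == dm])
  }, 0)
  list(pooledMedians = pooled, groupedMedians = grouped, auc = auc,
       results = out$results)
}

#' Surrogate-threshold calibration on independent channels
#'
#' On channels that are genuinely independent white noise every surviving
#' edge is a false positive, so the off-diagonal survival fraction after
#' thresholding at level alpha should sit near alpha. Runs `nSegments`
#' independent 4-s segments and pools all off-diagonal edges.
#'
#' @param nSegments independent segments to test.
#' @param nChannels channels per segment (default 4).
#' @param fs sampling rate (default 500).
#' @param windowS segment length in seconds (default 4).
#' @param nSurrogates surrogate replicates (default 100).
#' @param alpha edge-pruning level (default 0.05).
#' @param method connectivity estimator.
#' @param seed master seed.
#' @return list with `survivalRate`, `nEdges`, and the per-segment counts.
#' @export
surrogateCalibrationExperiment <- function(nSegments = 17, nChannels = 4,
                                           fs = 500, windowS = 4,
                                           nSurrogates = 100, alpha = 0.05,
                                           method = "pdc", seed = 1L) {
  nWin <- round(windowS * fs)
  survived <- 0L
  total <- 0L
  perSeg <- integer(nSegments)
  for (s in seq_len(nSegments)) {
    set.seed(.deriveSeed(seed, 7000L + s))
    x <- matrix(stats::rnorm(nChannels * nWin), nChannels)
    p <- selectOrder(x, 1, 8, fs = fs)
    fit <- fitMVAR(x, p, fs = fs)
    spec <- if (method == "pdc") pdc(fit) else dtf(fit)
    cm <- bandAggregate(spec, c(3, 45), segmentIndex = s,
                        period = "preictal")
    null <- buildNull(x, p, method, nSurrogates = nSurrogates,
                      seed = .deriveSeed(seed, 8000L + s), fs = fs,
                      alpha = alpha)
    thr <- thresholdConnectivity(cm, null, alpha = alpha)
    off <- row(thr@weights) != col(thr@weights)
    perSeg[s] <- sum(thr@weights[off] > 0)
    survived <- survived + perSeg[s]
    total <- total + sum(off)
  }
  list(survivalRate = survived / total, nEdges = total, perSegment = perSeg)
}
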