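test_that("generated networks honour the regime's coupling structure", {
  specOut <- syntheticSpec(nChannels = 8, nSoz = 2,
                           regime = "outflow_dominant", seed = 51)
  m <- makeNetwork(specOut, 7)
  soz <- generateRecording(specOut)$truth$sozIdx
  A1 <- mvarCoefficients(m)[, , 1]
  diag(A1) <- 0
  colMass <- colSums(abs(A1))
  expect_true(all(colMass[soz] > 0))
  expect_true(all(colMass[setdiff(1:8, soz)] == 0))
  expect_equal(sum(abs(A1[soz, ])), 0) # SOZ sources receive nothing

  specZero <- syntheticSpec(nChannels = 6, regime = "inflow_dominant",
                            coupling = 0, seed = 52)
  A0 <- mvarCoefficients(makeNetwork(specZero, 3))
  offd <- A0; for (k in 1:2) diag(offd[, , k]) <- 0
  expect_equal(sum(abs(offd)), 0)
})

test_that("every generated model is stable, across regimes and windows", {
  for (rg in c("inflow_dominant", "outflow_dominant", "null")) {
    spec <- syntheticSpec(nChannels = 9, regime = rg, seed = 53)
    for (s in c(1, 4, 7))
      expect_true(isStable(makeNetwork(spec, s)))
    expect_true(isStable(makeNetwork(spec, period = "ictal")))
  }
})

test_that("the null regime has uniform in- and out-degree", {
  spec <- syntheticSpec(nChannels = 10, regime = "null", seed = 54)
  A1 <- mvarCoefficients(makeNetwork(spec, 1))[, , 1]
  diag(A1) <- 0
  expect_true(all(rowSums(A1 != 0) == spec$nCouplingsPerSoz))
  expect_true(all(colSums(A1 != 0) == spec$nCouplingsPerSoz))
})

test_that("coupled channels keep amplitudes comparable to the network", {
  for (rg in c("inflow_dominant", "outflow_dominant")) {
    gen <- generateRecording(syntheticSpec(nChannels = 10, regime = rg,
                                           seed = 55, noiseSd = 0))
    sds <- apply(recordingData(gen$recording), 1, sd)
    expect_lt(max(sds) / min(sds), 3)
  }
})

test_that("recordings have the advertised geometry and are reproducible", {
  spec <- syntheticSpec(nChannels = 7, regime = "inflow_dominant", seed = 56)
  gen <- generateRecording(spec)
  rec <- gen$recording
  expect_equal(onsetSample(rec), 14000) # 28 s preictal at 500 Hz
  expect_equal(ncol(recordingData(rec)), 28000)
  segs <- segmentEpoch(rec, "preictal")
  expect_length(segs@segments, 7)
  expect_equal(sum(sozMask(rec)), spec$nSoz)
  expect_equal(gen$truth$expectedDominant, "inflow")

  again <- generateRecording(spec)
  expect_identical(recordingData(again$recording), recordingData(rec))
})

test_that("cohorts are reproducible, mixed as requested, within ranges", {
  coh <- generateCohort(4, c(inflow_dominant = 0.5, outflow_dominant = 0.5),
                        baseSeed = 57, nChannelsRange = c(6, 9),
                        seizuresRange = c(2, 3))
  regimes <- vapply(coh, function(g) g$truth$regime, "")
  pats <- vapply(coh, function(g) g$recording@meta$patient, "")
  byPat <- tapply(regimes, pats, unique)
  expect_length(byPat, 4)
  expect_equal(as.integer(sort(table(unlist(byPat)))), c(2L, 2L))
  nch <- vapply(coh, function(g) nChannels(g$recording), 0L)
  expect_true(all(nch >= 6 & nch <= 9))
  szs <- table(pats)
  expect_true(all(szs >= 2 & szs <= 3))
  # patient-level SOZ: same mask across a patient's seizures
  for (p in unique(pats)) {
    masks <- lapply(coh[pats == p], function(g) sozMask(g$recording))
    for (m in masks[-1]) expect_identical(m, masks[[1]])
  }

  coh2 <- generateCohort(4, c(inflow_dominant = 0.5, outflow_dominant = 0.5),
                         baseSeed = 57, nChannelsRange = c(6, 9),
                         seizuresRange = c(2, 3))
  expect_identical(recordingData(coh2[[1]]$recording),
                   recordingData(coh[[1]]$recording))

  expect_error(generateCohort(4, c(inflow_dominant = 0.5,
                                   outflow_dominant = 0.4), baseSeed = 1),
               "sum to 1")
})

test_that("synthetic signals concentrate their power in the analysis band", {
  gen <- generateRecording(syntheticSpec(nChannels = 6,
                                         regime = "outflow_dominant",
                                         seed = 58, noiseSd = 0))
  x <- recordingData(gen$recording)[1, 1:14000]
  px <- spec.pgram(ts(x, frequency = 500), plot = FALSE, taper = 0)
  inband <- sum(px$spec[px$freq >= 3 & px$freq <= 45]) / sum(px$spec)
  expect_gt(inband, 0.6)
})
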