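mkConn <- function(W, method = "pdc", seg = 1L, period = "preictal") {
  new("ConnectivityMatrix", method = method, band = c(3, 45),
      weights = W, thresholded = FALSE, segmentIndex = as.integer(seg),
      period = period)
}

test_that("inflow and outflow are off-diagonal row and column sums", {
  W <- matrix(c(0, 0.2, 0,
                0.5, 0, 0.1,
                0, 0.3, 0), 3, 3, byrow = TRUE)
  cm <- mkConn(W)
  expect_equal(inflow(cm), c(0.2, 0.6, 0.3))
  expect_equal(outflow(cm), c(0.5, 0.5, 0.1))

  single <- matrix(0, 2, 2); single[1, 2] <- 0.7
  expect_equal(inflow(single), c(0.7, 0))
  expect_equal(outflow(single), c(0, 0.7))
  expect_equal(inflow(matrix(0, 3, 3)), rep(0, 3))

  sym <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3, 3)
  expect_equal(inflow(sym), outflow(sym))
})

test_that("total inflow equals total outflow for any weight matrix", {
  for (s in 1:10) {
    set.seed(s)
    W <- matrix(runif(36), 6, 6); diag(W) <- 0
    expect_equal(sum(inflow(W)), sum(outflow(W)))
  }
})

test_that("min-max normalization has its documented degenerate behaviour", {
  expect_equal(normalizeScores(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalizeScores(c(5, 5)), c(0, 0))
  x <- runif(10)
  expect_equal(normalizeScores(3 * x - 7), normalizeScores(x)) # affine invariant
  nz <- normalizeScores(rnorm(50))
  expect_equal(range(nz), c(0, 1)) # attains both ends when not constant
})

test_that("flow series assembly stacks normalized per-window strengths", {
  W <- matrix(runif(16), 4, 4); diag(W) <- 0
  conns <- lapply(1:7, function(s) mkConn(W, seg = s))
  fl <- assembleFlowSeries(conns, "inflow", sozMask = c(TRUE, rep(FALSE, 3)))
  expect_s4_class(fl, "FlowSeries")
  expect_equal(dim(flowValues(fl)), c(7, 4))
  for (s in 2:7) expect_equal(flowValues(fl)[s, ], flowValues(fl)[1, ])
  expect_equal(flowValues(fl)[1, ], normalizeScores(inflow(W)))

  # permutation equivariance
  perm <- c(2, 4, 1, 3)
  connsP <- lapply(1:7, function(s) mkConn(W[perm, perm], seg = s))
  flP <- assembleFlowSeries(connsP, "inflow",
                            sozMask = (c(TRUE, rep(FALSE, 3)))[perm])
  expect_equal(flowValues(flP), flowValues(fl)[, perm], ignore_attr = TRUE)

  bad <- c(conns[1:6], list(mkConn(matrix(0, 3, 3))))
  expect_error(assembleFlowSeries(bad, "inflow", c(TRUE, FALSE, FALSE, FALSE)),
               "inconsistent")
})

test_that("a planted sink carries the maximum inflow in nearly all windows", {
  top <- 0L; total <- 0L
  for (s in 1:10) {
    spec <- syntheticSpec(nChannels = 8, nSoz = 1, regime = "inflow_dominant",
                          seed = 800 + s, noiseSd = 0)
    truth <- generateRecording(spec)$truth
    sink <- truth$sozIdx
    for (seg in c(1, 4, 7)) {
      m <- truth$models[[seg]]
      x <- simulateMVAR(m, 2000, seed = 900 + 10 * s + seg)
      W <- bandAggregate(pdc(fitMVAR(x, 2)))@weights
      v <- normalizeScores(inflow(W))
      total <- total + 1L
      if (which.max(v) == sink) top <- top + 1L
    }
  }
  expect_gte(top / total, 0.95)
})

test_that("long-format export is tidy and faithful", {
  W <- matrix(runif(9), 3, 3); diag(W) <- 0
  fl <- assembleFlowSeries(lapply(1:2, function(s) mkConn(W, seg = s)),
                           "outflow", sozMask = c(TRUE, FALSE, FALSE),
                           channelLabels = c("a", "b", "c"))
  long <- flowSeriesToLong(fl)
  expect_equal(nrow(long), 6)
  expect_equal(unique(long$measure), "outflow")
  expect_equal(long$normalized_value[long$channel == "b" & long$segment == 1],
               normalizeScores(outflow(W))[2])
  expect_equal(sum(long$is_soz), 2)
})
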