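# Reference bivariate model used throughout: A1 = [[0.5, 0], [0.4, 0.5]],
# i.e. channel 1 drives channel 2 with weight 0.4. At f = 0:
#   Abar = [[0.5, 0], [-0.4, 0.5]],  H = Abar^-1 = [[2, 0], [1.6, 2]]
#   PDC(2<-1) = 0.4 / sqrt(0.5^2 + 0.4^2) = DTF(2<-1) = 1.6 / sqrt(1.6^2 + 2^2)
biv <- MVARModel(array(matrix(c(0.5, 0.4, 0, 0.5), 2, 2), c(2, 2, 1)))

test_that("Fourier coefficient matrix matches closed-form values", {
  z <- MVARModel(array(0, c(2, 2, 1)))
  Az <- fourierCoefficientMatrix(z, c(0, 10, 45))
  for (f in 1:3) expect_equal(Az[f, , ], diag(2) + 0i)

  u <- MVARModel(array(c(0.5, 0, 0, 0), c(2, 2, 1)))
  expect_equal(fourierCoefficientMatrix(u, 0)[1, 1, 1], 0.5 + 0i)

  A0 <- fourierCoefficientMatrix(biv, 0)[1, , ]
  expect_equal(A0, matrix(c(0.5, -0.4, 0, 0.5), 2, 2) + 0i,
               tolerance = 1e-12)
})

test_that("transfer function inverts the coefficient matrix everywhere", {
  H0 <- transferFunction(biv, 0)[1, , ]
  expect_equal(H0, matrix(c(2, 1.6, 0, 2), 2, 2) + 0i, tolerance = 1e-12)

  freqs <- defaultFreqGrid()
  H <- transferFunction(biv, freqs)
  Ab <- fourierCoefficientMatrix(biv, freqs)
  for (f in seq_along(freqs))
    expect_equal(H[f, , ] %*% Ab[f, , ], diag(2) + 0i, tolerance = 1e-10)
})

test_that("PDC and DTF reproduce the hand-derived value 0.6247 at f = 0", {
  expect_equal(pdc(biv, 0)@values[1, 2, 1], 0.4 / sqrt(0.5^2 + 0.4^2),
               tolerance = 1e-12)
  expect_equal(dtf(biv, 0)@values[1, 2, 1], 1.6 / sqrt(1.6^2 + 2^2),
               tolerance = 1e-12)
  expect_equal(pdc(biv, 0)@values[1, 2, 1], 0.6247, tolerance = 1e-4)
})

test_that("the uncoupled direction is exactly zero and diagonals dominate", {
  freqs <- defaultFreqGrid()
  expect_true(all(pdc(biv, freqs)@values[, 1, 2] == 0))
  expect_true(all(dtf(biv, freqs)@values[, 1, 2] == 0))
  dg <- MVARModel(array(diag(c(0.5, 0.3)), c(2, 2, 1)))
  expect_true(all(dtf(dg, freqs)@values[, 1, 2] == 0) &&
                all(dtf(dg, freqs)@values[, 2, 1] == 0))
})

test_that("normalization identities hold on random stable models", {
  freqs <- defaultFreqGrid()
  for (s in 1:25) {
    n <- sample(2:8, 1)
    p <- sample(1:3, 1)
    m <- randomStableModel(n, p, seed = 400 + s)
    vp <- pdc(m, freqs)@values
    vd <- dtf(m, freqs)@values
    expect_equal(apply(vp^2, c(1, 3), sum),
                 matrix(1, length(freqs), n), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(apply(vd^2, c(1, 2), sum),
                 matrix(1, length(freqs), n), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("band aggregation averages magnitudes and zeroes the diagonal", {
  freqs <- defaultFreqGrid()
  sp <- pdc(biv, freqs)
  cm <- bandAggregate(sp, c(3, 45))
  # independent re-summation
  sel <- freqs >= 3 & freqs <= 45
  expect_equal(cm@weights[2, 1], mean(sp@values[sel, 2, 1]),
               tolerance = 1e-12)
  expect_equal(diag(cm@weights), c(0, 0))

  one <- bandAggregate(pdc(biv, 10), c(3, 45))
  expect_equal(one@weights[2, 1], pdc(biv, 10)@values[1, 2, 1])

  expect_error(bandAggregate(sp, c(100, 120)), "no grid frequencies")
})

test_that("estimated orientation follows the simulated coupling direction", {
  wins <- 0L
  for (s in 1:10) {
    m <- MVARModel(array(matrix(c(0.5, 0.45, 0, 0.5), 2, 2), c(2, 2, 1)))
    x <- simulateMVAR(m, 2000, seed = 500 + s)
    f <- fitMVAR(x, 1)
    Wp <- bandAggregate(pdc(f))@weights
    Wd <- bandAggregate(dtf(f))@weights
    if (Wp[2, 1] > Wp[1, 2] && Wd[2, 1] > Wd[1, 2]) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("channel permutation permutes connectivity rows and columns alike", {
  m <- randomStableModel(4, 2, seed = 42)
  W <- bandAggregate(pdc(m))@weights
  perm <- c(3, 1, 4, 2)
  mP <- MVARModel(m@coeffs[perm, perm, , drop = FALSE], fs = m@fs)
  WP <- bandAggregate(pdc(mP))@weights
  expect_equal(WP, W[perm, perm], tolerance = 1e-12)
})

test_that("the vectorized band-weight engine matches the public path", {
  for (s in 1:5) {
    m <- randomStableModel(sample(2:6, 1), sample(1:3, 1), seed = 600 + s)
    fast <- ieegflow:::.fastBandWeights(m@coeffs, m@fs, defaultFreqGrid(),
                                        c(3, 45))
    expect_equal(fast$pdc, bandAggregate(pdc(m), c(3, 45))@weights,
                 tolerance = 1e-12)
    expect_equal(fast$dtf, bandAggregate(dtf(m), c(3, 45))@weights,
                 tolerance = 1e-12)
  }
})
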