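#' Fit a multivariate autoregressive model by least squares
#'
#' Estimates x_t = sum_{k=1..p} A_k x_{t-k} + e_t by ordinary least squares on
#' the lagged design (no intercept; inputs are expected z-scored). The
#' innovation covariance uses the unbiased denominator T - p - n*p.
#'
#' @param segment numeric matrix, channels x samples.
#' @param order model order p (>= 1).
#' @param fs sampling rate in Hz, stored for later spectral evaluation.
#' @return An [MVARModel-class].
#' @examples
#' m0 <- MVARModel(array(0.5 * diag(2), c(2, 2, 1)))
#' x <- simulateMVAR(m0, 2000, seed = 1)
#' fitMVAR(x, order = 1)
#' @export
fitMVAR <- function(segment, order, fs = 500) {
  fit <- .olsMVAR(as.matrix(segment), as.integer(order))
  new("MVARModel", order = as.integer(order), coeffs = fit$A,
      noiseCov = fit$Sigma, fs = as.numeric(fs),
      nSamplesFit = as.integer(ncol(segment)))
}

# OLS engine shared by fitMVAR and the surrogate hot loop (no S4 overhead).
.olsMVAR <- function(segment, p) {
  n <- nrow(segment)
  T <- ncol(segment)
  if (p < 1L) stop("order must be >= 1")
  if (T <= n * p + p)
    stop(sprintf("segment too short: %d samples for %d coefficients per channel",
                 T, n * p))
  tEff <- T - p
  # design: row t holds (x_{t-1}', ..., x_{t-p}') for t = p+1 .. T
  Z <- matrix(0, tEff, n * p)
  for (k in seq_len(p))
    Z[, ((k - 1L) * n + 1L):(k * n)] <- t(segment[, (p + 1L - k):(T - k),
                                                  drop = FALSE])
  Y <- t(segment[, (p + 1L):T, drop = FALSE])
  G <- crossprod(Z)
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch) || !all(is.finite(ch)))
    stop(sprintf("singular regressor matrix (reciprocal condition ~ %.3e)",
                 rcond(G)))
  B <- backsolve(ch, forwardsolve(t(ch), crossprod(Z, Y)))
  resid <- Y - Z %*% B
  Sigma <- crossprod(resid) / (T - p - n * p)
  Sigma <- (Sigma + t(Sigma)) / 2
  A <- array(0, c(n, n, p))
  for (k in seq_len(p))
    A[, , k] <- t(B[((k - 1L) * n + 1L):(k * n), , drop = FALSE])
  list(A = A, Sigma = Sigma)
}

#' Select the MVAR model order by information criterion
#'
#' Scores every order in `pMin:pMax` and minimizes Schwarz's Bayesian
#' criterion (SBC, the default) or Akaike's information criterion (AIC),
#' both computed from the residual covariance determinant:
#' \deqn{SBC(p) = \log\det\hat\Sigma_p + p n^2 \log(T_{eff}) / T_{eff}}
#' \deqn{AIC(p) = \log\det\hat\Sigma_p + 2 p n^2 / T_{eff}}
#' All candidate orders are evaluated on the same effective sample -- the
#' \eqn{T_{eff} = T - p_{max}} rows that support the largest candidate --
#' so their residual determinants are directly comparable and the lagged
#' design is built only once (the convention of the classical stepwise
#' autoregression fitters). Ties break toward the smaller order.
#'
#' @param segment numeric matrix, channels x samples.
#' @param pMin,pMax order range to scan (defaults 1 and 20).
#' @param criterion `"sbc"` or `"aic"`.
#' @param fs sampling rate in Hz (unused in the score; kept for interface
#'   symmetry with [fitMVAR()]).
#' @return The selected order (integer).
#' @export
selectOrder <- function(segment, pMin = 1, pMax = 20,
                        criterion = c("sbc", "aic"), fs = 500) {
  criterion <- match.arg(criterion)
  segment <- as.matrix(segment)
  if (pMin > pMax) stop("pMin must not exceed pMax")
  n <- nrow(segment)
  T <- ncol(segment)
  pMax <- as.integer(pMax)
  if (T <= n * pMax + pMax)
    stop(sprintf("segment too short for pMax = %d", pMax))
  tEff <- T - pMax
  # shared design: rows t = pMax+1 .. T, lag-k block in columns (k-1)n+1..kn
  Z <- matrix(0, tEff, n * pMax)
  for (k in seq_len(pMax))
    Z[, ((k - 1L) * n + 1L):(k * n)] <- t(segment[, (pMax + 1L - k):(T - k),
                                                  drop = FALSE])
  Y <- t(segment[, (pMax + 1L):T, drop = FALSE])
  G <- crossprod(Z)
  ZY <- crossprod(Z, Y)
  YY <- crossprod(Y)
  orders <- seq.int(pMin, pMax)
  crit <- rep(NA_real_, length(orders))
  for (i in seq_along(orders)) {
    p <- orders[i]
    idx <- seq_len(n * p)
    ch <- tryCatch(chol(G[idx, idx]), error = function(e) NULL)
    if (is.null(ch)) next
    W <- forwardsolve(t(ch), ZY[idx, , drop = FALSE])
    S <- (YY - crossprod(W)) / (tEff - n * p)
    ld <- determinant((S + t(S)) / 2, logarithm = TRUE)
    if (ld$sign <= 0) next
    penalty <- if (criterion == "sbc") p * n^2 * log(tEff) / tEff
               else 2 * p * n^2 / tEff
    crit[i] <- as.numeric(ld$modulus) + penalty
  }
  if (all(!is.finite(crit)))
    stop("criterion non-finite at every candidate order")
  orders[which.min(crit)] # which.min: first minimum, i.e. smallest order
}

# Companion-form matrix of an MVAR coefficient stack (np x np).
.companionMatrix <- function(coeffs) {
  n <- dim(coeffs)[1]
  p <- dim(coeffs)[3]
  C <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) C[1:n, ((k - 1) * n + 1):(k * n)] <- coeffs[, , k]
  if (p > 1)
    C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  C
}

#' Test MVAR stability
#'
#' A model is stable (stationary) iff the spectral radius of its companion
#' matrix is strictly below 1.
#'
#' @param model an [MVARModel-class].
#' @return TRUE or FALSE.
#' @export
isStable <- function(model) {
  stopifnot(is(model, "MVARModel"))
  max(Mod(eigen(.companionMatrix(model@coeffs), only.values = TRUE)$values)) < 1
}

#' Simulate from an MVAR model
#'
#' Iterates the autoregression with Gaussian innovations drawn from the
#' model's noise covariance, discarding `burnIn` initial samples so the
#' returned block is (approximately) a stationary draw. Deterministic given
#' `seed`.
#'
#' @param model a stable [MVARModel-class].
#' @param nSamples number of samples to return.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param burnIn samples to discard before recording (default 1000).
#' @param init optional n x p matrix of initial lag values (most recent last
#'   column); when supplied, `burnIn` may be 0 to continue a trajectory.
#' @return numeric matrix, channels x `nSamples`.
#' @export
simulateMVAR <- function(model, nSamples, seed = NULL, burnIn = 1000,
                         init = NULL) {
  stopifnot(is(model, "MVARModel"))
  if (!isStable(model)) stop("model is unstable; refusing to simulate")
  if (!is.null(seed)) set.seed(seed)
  n <- dim(model@coeffs)[1]
  p <- model@order
  L <- tryCatch(t(chol(model@noiseCov)), error = function(e) {
    eg <- eigen(model@noiseCov, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  })
  total <- nSamples + burnIn
  E <- L %*% matrix(stats::rnorm(n * total), n, total)
  X <- matrix(0, n, total + p)
  if (!is.null(init)) {
    stopifnot(nrow(init) == n, ncol(init) == p)
    X[, seq_len(p)] <- init
  }
  A <- model@coeffs
  for (t in seq_len(total)) {
    xt <- E[, t]
    for (k in seq_len(p)) xt <- xt + A[, , k] %*% X[, p + t - k]
    X[, p + t] <- xt
  }
  X[, (p + burnIn + 1L):(p + total), drop = FALSE]
}
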