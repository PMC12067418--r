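#' Phase-randomized surrogate of a multichannel segment
#'
#' Fourier-transforms each channel, replaces the phases of the positive
#' frequencies by independent uniform draws (independently per channel, which
#' destroys cross-channel temporal correlation), enforces conjugate symmetry,
#' and inverse-transforms. DC and Nyquist bins are left real, so each
#' channel's amplitude spectrum -- hence its periodogram -- is preserved
#' exactly up to round-off.
#'
#' @param segment numeric matrix, channels x samples (>= 4 samples).
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return Surrogate matrix of the same shape.
#' @export
phaseRandomize <- function(segment, seed = NULL) {
  segment <- as.matrix(segment)
  T <- ncol(segment)
  if (T < 4) stop("need at least 4 samples")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(segment)
  half <- if (T %% 2 == 0) T / 2 - 1 else (T - 1) / 2 # strictly positive, non-Nyquist bins
  X <- stats::mvfft(t(segment)) # columns = channels
  idx <- 2:(half + 1)
  # one phase draw per (bin, channel): column-major runif matches a
  # channel-by-channel loop drawing `half` phases each
  phi <- matrix(stats::runif(half * n, 0, 2 * pi), half, n)
  X[idx, ] <- Mod(X[idx, , drop = FALSE]) * exp(1i * phi)
  X[T + 2 - idx, ] <- Conj(X[idx, , drop = FALSE])
  t(Re(stats::mvfft(X, inverse = TRUE))) / T
}

# Shared engine: one pass of surrogate fitting that yields the null for both
# estimators from the same surrogate fits (the phase-randomized data and the
# MVAR fit do not depend on the estimator).
.buildNullBoth <- function(segment, modelOrder, band = c(3, 45),
                           nSurrogates = 100, seed = 1L,
                           freqs = defaultFreqGrid(), fs = 500,
                           methods = c("pdc", "dtf"), alpha = 0.05) {
  segment <- as.matrix(segment)
  n <- nrow(segment)
  nulls <- lapply(methods, function(m) array(0, c(nSurrogates, n, n)))
  names(nulls) <- methods
  for (s in seq_len(nSurrogates)) {
    surr <- phaseRandomize(segment, seed = .deriveSeed(seed, s))
    fit <- tryCatch(.olsMVAR(surr, as.integer(modelOrder)), error = function(e)
      stop(sprintf("surrogate %d: %s", s, conditionMessage(e)), call. = FALSE))
    W <- .fastBandWeights(fit$A, fs, freqs, band, methods)
    for (m in methods) nulls[[m]][s, , ] <- W[[m]]
  }
  out <- vector("list", length(methods))
  names(out) <- methods
  for (m in methods)
    out[[m]] <- new("SurrogateNull", method = m, nullWeights = nulls[[m]],
                    alpha = alpha)
  out
}

#' Build the surrogate null distribution for one segment
#'
#' Repeats `nSurrogates` times: phase-randomize the segment, refit the MVAR at
#' the segment's selected order (holding model complexity constant under the
#' null), compute the requested estimator, and band-aggregate. The stacked
#' weights form the per-edge empirical null of no true interaction.
#'
#' @param segment numeric matrix, channels x samples.
#' @param modelOrder MVAR order used for every surrogate fit.
#' @param method `"pdc"` or `"dtf"`.
#' @param band aggregation band in Hz.
#' @param nSurrogates number of surrogate replicates (default 100).
#' @param seed master seed; each replicate uses a derived stream, so the whole
#'   null is reproducible from this one integer.
#' @param freqs frequency grid.
#' @param fs sampling rate in Hz.
#' @param alpha significance level recorded in the result (default 0.05).
#' @return A [SurrogateNull-class].
#' @export
buildNull <- function(segment, modelOrder, method = c("pdc", "dtf"),
                      band = c(3, 45), nSurrogates = 100, seed = 1L,
                      freqs = defaultFreqGrid(), fs = 500, alpha = 0.05) {
  method <- match.arg(method)
  segment <- as.matrix(segment)
  n <- nrow(segment)
  nullW <- array(0, c(nSurrogates, n, n))
  for (s in seq_len(nSurrogates)) {
    surr <- phaseRandomize(segment, seed = .deriveSeed(seed, s))
    fit <- tryCatch(fitMVAR(surr, modelOrder, fs = fs), error = function(e)
      stop(sprintf("surrogate %d: %s", s, conditionMessage(e)), call. = FALSE))
    spec <- if (method == "pdc") pdc(fit, freqs) else dtf(fit, freqs)
    nullW[s, , ] <- bandAggregate(spec, band)@weights
  }
  new("SurrogateNull", method = method, nullWeights = nullW, alpha = alpha)
}

#' Prune non-significant edges against a surrogate null
#'
#' An edge survives iff its weight strictly exceeds the empirical
#' (1 - alpha) quantile of its surrogate null (order statistic at
#' `ceiling((1 - alpha) * n_surrogates)`; ties are removed -- strict
#' inequality is the conservative choice). Removed edges are set to 0.
#'
#' @param conn an unthresholded [ConnectivityMatrix-class].
#' @param null a [SurrogateNull-class] of matching method and shape.
#' @param alpha significance level (default 0.05).
#' @return The thresholded [ConnectivityMatrix-class].
#' @export
thresholdConnectivity <- function(conn, null, alpha = 0.05) {
  stopifnot(is(conn, "ConnectivityMatrix"), is(null, "SurrogateNull"))
  if (conn@method != null@method)
    stop(sprintf("method mismatch: connectivity is %s, null is %s",
                 conn@method, null@method))
  n <- nrow(conn@weights)
  if (any(dim(null@nullWeights)[2:3] != n))
    stop("shape mismatch between connectivity and null")
  S <- dim(null@nullWeights)[1]
  k <- ceiling((1 - alpha) * S)
  thresh <- apply(null@nullWeights, c(2, 3), function(v) sort(v)[k])
  W <- ifelse(conn@weights > thresh, conn@weights, 0)
  diag(W) <- 0
  initialize(conn, weights = W, thresholded = TRUE)
}
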