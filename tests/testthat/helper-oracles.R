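# Independent oracles and small fixture builders used across the suite.

# Brute-force AUC: count concordant positive/negative score pairs with
# half-credit for ties. Deliberately naive O(n^2); the reference for rocAuc.
bruteAuc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Full-enumeration two-sided rank-sum p-value (independent of the package's
# own exact branch: works on raw values, enumerates group assignments).
enumRanksumP <- function(x, y) {
  N <- length(x) + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  sums <- combn(N, length(x), FUN = function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums >= W - 1e-9), mean(sums <= W + 1e-9)))
}

# Small stable random MVAR model (n channels, order p); rejection-samples
# coefficient scales until the companion spectral radius is below 0.9.
randomStableModel <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    A <- array(rnorm(n * n * p, sd = 0.25 / p), c(n, n, p))
    for (k in seq_len(p)) diag(A[, , k]) <- diag(A[, , k]) + 0.4 / p
    m <- MVARModel(A, fs = 500)
    if (isStable(m)) return(m)
  }
}

# Quick synthetic recording fixture for IO tests.
toyRecording <- function(n = 4, T = 20000, fs = 500, onset = floor(0.75 * T),
                         seed = 1) {
  set.seed(seed)
  IEEGRecording(matrix(rnorm(n * T), n), fs = fs, onsetSample = onset,
                sozMask = seq_len(n) == 1,
                meta = list(id = "toy", patient = "p1", seizure = 1))
}
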