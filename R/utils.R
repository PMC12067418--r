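# Internal helpers shared across modules.

# Deterministically derive a child seed from a master seed and a stream index.
# Lehmer step modulo the Mersenne prime 2^31 - 1 keeps results in R's 32-bit
# integer range and gives well-separated streams for consecutive indices.
.deriveSeed <- function(master, index) {
  m <- 2147483647
  s <- (as.double(master) %% m + 1) # avoid the absorbing state 0
  s <- (s * 48271) %% m
  s <- (s + as.double(index) * 69621) %% m
  as.integer((s * 16807) %% m)
}

.assertScalarNumeric <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Greatest common divisor for integer resampling ratios.
.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

.matchMethod <- function(method) match.arg(method, c("pdc", "dtf"))
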