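#' Specification of a synthetic iEEG seizure recording
#'
#' Describes one ground-truth recording: an order-2 MVAR network whose
#' designated SOZ subset acts as a net sink (`inflow_dominant`), a net source
#' (`outflow_dominant`), or neither (`null`, sparse couplings with no SOZ
#' asymmetry). With `ramp = TRUE` the coupling strength grows linearly across
#' the seven preictal windows, emulating flow that builds up toward onset; the
#' ictal block reuses the final preictal network with doubled coupling (a
#' deliberately schematic stand-in -- no seizure waveform modelling).
#'
#' @param nChannels number of channels (default 12; clinical recordings run
#'   45-176 channels, but MVAR fits on 4-s windows need n well below
#'   T / (2p), so small networks are the sensible simulation default).
#' @param nSoz number of SOZ channels (default ~15\% of channels, min 2).
#' @param regime `"inflow_dominant"`, `"outflow_dominant"` or `"null"`.
#' @param coupling off-diagonal MVAR coefficient magnitude (default 0.4).
#' @param ramp logical; ramp coupling across preictal windows (default TRUE).
#' @param fs sampling rate in Hz (default 500).
#' @param preictalS,ictalS epoch lengths in seconds (defaults 28 and 28).
#' @param windowS analysis window in seconds (default 4).
#' @param noiseSd additive white observation-noise SD (default 0.5).
#' @param nCouplingsPerSoz planted edges per SOZ channel (default 3).
#' @param seed integer seed making the recording fully reproducible.
#' @return A validated list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nChannels = 12,
                          nSoz = max(2L, round(0.15 * nChannels)),
                          regime = c("inflow_dominant", "outflow_dominant",
                                     "null"),
                          coupling = 0.4, ramp = TRUE, fs = 500,
                          preictalS = 28, ictalS = 28, windowS = 4,
                          noiseSd = 0.5, nCouplingsPerSoz = 3, seed = 1L) {
  regime <- match.arg(regime)
  if (nSoz >= nChannels) stop("nSoz must be smaller than nChannels")
  if (nSoz < 1) stop("need at least one SOZ channel")
  if (coupling < 0) stop("coupling must be >= 0")
  spec <- list(nChannels = as.integer(nChannels), nSoz = as.integer(nSoz),
               regime = regime, coupling = coupling, ramp = isTRUE(ramp),
               fs = fs, preictalS = preictalS, ictalS = ictalS,
               windowS = windowS, noiseSd = noiseSd,
               nCouplingsPerSoz = as.integer(nCouplingsPerSoz),
               seed = as.integer(seed))
  class(spec) <- c("SyntheticSpec", "list")
  spec
}

.nSegments <- function(spec, period = "preictal") {
  dur <- if (period == "preictal") spec$preictalS else spec$ictalS
  as.integer(round(dur / spec$windowS))
}

# Fixed network topology for a spec: which directed couplings exist.
# Drawn from the spec seed only, so all of a recording's windows share the
# same structure (only the coupling magnitude ramps).
.networkTopology <- function(spec) {
  seed <- if (!is.null(spec$topologySeed)) spec$topologySeed else spec$seed
  set.seed(.deriveSeed(seed, 104729L))
  n <- spec$nChannels
  sozIdx <- sort(sample.int(n, spec$nSoz))
  nonSoz <- setdiff(seq_len(n), sozIdx)
  # per-channel rhythm frequencies inside the 3-45 Hz analysis band; the
  # self-dynamics are oscillatory (complex AR(2) poles) so the synthetic
  # signal carries its energy where the protocol's band-pass is transparent
  oscFreq <- stats::runif(n, 5, 35)
  edges <- NULL # rows: (target i, source j)
  kEdges <- spec$nCouplingsPerSoz
  if (spec$regime == "inflow_dominant") {
    for (i in sozIdx) {
      src <- sample(nonSoz, min(kEdges, length(nonSoz)))
      edges <- rbind(edges, cbind(i, src))
    }
  } else if (spec$regime == "outflow_dominant") {
    for (j in sozIdx) {
      tgt <- sample(nonSoz, min(kEdges, length(nonSoz)))
      edges <- rbind(edges, cbind(tgt, j))
    }
  } else {
    # null: every channel gets exactly kEdges incoming and kEdges outgoing
    # couplings (random fixed-point-free permutations), so in-/out-degree is
    # uniform and no channel subset is a net sink or source by construction
    # -- label-permutation symmetry holds per realization, not just in
    # distribution
    drawPerm <- function() {
      perm <- sample.int(n)
      fp <- which(perm == seq_len(n))
      if (length(fp) == 1L) {
        swap <- if (fp == n) 1L else n
        perm[c(fp, swap)] <- perm[c(swap, fp)]
      } else if (length(fp) > 1L) {
        perm[fp] <- perm[c(fp[-1], fp[1])]
      }
      perm
    }
    for (k in seq_len(kEdges)) {
      for (try in 1:50) {
        perm <- drawPerm()
        cand <- cbind(seq_len(n), perm)
        if (is.null(edges) ||
            !any(duplicated(rbind(edges, cand))[-seq_len(nrow(edges))]))
          break
      }
      edges <- rbind(edges, cand)
    }
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  list(sozIdx = sozIdx, edges = edges, oscFreq = oscFreq)
}

.rampFactor <- function(spec, segmentIndex, nSeg) {
  if (!spec$ramp || nSeg == 1L) return(1)
  0.5 + 0.5 * (segmentIndex - 1) / (nSeg - 1)
}

#' Ground-truth MVAR network for one analysis window
#'
#' Order-2 model. Each channel's self-dynamics are a damped oscillation: a
#' complex AR(2) pole pair at that channel's rhythm frequency (drawn in
#' 5-35 Hz) with modulus 0.65, i.e. diagonal coefficients
#' \eqn{a_1 = 2 r \cos(2\pi f_0/f_s)}, \eqn{a_2 = -r^2}. This concentrates
#' the synthetic signal's power inside the 3-45 Hz analysis band, where the
#' protocol's band-pass is transparent -- broadband (real-pole) self-dynamics
#' would leave most variance outside the band and the filter, not the
#' network, would then dominate the fitted dynamics. On top of that the
#' regime's planted lag-1 couplings are added at magnitude `coupling * ramp`.
#' If the companion spectral radius exceeds 0.95 the off-diagonal couplings
#' are scaled down (at most 20 times) until it does not.
#'
#' @param spec a [syntheticSpec()] object.
#' @param segmentIndex which preictal window (1-based) the model drives.
#' @param period `"preictal"` or `"ictal"`; the ictal network is the final
#'   preictal one with doubled coupling.
#' @return An [MVARModel-class] that passes [isStable()].
#' @export
makeNetwork <- function(spec, segmentIndex = 1L,
                        period = c("preictal", "ictal")) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  period <- match.arg(period)
  n <- spec$nChannels
  nSeg <- .nSegments(spec, "preictal")
  topo <- .networkTopology(spec)
  if (period == "preictal") {
    cEff <- spec$coupling * .rampFactor(spec, segmentIndex, nSeg)
  } else {
    cEff <- 2 * spec$coupling * .rampFactor(spec, nSeg, nSeg)
  }
  A <- array(0, c(n, n, 2))
  r <- 0.65
  diag(A[, , 1]) <- 2 * r * cos(2 * pi * topo$oscFreq / spec$fs)
  diag(A[, , 2]) <- -r^2
  if (nrow(topo$edges)) {
    A1 <- A[, , 1]
    A1[topo$edges] <- A1[topo$edges] + cEff
    A[, , 1] <- A1
  }
  A <- .stabilizeCouplings(A)
  A <- .balanceCouplings(A)
  MVARModel(A, noiseCov = diag(n), fs = spec$fs)
}

# Shrink off-diagonal couplings (bisection on a common scale factor, the
# diagonal self-dynamics untouched) until the companion spectral radius is
# at most 0.95. Cyclic couplings between near-resonant oscillators can
# inflate the radius well beyond the product of the individual moduli, so a
# guaranteed-bracketing search is used rather than fixed-point rescaling.
.stabilizeCouplings <- function(A, radMax = 0.95, iters = 40L) {
  radiusAt <- function(s) {
    As <- A
    for (k in seq_len(dim(A)[3])) {
      Ak <- A[, , k]
      d <- diag(Ak)
      Ak <- Ak * s
      diag(Ak) <- d
      As[, , k] <- Ak
    }
    list(A = As,
         rad = max(Mod(eigen(.companionMatrix(As), only.values = TRUE)$values)))
  }
  full <- radiusAt(1)
  if (full$rad <= radMax) return(full$A)
  lo <- 0; hi <- 1
  best <- radiusAt(0)
  if (best$rad > radMax)
    stop("could not stabilize the generated network")
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    cand <- radiusAt(mid)
    if (cand$rad <= radMax) { lo <- mid; best <- cand } else hi <- mid
  }
  best$A
}

# Stationary per-channel variances of a stable MVAR with unit innovations,
# by iterating the companion-form Lyapunov recursion S <- Q + C S C'.
.stationaryVariances <- function(A, iters = 300L) {
  n <- dim(A)[1]
  p <- dim(A)[3]
  C <- .companionMatrix(A)
  Q <- matrix(0, n * p, n * p)
  Q[1:n, 1:n] <- diag(n)
  S <- Q
  for (k in seq_len(iters)) S <- Q + C %*% S %*% t(C)
  diag(S)[1:n]
}

# Cap the variance a channel's incoming couplings inject to `cap` times its
# intrinsic (decoupled) variance, by shrinking that channel's off-diagonal
# row. Near-resonant driving can otherwise inflate a coupled channel's
# amplitude several-fold, which clinical (amplifier-ranged, montaged) iEEG
# does not show; after z-scoring such inflation would crush the very
# coefficients the analysis must recover.
.balanceCouplings <- function(A, cap = 1.5, iters = 6L) {
  n <- dim(A)[1]
  p <- dim(A)[3]
  base <- A
  for (k in seq_len(p)) base[, , k] <- diag(diag(base[, , k]), n)
  v0 <- .stationaryVariances(base)
  for (it in seq_len(iters)) {
    ratio <- .stationaryVariances(A) / v0
    if (all(ratio <= cap * 1.05)) break
    for (i in which(ratio > cap)) for (k in seq_len(p)) {
      row <- A[i, , k]
      d <- row[i]
      row <- row * sqrt(max(cap / ratio[i], 0.1))
      row[i] <- d
      A[i, , k] <- row
    }
  }
  A
}

#' Generate one ground-truth synthetic recording
#'
#' Simulates each preictal window from its own [makeNetwork()] model,
#' continuing the trajectory across window boundaries (the previous window's
#' tail seeds the next recursion), appends the ictal block, adds white
#' Gaussian observation noise, and places electrical onset exactly at the
#' preictal/ictal boundary. Bit-reproducible given `spec$seed`.
#'
#' @param spec a [syntheticSpec()] object.
#' @return list with `recording` (an [IEEGRecording-class]) and `truth`
#'   (list: sozIdx, sozMask, regime, expectedDominant, models).
#' @export
generateRecording <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$nChannels
  nWin <- round(spec$windowS * spec$fs)
  nSegPre <- .nSegments(spec, "preictal")
  nSegIct <- .nSegments(spec, "ictal")
  topo <- .networkTopology(spec)
  models <- list()
  blocks <- vector("list", nSegPre + nSegIct)
  init <- NULL
  for (s in seq_len(nSegPre)) {
    m <- makeNetwork(spec, s, "preictal")
    models[[s]] <- m
    blocks[[s]] <- simulateMVAR(m, nWin, seed = .deriveSeed(spec$seed, s),
                                burnIn = if (s == 1L) 1000L else 50L,
                                init = init)
    init <- blocks[[s]][, (nWin - m@order + 1L):nWin, drop = FALSE]
  }
  if (nSegIct > 0) {
    mIct <- makeNetwork(spec, period = "ictal")
    for (s in seq_len(nSegIct)) {
      blocks[[nSegPre + s]] <- simulateMVAR(
        mIct, nWin, seed = .deriveSeed(spec$seed, 1000L + s),
        burnIn = if (s == 1L) 200L else 50L, init = init)
      init <- blocks[[nSegPre + s]][, (nWin - mIct@order + 1L):nWin,
                                    drop = FALSE]
    }
    models$ictal <- mIct
  }
  X <- do.call(cbind, blocks)
  if (spec$noiseSd > 0) {
    set.seed(.deriveSeed(spec$seed, 424243L))
    X <- X + matrix(stats::rnorm(length(X), sd = spec$noiseSd), nrow(X))
  }
  sozMask <- seq_len(n) %in% topo$sozIdx
  rec <- IEEGRecording(
    X, fs = spec$fs, onsetSample = nSegPre * nWin, sozMask = sozMask,
    meta = list(id = sprintf("synthetic-seed%d", spec$seed),
                dataset = "synthetic", regime = spec$regime,
                coupling = spec$coupling, noiseSd = spec$noiseSd))
  truth <- list(
    sozIdx = topo$sozIdx, sozMask = sozMask, regime = spec$regime,
    expectedDominant = switch(spec$regime,
                              inflow_dominant = "inflow",
                              outflow_dominant = "outflow",
                              "none"),
    models = models)
  list(recording = rec, truth = truth)
}

#' Generate a reproducible synthetic cohort
#'
#' Draws per-patient channel counts and seizure counts, assigns regimes by
#' the requested mix (largest-remainder rounding, then a seeded shuffle), and
#' generates every seizure via [generateRecording()]. SOZ annotations are at
#' the patient level: all of a patient's seizures share one SOZ set, as in
#' the open iEEG archives this emulates. Implant type and lesional status are
#' drawn as inert metadata for stratified summaries.
#'
#' @param nPatients number of patients.
#' @param regimeMix named proportions over
#'   `c("inflow_dominant", "outflow_dominant", "null")`; must sum to 1.
#' @param baseSeed master seed; the whole cohort is a pure function of it.
#' @param nChannelsRange inclusive range of per-patient channel counts
#'   (default `c(10, 16)`, chosen so every 4-s window comfortably supports
#'   the MVAR fit; pass e.g. `c(45, 176)` to emulate clinical channel
#'   counts).
#' @param seizuresRange inclusive range of seizures per patient (default
#'   `c(2, 5)`).
#' @param ... further arguments passed to [syntheticSpec()] (coupling,
#'   noiseSd, ramp, ...).
#' @return list of per-seizure lists `(recording, truth)`; each recording's
#'   meta carries patient, seizure, regime, implant_type and lesional.
#' @export
generateCohort <- function(nPatients, regimeMix = c(inflow_dominant = 0.5,
                                                    outflow_dominant = 0.5),
                           baseSeed = 1L, nChannelsRange = c(10, 16),
                           seizuresRange = c(2, 5), ...) {
  full <- c(inflow_dominant = 0, outflow_dominant = 0, null = 0)
  if (is.null(names(regimeMix)) || !all(names(regimeMix) %in% names(full)))
    stop("regimeMix must be named with regimes: ",
         paste(names(full), collapse = ", "))
  full[names(regimeMix)] <- regimeMix
  if (abs(sum(full) - 1) > 1e-9)
    stop(sprintf("regime proportions must sum to 1 (got %g)", sum(full)))
  # largest-remainder apportionment, deterministic
  raw <- full * nPatients
  counts <- floor(raw)
  rem <- nPatients - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  regimes <- rep(names(full), counts)
  set.seed(.deriveSeed(baseSeed, 7919L))
  regimes <- sample(regimes)
  out <- list()
  for (p in seq_len(nPatients)) {
    pSeed <- .deriveSeed(baseSeed, p)
    set.seed(pSeed)
    nCh <- sample(seq(nChannelsRange[1], nChannelsRange[2]), 1)
    nSz <- sample(seq(seizuresRange[1], seizuresRange[2]), 1)
    implant <- sample(c("ecog", "seeg", "grid_strip_depth"), 1)
    lesional <- sample(c(TRUE, FALSE), 1)
    for (s in seq_len(nSz)) {
      # patient-level SOZ: the topology seed is shared across the patient's
      # seizures, only innovations differ
      spec <- syntheticSpec(nChannels = nCh, regime = regimes[p],
                            seed = pSeed, ...)
      szSpec <- spec
      szSpec$seed <- .deriveSeed(pSeed, 500000L + s)
      gen <- generateRecording(.withSharedTopology(szSpec, spec))
      gen$recording@meta <- c(gen$recording@meta[
        setdiff(names(gen$recording@meta), "id")],
        list(id = sprintf("p%02d_s%02d", p, s),
             patient = sprintf("p%02d", p), seizure = s,
             implant_type = implant, lesional = lesional))
      out[[length(out) + 1L]] <- gen
    }
  }
  out
}

# Carry the topology seed of `base` while using `spec`'s innovation seed:
# the generator reads topology from `topologySeed` when present.
.withSharedTopology <- function(spec, base) {
  spec$topologySeed <- base$seed
  spec
}
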