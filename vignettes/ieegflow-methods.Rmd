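---
title: "Preictal directed-connectivity analysis with ieegflow: models, choices, limits"
author: "ieegflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preictal directed-connectivity analysis with ieegflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegflow)
```

## The question the package addresses

In focal epilepsy, the electrode contacts where clinicians first see ictal
activity — the seizure-onset zone (SOZ) — are embedded in a wider network.
In the half-minute before electrical onset, is the SOZ predominantly
*receiving* directed influence from the rest of the network (a net sink,
consistent with surrounding tissue exerting control), or predominantly
*sending* it (a net source, consistent with the SOZ already driving the
network)? `ieegflow` implements a complete, reproducible pipeline for that
question: given multichannel intracranial EEG with an onset annotation and
an SOZ channel set, it estimates frequency-resolved directed connectivity,
prunes edges against a spectral-preserving null, reduces the directed graph
to per-channel inflow and outflow, scores how well those flows separate SOZ
from non-SOZ channels (ROC/AUC), and labels each recording
*inflow-dominant*, *outflow-dominant*, or *unclassified*.

## The model chain

**Preprocessing.** Channels flagged artifactual are dropped; signals are
band-pass filtered to 3–45 Hz with a 60 Hz notch, downsampled to 500 Hz,
z-scored over the retained recording, and cut into seven non-overlapping
4-s windows per 28-s epoch (preictal: ending exactly at onset; ictal:
starting exactly at it). Four seconds is the usual compromise between the
quasi-stationarity a vector-autoregression assumes and having enough
samples (2000 at 500 Hz) to estimate it.

**MVAR.** Each window is modelled as
$x_t = \sum_{k=1}^{p} A_k\, x_{t-k} + e_t$, fitted by ordinary least
squares on the lagged design. The innovation covariance uses the unbiased
denominator $T - p - np$. Model order is selected by Schwarz's Bayesian
criterion by default (`selectOrder(..., criterion = "sbc")`), with AIC
available; both are computed from $\log\det\hat\Sigma_p$ plus their
penalty. SBC is the default because it is the more parsimonious of the two
and order inflation is the greater danger on filtered data (see
*Numerical behaviour* below). Order selection is per window; on synthetic
data the selected order is stable across a recording's windows, and the
pipeline records all selections. Unstable fits (companion spectral radius
$\ge 1$) are flagged with a warning but retained — connectivity is still
computable, and discarding windows would bias the flow dynamics.

**Spectral connectivity.** With
$\bar A(f) = I - \sum_k A_k e^{-i 2\pi f k / f_s}$ and
$H(f) = \bar A(f)^{-1}$, partial directed coherence is the
column-normalized $|\bar A_{ij}(f)|$ and the directed transfer function the
row-normalized $|H_{ij}(f)|$. Entry $(i, j)$ always means influence of
source $j$ on target $i$, so inflow is a row sum and outflow a column sum,
for both methods. Values are averaged (magnitudes, not squares) over a
3–45 Hz grid at 0.5 Hz steps — 85 bins, matching the band-pass and roughly
the 0.25 Hz native resolution of a 4-s window. Mean-of-magnitudes keeps
weights in $[0, 1]$; the grid and band are configurable.

**Surrogate pruning.** Per window and per estimator, 100 phase-randomized
surrogates (independent uniform phases per channel, amplitude spectra
preserved exactly) are refitted at the window's selected order, giving each
directed edge an empirical null. Edges not *strictly* above the null's
0.95 order statistic (at `ceiling((1 - alpha) * n)`) are zeroed. Strict
inequality makes ties conservative; fixing the surrogate order holds model
complexity constant under the null. Thresholding acts on the
band-aggregated weight — the quantity every downstream step consumes.

**Flows, AUC, classification.** Inflow/outflow are weighted node strengths
(continuous, not binary degree), min–max normalized within each window so
the 0–1 ROC threshold sweep is well defined. A channel's score for a
seizure is the median of its seven window values (robust, and the simplest
defensible pooling; configurable in principle but fixed here). AUC is the
tie-aware Mann–Whitney form. A recording is *inflow-dominant* when pooled
SOZ inflow exceeds non-SOZ inflow by one-sided Wilcoxon rank-sum under
**both** PDC and DTF (Bonferroni over the four tests of one recording) and
the same conjunction does **not** hold for outflow; symmetrically for
*outflow-dominant*; anything else is *unclassified*. Demanding both
methods and exclusivity makes the rule conservative — on exchangeable data
the dominant labels fire at well under $2\alpha$.

## The synthetic cohort: what it emulates and what it does not

`syntheticSpec()`/`generateRecording()` produce ground-truth recordings:
an order-2 MVAR network per 4-s window, simulated with Gaussian
innovations, concatenated with trajectory continuity, plus additive white
observation noise (SD 0.5), 28 s preictal + 28 s ictal at 500 Hz. Regimes:
*inflow-dominant* (each SOZ channel receives 3 couplings of magnitude 0.4
from random non-SOZ sources), *outflow-dominant* (mirror image), *null*
(degree-regular random couplings: every channel has identical in- and
out-degree, so no subset is a net sink or source by construction). With
`ramp = TRUE` (default) coupling grows linearly from 50% to 100% across
the seven preictal windows, emulating flow that builds toward onset; the
ictal block reuses the final network with doubled coupling and is a
deliberately schematic stand-in (no spikes, DC shifts or high-frequency
oscillations — none of the waveform phenomenology of real seizures).

Three generator decisions deserve emphasis, because each was forced by an
identifiable failure mode of the analysis protocol itself:

1. **Oscillatory self-dynamics.** Each channel's diagonal is a damped
   oscillation — complex AR(2) poles at a per-channel rhythm frequency
   drawn from 5–35 Hz with modulus 0.65 — rather than a broadband real
   pole. Real iEEG carries its usable power in band; a generator that puts
   most variance outside 3–45 Hz hands the band-pass filter, not the
   network, control of the fitted dynamics, and direction recovery
   collapses.

2. **Coupling balancing.** Incoming couplings are rescaled (companion-form
   Lyapunov computation) so planted edges inject at most ~50% extra
   stationary variance into their target. Near-resonant driving can
   otherwise inflate a coupled channel's amplitude an order of magnitude —
   which amplifier-ranged clinical recordings do not show — and z-scoring
   would then shrink precisely the coefficients the analysis must recover
   below the estimation floor.

3. **Degree-regular null.** The null regime's couplings are built from
   fixed-point-free permutations so label-permutation symmetry holds per
   realization, not merely in distribution. A null made of a few strong
   random edges contains genuine realized sinks and sources, and a
   calibration test against it measures generator asymmetry rather than
   classifier behaviour.

Simulations default to 10–16 channels although clinical recordings run
45–176: a 4-s window has 2000 samples, and least-squares MVAR needs
$n \ll T/(2p)$; at ~100 channels and the orders selected on filtered data
the regression is rank-deficient. Passing tests on small dense networks
demonstrate that the chain of estimators is correct and calibrated — they
do not demonstrate that the method works at clinical channel counts, on
non-stationary data, or against real artifact structure.

## Numerical behaviour of the protocol (why some choices look odd)

Band-limiting before autoregression is the analytically delicate step in
this protocol. A band-passed process has (numerically) no power over most
of the Nyquist range, its innovations are non-invertible, and no
finite-order AR whitens them; the misfit re-routes through whatever
channel offers predictive power, so high-variance aggregate channels
acquire strong spurious *reverse* edges. We verified the effect is caused
by band-limitation, not phase handling: a causal filter inverts direction
estimates exactly as the zero-phase one does, and raising the fitted order
to 36 does not repair it. Three package choices follow directly:

* the low-pass side of the filter is 3rd order — as gentle as the 40 dB
  stop-band requirement at 100 Hz allows — while the high-pass side is 4th
  order (nothing informative lives below 3 Hz);
* the generator keeps channel variances comparable (balancing, above), so
  no channel is a privileged proxy predictor;
* order selection defaults to the more parsimonious SBC.

Other numerical conventions: zero-phase filtering via forward–backward
application; the notch is an RBJ biquad (Q = 30); polyphase resampling
with `onset` mapped by rounding; ties in order selection break toward the
smaller order; constant score vectors normalize to all zeros; AUC gives
ties half credit; the exact Wilcoxon branch (pooled $n \le 12$) enumerates
all rank assignments and handles ties, larger samples use the
tie-corrected normal approximation with continuity correction; epochs must
divide exactly into windows (the 28/4 design never needs truncation).

## Problem sizes used by the test-suite experiments

The acceptance-level experiments run at: 100 random stable models
($n \le 8$, $p \le 3$) for the normalization identities; 1000 random small
cases for the AUC oracle; 17 four-channel white-noise segments
(204 off-diagonal edges) with 100 surrogates for threshold calibration; 20
seeds per regime at 10 channels for regime recovery; and a 10-patient
50/50 mixed cohort (2–3 seizures each, 10–14 channels) for the
pooled-versus-grouped contrast. These sizes were chosen as the smallest
that give the binomial and rank statistics room to be decisive.

## Known limitations

* The band-limitation pathology is asymmetric between the two regimes.
  A fan-in (sink) channel aggregates several sources and therefore makes
  an unusually good proxy predictor on band-limited data, so it acquires
  spurious *outgoing* edges; a fan-out source does not aggregate anything
  and suffers much less. In the test-suite experiments this shows up
  directly: outflow-dominant synthetic recordings are recovered almost
  always, while for inflow-dominant recordings the spurious SOZ outflow
  frequently either defeats the classification's exclusivity clause or
  dilutes the PDC-inflow significance, and pooled outflow AUC medians sit
  well above chance in both regimes. The package reports these numbers as
  measured rather than working around them, because the mechanism lives in
  the specified protocol (band-pass, then autoregression at 500 Hz), not
  in any implementation choice that could be corrected downstream.
* Estimators are linear; nonlinear or cross-frequency coupling is
  invisible to them.
* The ictal synthetic block is schematic; ictal-period results on
  synthetic data exercise the code path, not seizure physiology.
* No re-referencing/montage logic and no automated artifact detection:
  recordings are consumed as stored, with artifact channels taken from
  annotations.
* Band-limited autoregression has the intrinsic pathology described
  above; on real data this biases flow estimates in ways that cannot be
  fully corrected downstream, which is consistent with the modest
  real-data AUCs reported in the literature this protocol follows.

## A minimal worked example

```{r example, eval = FALSE}
library(ieegflow)

gen <- generateRecording(syntheticSpec(nChannels = 10,
                                       regime = "outflow_dominant",
                                       seed = 42))
cfg <- pipelineConfig(masterSeed = 1)
res <- analyzeRecording(gen$recording, cfg)
groupLabel(res)   # "outflow_dominant"
aucTable(res)     # per method x measure AUCs

cohort <- generateCohort(4, c(inflow_dominant = 0.5, outflow_dominant = 0.5),
                         baseSeed = 7, seizuresRange = c(2, 2))
out <- runPipeline(cohort, cfg, outDir = tempfile("ieegflow-run-"))
out$summary$summary
```
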