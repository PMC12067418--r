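# ieegflow

Directed-connectivity analysis of preictal intracranial EEG (iEEG), asking
a simple clinical-network question: in the 28 seconds before a seizure, are
the seizure-onset-zone (SOZ) electrode contacts a net **sink** of directed
influence (high inflow) or a net **source** (high outflow)?

The package is aimed at epilepsy-network researchers who want the complete
chain — preprocessing, multivariate autoregressive (MVAR) modelling,
spectral directed connectivity, surrogate-based edge pruning, graph flow
metrics, ROC/AUC evaluation, and per-recording regime classification — as
tested, seedable R functions rather than a pile of scripts.

## The method in brief

Each 28-s preictal (and optionally ictal) epoch is band-passed to 3–45 Hz
(zero-phase) with a 60 Hz notch, downsampled to 500 Hz, z-scored, and cut
into seven 4-s windows. Each window is fitted with an MVAR model

    x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t

(order by Schwarz's Bayesian criterion). From the Fourier-domain
coefficient matrix Ā(f) = I − Σ_k A_k e^(−i2πfk/fs) and the transfer
function H(f) = Ā(f)⁻¹, two directed estimators are computed on an 85-bin
grid and averaged over the band:

* **PDC** π_ij(f) = |Ā_ij(f)| / √(Σ_m |Ā_mj(f)|²) — direct influence,
  column-normalized;
* **DTF** γ_ij(f) = |H_ij(f)| / √(Σ_m |H_im(f)|²) — direct plus cascaded
  influence, row-normalized.

Every edge is tested against 100 phase-randomized surrogates (spectra
preserved, cross-channel correlation destroyed) and pruned at p = 0.05.
Per-channel **inflow** (in-strength) and **outflow** (out-strength) are
min–max normalized per window; the median over the seven windows scores
each channel, and the AUC of that score against the clinician SOZ labels
measures discrimination. A recording is *inflow-dominant* when SOZ inflow
is significantly higher than non-SOZ inflow under both PDC and DTF (and
outflow is not), *outflow-dominant* symmetrically, otherwise
*unclassified*.

A ground-truth synthetic cohort generator (`syntheticSpec()`,
`generateRecording()`, `generateCohort()`) produces seedable recordings
whose SOZ really is a net sink, a net source, or neither, so the entire
pipeline is testable without clinical data. Real data can be read from
EDF files, BIDS-iEEG-style directories, or a plain-text fixture format.

## Worked example

```r
library(ieegflow)

gen <- generateRecording(syntheticSpec(nChannels = 10,
                                       regime = "outflow_dominant",
                                       seed = 3))
res <- analyzeRecording(gen$recording, pipelineConfig(masterSeed = 7))
res
#> EvaluationResult: outflow_dominant (4 AUC entries)
#>  method measure   period  auc
#>     dtf  inflow preictal 0.25
#>     pdc  inflow preictal 0.25
#>     dtf outflow preictal 1.00
#>     pdc outflow preictal 1.00
res@tests[, c("name", "p_adjusted")]
#>          name   p_adjusted
#> 1  pdc_inflow 1.000000e+00
#> 2  dtf_inflow 1.000000e+00
#> 3 pdc_outflow 1.750907e-05
#> 4 dtf_outflow 1.516150e-04
```

The two SOZ channels of this simulated recording send, rather than
receive, directed influence: both outflow AUCs are at ceiling, the
outflow rank-sum tests survive Bonferroni correction while the inflow
tests do not, and the recording is labelled `outflow_dominant` — matching
the generator's ground truth. (Numbers above were produced by this exact
code; seeds make them reproducible. AUC values printed by your session may
differ if you change any configuration default.)

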