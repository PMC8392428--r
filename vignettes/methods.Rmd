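---
title: "Dynamic brain-network tensors for seizure prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic brain-network tensors for seizure prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

Scalp EEG before an epileptic seizure (the *pre-ictal* state) shows altered
statistical coupling between channels compared with the seizure-free
*inter-ictal* baseline. This package implements a prediction pipeline that
exploits the *dynamics* of that coupling rather than a static summary:

1. **Band filtering.** Each multichannel segment is restricted to one of the
   five canonical bands — delta (0.5–4 Hz), theta (4–8), alpha (8–15),
   beta (15–30), gamma (30–60) — or left unfiltered ("raw"), with a
   Fourier-transform filter (`fftBandpass()`).
2. **Windowed correlation networks.** The signal is cut into 8-s windows
   sliding by 4 s. For each window the Pearson correlation matrix of the 23
   channels is thresholded at the significance level
   \(Th = 1 - (1-\alpha)^{1/(L-1)}\) and binarized
   (`adjacencySeries()`), giving one functional brain network per window.
3. **Tensor stacking.** `num` consecutive networks (3–6) are stacked into a
   binary third-order tensor \(X \in \{0,1\}^{23\times 23\times num}\), a
   *dynamic* functional brain network (`stackTensors()`).
4. **CP features with frozen channel factors.** A reference tensor is
   decomposed by CP/PARAFAC,
   \(X \approx \sum_{r=1}^{R} \lambda_r\, a_r \circ b_r \circ c_r\),
   with the rank \(R\) grown until the relative Frobenius error drops below
   0.05 (`selectRank()`). The channel-mode factors \(A, B\) are then frozen
   (`fitReference()`); every other tensor only needs the closed-form
   least-squares solve for its time-mode factor \(C\), and the feature is
   the column mean of \(F = C\,\mathrm{diag}(\lambda)\)
   (`extractFeature()`), a length-\(R\) vector per tensor.
5. **Classification.** A regularized extreme learning machine — random
   sigmoid hidden layer, ridge output weights
   \(\hat\beta = (H^\top H + E I)^{-1} H^\top Y\) — classifies feature rows
   as inter-ictal (1) or pre-ictal (2); the regularization parameter is
   chosen by the closed-form PRESS leave-one-out error (`selectRegularization()`).
6. **Alarm rule.** Streaming per-tensor labels feed a counter that
   increments on 2 and resets on 1; 30 consecutive pre-ictal detections
   trigger an alert (`alarmScan()`), and the prediction time is
   \(T = s\,(n+1)\) with \(s\) the stream step and \(n\) the number of
   unprocessed windows at the alert (`predictionTime()`).

Degree \(D_i = \sum_j a_{ij}\) and clustering coefficient
\(C_i = 2E_i / (k_i(k_i-1))\) serve as per-window baseline feature families
for comparison (`metricFeatures()`).

# Parameters that matter

| parameter | default | unit | notes |
|---|---|---|---|
| `fs` | 256 | Hz | sampling rate of the recordings |
| `windowS` / `stepS` | 8 / 4 | s | semi-overlapping correlation windows |
| `alpha` | 0.95 | — | confidence level of the threshold |
| `L` | 337 | — | disjoint 8-s sections of a 45-min segment (2700/8) |
| `num` | 3 | networks | tensor depth; 3–6 in the reference protocol |
| `tensorStride` | `num` | networks | disjoint stacks by default |
| `errThresh` | 0.05 | — | CP rank-search target error |
| `M` | 100 | neurons | ELM hidden width |
| `Egrid` | \(2^{-10}..2^{10}\) | — | ridge grid for PRESS selection |
| `alarmLen` | 30 | detections | consecutive pre-ictal states for an alert |

**On `L`.** With \(\alpha=0.95\) and \(L=337\), \(Th \approx 0.0089\): almost
any systematic coupling clears it, and the networks are dense. The defining
phrase for \(L\) ("average number of disjoint sections") admits smaller
readings under which the threshold would be far stricter. We keep \(L\)
configurable, default 337, and do not guess beyond that; the synthetic
generator was calibrated so that the two classes differ *through* this
dense-network regime (below).

**Binarization rule.** The default thresholds the correlation magnitude
(\(|r| > Th\)): strong anticorrelation is physiologically a connection. The
literal signed rule \(r > Th\) is available as `binRule = "signed"`.
"Directional relationships" cannot arise from Pearson correlation, so the
networks are undirected by construction.

# The synthetic generator — what it emulates and what it does not

`generateSegment()` mixes five shared unit-variance narrowband oscillators
(a random-phase sinusoid plus band-limited noise, one per canonical band, at
2, 6, 11.5, 22 and 40 Hz) into independent Gaussian channel noise:

\[ x_c(t) = \varepsilon_c(t) + 0.4 \sum_s m_{cs}\, g(t)\, s_s(t), \qquad
   m_{cs} \sim U(0.2, 1), \]

with the coupling envelope \(g(t)\) clamped to \([0,1]\) and drifting
linearly at `driftRate` per second for the pre-ictal class. Mixing weights
are drawn once per segment, so segments are individuals, not replicas.
Amplitudes are scaled into a ±95 µV range (one global gain, leaving
correlations untouched) before EDF writing so the 16-bit quantization of the
format is exercised realistically.

The amplitude calibration was chosen analytically, before any end-to-end
run, so that the study conditions (inter-ictal coupling 0.2, stationary;
pre-ictal 0.8, drifting) straddle the default threshold: with a source scale
of 0.4 on unit noise, gamma-band pair correlations at coupling 0.2 sit near
\(Th(\alpha=0.95, L=337) \approx 0.009\) — partial, window-varying edge
occupancy (~0.85) — while coupling 0.8 saturates the band (~0.98 occupancy).
The classes therefore differ in both the level and the temporal dynamics of
network density, which is exactly the structure the time-mode CP factor is
meant to capture.

What the generator does **not** model: spikes and artifacts, realistic 1/f
spectra, volume conduction, electrode montage geometry, or any physiological
seizure mechanism. Passing tests on these data show that the pipeline
recovers controllable coupling structure through the full stack (EDF I/O,
filtering, thresholding, tensors, classifier, alarm); they do not certify
clinical performance on real recordings, which depend on montage handling
and far messier class structure.

# Numerical choices

* **ALS.** Factors are initialized uniformly on \([0,1)\) (nonnegative, like
  the binary tensors). Each factor update is an exact least-squares solve
  via the Moore–Penrose pseudoinverse of the Hadamard-product Gram matrix,
  so the per-sweep relative error is provably non-increasing; iteration
  stops when the error changes by less than `tol` (1e-6) or after
  `maxIter` (200) sweeps.
* **Warm-started rank search.** The \(R\)-component search starts from the
  accepted \((R-1)\)-component factors plus one fresh random component. The
  new component enters with a *small random* time-mode weight: a zero
  column, the obvious neutral choice, is a degenerate ALS fixed point (its
  Gram row is zero and the pseudoinverse keeps it at zero forever). Because
  the first factor update can always reproduce the previous solution, the
  error trace over \(R\) is still non-increasing.
* **Reference tensor.** "Decomposed for the first time" is resolved as: the
  first tensor of the first *training* segment in catalog order, per band
  and per `num`. Under leave-one-segment-out this means at most two distinct
  references (the fold that holds out the first segment uses the second),
  and a held-out segment never influences its own training fold.
* **Degenerate inputs.** Zero-variance channels get correlation 0 (isolated
  nodes) rather than an error; a zero tensor has relative error 0 against a
  zero reconstruction and selects rank 1; nodes with degree ≤ 1 have
  clustering 0; ELM prediction ties break toward label 1.
* **Tie-breaks in model selection.** PRESS ties choose the smaller \(E\);
  grid values whose leverage \(1 - HAT_{ii}\) falls below 1e-12 are skipped.

# Evaluation design

* **Grouped cross-validation.** Feature rows inherit the identity of their
  source segment, and folds are assigned at segment level (stratified by
  class). Row-level folds would let the classifier match a test row to
  training rows from the *same* recording — with per-segment mixing weights
  that is segment re-identification, not state classification, and it would
  break the null-calibration property (identical class specifications must
  yield chance accuracy). With 16 segments and 10 requested folds, 8 groups
  per class fill 8 effective folds.
* **Alarm stream units.** For tensor features the label stream advances one
  tensor per step, so the step size in \(T = s(n+1)\) is
  `tensorStride * stepS` (12 s at the defaults); for the per-window
  baselines it is `stepS` (4 s).
* **Null calibration band.** Under grouped folding the exchangeable unit is
  the segment, so the binomial 95% band around 0.5 uses \(n = \) number of
  segments, not number of rows; within-segment predictions are strongly
  correlated.
* **Problem sizes.** The packaged experiments use 8+8 segments of 10 min
  (149 windows, 49 tensors at `num = 3` per segment; 784 feature rows),
  chosen as the smallest scale at which the alarm rule (30 consecutive
  detections out of 49) and the cross-validated protocols are all
  non-trivially exercised.

# Known limitations

* The channel montage is a fixed, configured 23-name list; recordings that
  cannot supply it are not resolved or re-montaged.
* The rank search is a single-seed, single-restart loop per \(R\) (the
  literal reading of the reference procedure); multi-restart robustness is
  not attempted.
* CP feature quality depends on the (random) reference decomposition; the
  influence of that randomness is not averaged out.
* Ten-fold results on per-tensor rows and leave-one-segment-out results on
  whole recordings answer different questions (state discrimination vs
  alert behavior); neither is a clinical endpoint.
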