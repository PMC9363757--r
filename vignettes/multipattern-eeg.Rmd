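---
title: "Multi-pattern resting-state EEG analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pattern resting-state EEG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions they make, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical decisions
taken where the design was genuinely open. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## 1. The analysis model

A subject's resting-state EEG is a channels × samples matrix in microvolts
(32 channels in the canonical montage; 500–512 Hz sampling). The pipeline
is:

1. **Band-pass 0.5–50 Hz**, zero phase. Artifact removal (eye blinks,
   channel noise, heartbeat) is *not* performed: interactive ICA cannot be
   reproduced from a text description, so recordings are assumed clean and
   a `hook` argument on `preprocess_recording()` accepts a user-supplied
   cleaning step.
2. **Montage harmonisation** to the 32 common channels, in a fixed order.
   A recording that referenced online to Pz lacks that channel; it is
   reconstructed as the arithmetic mean of its four neighbours P1, P2, CPz
   and POz. No re-referencing beyond this rule (the reference of the source
   recordings is left untouched — a deliberate choice, since the upstream
   acquisition reference is not recoverable).
3. **Truncation** to the first 180 s (512 Hz systems) or 120 s (500 Hz),
   then **segmentation into 1-s non-overlapping epochs**, dropping any
   trailing partial epoch. This reproduces the canonical tensor shapes
   32 × 512 × 180 and 32 × 500 × 120 exactly.
4. **Features per epoch**:
   - *PSD (activation)*: one-sided periodogram — squared DFT magnitude
     scaled by $1/(f_s n)$ — summed over the DFT bins of each band. With
     1-s epochs the bin spacing is 1 Hz.
   - *PLV (connectivity)*: per band, a zero-phase Hamming-window FIR
     band-pass, the Hilbert analytic-signal phase $\varphi(t)$, then for
     each unordered channel pair
     $\mathrm{PLV}_{A,B} = \bigl|\tfrac1N\sum_t e^{-i(\varphi_A(t)-\varphi_B(t))}\bigr|$
     over the epoch's (edge-trimmed) time points. 496 pairs for 32
     channels, named `ChA-ChB` with A before B in montage order.
5. **Group contrast**: per unit (channel or pair), a two-sample pooled-
   variance Student's t-test on per-epoch feature values and the ratio of
   group means (Fisher-domain means for PLV: $\tanh(\overline{\mathrm{artanh}})$);
   the significance mask keeps units with $P \le 0.05$.
6. **Classification**: per-epoch feature rows — PSD (32), PLV (496) or
   their concatenation PSD+PLV (528) for one band — are z-scored with
   statistics fitted on training rows only, then classified by a linear
   SVM (C = 1) or by the multi-scale CNN; stratified 10-fold
   cross-validation at the epoch level (a 9:1 split), reporting accuracy,
   sensitivity, specificity, ROC and AUC.

### Assumptions worth stating

- Epochs are treated as exchangeable observations. Consecutive 1-s epochs
  of the same subject are *not* independent, and epoch-level CV lets the
  classifier exploit subject identity. This matches the published
  evaluation protocol, and it is why a `split = "subject"` mode exists:
  with it, no subject contributes rows to both train and test folds. The
  epoch-level default is a faithful-reproduction choice, not an
  endorsement.
- The t-test unit is the per-epoch value pooled across a group's subjects
  (`observation = "epoch"`), again matching the published masks. The
  per-subject-mean alternative (`observation = "subject"`) is the
  statistically conservative choice and is what `planted_effect_report()`
  uses, because at cohort scale the subject is the sampling unit.
- Disease (class 1) is the positive class for sensitivity; the source
  description leaves this unstated.
- Units are microvolts throughout; readers never rescale silently.

## 2. The multi-scale CNN

Each 528-feature row is assembled into a **32 × 32 symmetric matrix**:
channel $i$'s normalised band power on the diagonal, pair $(i,j)$'s PLV at
the off-diagonal positions. This construction is the package's own (the
source architecture never states how the hybrid vector becomes its 32 × 32
input); it is deterministic, invertible (`input_to_row()`), and puts the
connectivity structure where 2-D convolutions can see it.

The network has two parallel branches over that input:

- **Sub-network 1 (2-D scale)**: conv 6@5×5 (same-padded) → maxpool 2×2 →
  conv 16@5×5 → *residual block* (two shape-preserving conv 16@5×5, pad 2,
  identity skip added to their output) → maxpool 2×2 → conv 120@5×5 →
  maxpool 2×2. All ReLU.
- **Sub-network 2 (1-D scale)**: conv 32@7×1 (same) → maxpool 2×1 →
  conv 64@5×1 → maxpool 2×1. The ×1 kernels convolve along the channel
  axis (rows); the orientation is a design decision — the table only says
  "one-dimensional".
- Outputs are flattened, concatenated, and passed through dropout 0.5 →
  dense 84 (no activation is listed for this layer, so it is linear) →
  dropout 0.5 → dense 2 (per-unit sigmoid, binary cross-entropy on one-hot
  targets) or dense 3 (softmax, categorical cross-entropy).

**Residual placement.** The description puts the residual block "after the
first convolution pooling" and lists two pad-2 16-channel convolutions:
pad 2 on a 5×5 kernel preserves shape, which is exactly what an identity
skip needs, so those two layers form the residual body. A probe test
verifies the block reduces to the identity map when its weights are zeroed.

**Optimisation.** Plain SGD, learning rate 0.001. The stated "decay rate of
0.1" is read as inverse-time learning-rate decay,
$\eta_t = \eta_0 / (1 + 0.1\,t)$ per completed epoch $t$; the weight-decay
reading is available as `decay_mode = "weight"`. Loss is not stated
upstream; cross-entropy is the only loss consistent with the
sigmoid/softmax heads. Batch size (64) and the epoch budget (default 50,
best-validation checkpointing) are package choices; the wide dense head
makes the MCNN converge within a couple of epochs on separable data, while
the much smaller LeNet-5 baseline (classic 6-16-120-84 topology, ~61k
parameters against the MCNN's ~1.1M) needs ~20–25 epochs at this learning
rate.

The layers (convolution, pooling, dense, dropout, residual) are implemented
in vectorised R with C++ gather/scatter kernels — no deep-learning
framework exists in the supported environment. Determinism: one integer
seed controls initialisation, batch shuffling and dropout masks, and two
runs with the same seed produce identical training histories.

## 3. The synthetic cohort generator

`generate_cohort()` emulates the *statistical* structure the analysis is
meant to detect, not the biophysics. Each channel is

$$x_c(t) = \underbrace{b_c(t)}_{1/f\ \text{background}}
        + \sum_{\text{bands } k} a_k \,\mathrm{Re}\, z_{c,k}(t),$$

where $b_c$ is Gaussian noise with a $1/f$ amplitude spectrum (exponent 1,
flat below 0.5 Hz, total RMS 10 µV — a realistic resting-EEG amplitude) and
$z_{c,k}$ is a narrow-band analytic Gaussian oscillator confined to band
$k$ with a 10% cosine edge taper.

**Oscillator amplitudes.** `band_amplitudes` are relative to the square
root of the *total* 1–48 Hz background power (defaults δ 1, θ 1, α 1.2,
β 0.9, γ 0.8); α ≈ 1 means an alpha rhythm as strong as the entire
broadband background, the classic resting posterior-alpha picture. Because
the 1/f background spreads its power roughly log-uniformly across bands,
each oscillator then dominates its own band (in-band SNR ≈ 5–10). This is
what makes a planted power factor recoverable: a 2× γ factor on one channel
is observed as a group ratio of about $(2P_{osc}+P_{bg})/(P_{osc}+P_{bg})
\approx 1.8$ — background dilutes the raw factor, and the recovery
tolerance [1.7, 2.3] reflects that. A strictly in-band SNR-of-1 reading
would cap the observable ratio at 1.5 and make the generator unable to
express its own target effects.

**Phase coupling.** A coupled pair shares one band oscillator; each member
channel multiplies it by $e^{i\theta_c(t)}$ with $\theta_c(t)$ drawn from a
von Mises distribution of concentration $\kappa$, piecewise-constant over
0.125-s blocks. Two independent VM jitters give an asymptotic PLV of
$(I_1(\kappa)/I_0(\kappa))^2$ (`plv_from_kappa()`): ≈ 0.98 at κ = 50,
≈ 0.80 at κ = 5, 0 at κ = 0. Two deliberate subtleties:

- *κ = 0 plants nothing.* A blockwise-uniform jitter of a shared oscillator
  would still leave residual within-epoch dependence (only ~6 independent
  blocks per trimmed epoch), which is **not** the independent-phase null.
  At κ = 0 the channels therefore keep fully independent oscillators.
- *Coupled channels absorb their in-band background into the shared
  oscillator* (total band power unchanged, so PSD is untouched). Without
  this, independent in-band noise caps the estimated PLV of even a κ = 50
  pair near 0.6; with it, the estimate through the full FIR + Hilbert path
  sits above 0.8 — the remaining gap to the asymptotic 0.98 is honest
  estimation attenuation (FIR smoothing across jitter-block boundaries and
  the finite epoch).

Per-subject log-normal gain jitter (SD 0.1) models inter-subject amplitude
variability. The cohort is bit-reproducible from its seed.

**What the generator does not emulate** — and hence what a green test does
not establish: volume conduction and field spread (real PLV is inflated by
zero-lag mixing), artifacts, non-stationarity beyond the phase-jitter
blocks, realistic cross-frequency structure, and any physiological
difference between actual PD and HC brains. A green planted-effect test
means the *pipeline recovers what was planted*, not that the features are
clinically valid.

## 4. Numerical choices

- **Wide band-pass**: 4th-order Butterworth prototype (8-pole band-pass),
  applied forward-backward **twice**. One zero-phase pass of the 4th-order
  design leaves ~17% amplitude at 60 Hz for the 0.5–50 Hz band; the second
  pass brings stop-band leakage below 5% while keeping the polynomial
  well-conditioned. Response, not implementation, is what the tests check
  (60 Hz tone → <5% RMS; 10 Hz tone → within 5% of unity), measured in the
  filter's steady state (edges trimmed), since the 0.5 Hz edge rings for
  seconds. Coefficients were cross-checked against an independent
  implementation during development.
- **FIR design**: Hamming-window sinc, `3 * fs / low_hz` taps (odd), capped
  at one sample less than the epoch length — a 1-s epoch cannot support the
  1500-tap kernel a 1 Hz edge would ask for, so δ-band phase estimates on
  1-s epochs are intrinsically blurry; group delay removed exactly
  (symmetric kernel).
- **Hilbert edge artifacts**: 10% of the epoch trimmed from each side
  before the PLV mean (`edge_trim`, configurable).
- **DFT bin assignment**: half-open $[f_{low}, f_{high})$, so adjacent
  bands never double-count a bin, and contiguous bands tile total power to
  1e-9 (a Parseval property test).
- **PLV averaging domain**: the equation's "sum over N trials" conflicts
  with "PLV for every second"; the package averages over time points
  *within* each 1-s epoch, yielding a PLV time series (one value per epoch
  per pair per band) that feeds per-epoch classification. The across-epoch
  alternative (`average = "across_epochs"`) averages the phase-difference
  phasor across epochs at matched time points.
- **PSD scale**: absolute linear power (no log, no relative normalisation);
  the classifier-side z-score handles scale.
- **SVM**: L2-regularised L1-loss dual coordinate descent, C = 1, bias via
  an appended constant column, projected-gradient tolerance 1e-3, shuffled
  coordinate order from a seed independent of R's RNG stream.
- **ROC/AUC**: threshold sweep over distinct scores with trapezoid area;
  ties are handled by the diagonal segments, making AUC exactly the
  normalised Mann–Whitney U (a 50-case property test asserts equality to
  1e-12).
- **Degenerate inputs**: zero-variance contrast units get $p = 1$ with a
  warning; zero-variance features scale to 0; an all-zero signal has
  undefined phase and returns 0 with a warning; recordings shorter than
  the requested truncation are a validation error that reports the
  available length.

## 5. Known limitations

- Epoch-level CV leaks subject identity (see §1); published-protocol
  accuracy numbers should be read with that caveat, and subject-level CV is
  one switch away.
- No multiple-testing correction in the default contrast masks (faithful to
  the per-unit $P \le 0.05$ convention); Benjamini–Hochberg is available
  (`p_adjust = "BH"`) and is what the planted-effect report uses.
- The PD_OFF / PD_ON contrast involves the same subjects; a paired test
  would be more powerful, but the pairing is not modelled (the unpaired
  pooled-variance test matches the published analysis).
- The CNN engine is CPU-bound R/C++; it is sized for the 32 × 32 inputs of
  this problem, not for general deep learning.
- Real-data reproduction requires downloading the public datasets and an
  upstream artifact-removal step; only the synthetic validation is part of
  the test suite.
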