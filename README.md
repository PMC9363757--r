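# mpeeg — multi-pattern resting-state EEG analysis for Parkinson's disease detection

`mpeeg` is an R package for detecting Parkinson's disease (PD) from
resting-state EEG by combining two complementary views of brain function:

- the **activation pattern** — band power spectral density (PSD) per channel,
  summed over the canonical bands δ (1–4 Hz), θ (4–8), α (8–12), β (13–30)
  and γ (30–48 Hz);
- the **connectivity pattern** — the phase-locking value (PLV) per channel
  pair,

  PLV(A, B) = | (1/N) Σₜ exp(−i·(φ_A(t) − φ_B(t))) | ∈ [0, 1],

  where φ(t) is the instantaneous Hilbert phase of the band-limited signal
  and the sum runs over the time points of a 1-second epoch.

Per-epoch features feed group contrast maps (ratio of group means with
Student's-t significance masks, Fisher-domain means for PLV), a linear-SVM
baseline, and a **multi-scale convolutional neural network (MCNN)**: two
parallel sub-networks over a 32 × 32 multi-pattern input (a 2-D branch with
a residual block and a 1-D branch convolving along the channel axis), whose
flattened outputs are concatenated before a dense head — plus a classic
LeNet-5 as an ablation baseline. Everything is validated on synthetic
cohorts with *planted* spectral and connectivity effects, so the whole
pipeline is testable without patient data.

Who it is for: anyone who wants a reproducible, dependency-light EEG
biomarker pipeline — readers of the PD EEG-classification literature who
want to poke at the method, and methods developers who need a synthetic
ground-truth harness for PSD/PLV feature extractors and classifiers.

## What is inside

| module | contents |
| --- | --- |
| data model & I/O | `eeg_recording`, `eeg_epochs`; readers/writers for EDF, BDF (BioSemi), EEGLAB `.set`/`.fdt`; HDF5 epoch container; CSV feature store |
| preprocessing | zero-phase Butterworth 0.5–50 Hz band-pass, 32-channel montage harmonisation with Pz imputation (mean of P1/P2/CPz/POz), truncation, 1-s epoching |
| features | `compute_psd` (one-sided periodogram summed per band), `compute_plv` (Hamming-window FIR → Hilbert phase → per-epoch PLV), `fisher_mean_plv` |
| contrast | `group_contrast` (t-test masks at P ≤ 0.05, ratio of group means), `render_contrast` (topographic / matrix maps), permutation oracle |
| classification | `assemble_features` (PSD 32 / PLV 496 / PSD+PLV 528 columns), z-score normalisation with leakage guard, linear SVM (dual coordinate descent, C = 1), stratified k-fold CV, accuracy/sensitivity/specificity/ROC-AUC |
| deep model | `build_mcnn` / `build_lenet5` / `train_mcnn` / `crossval_mcnn`: SGD (lr 0.001, inverse-time decay 0.1), dropout 0.5, sigmoid/softmax heads |
| synthetic | `cohort_spec` / `generate_cohort`: 1/f background + per-band oscillators, planted power factors and von Mises phase coupling; `planted_effect_report` |
| cli | `mpeeg_cli()` / `inst/cli/mpeeg` with subcommands `run`, `synth`, `preprocess`, `features`, `contrast`, `classify`, `train-mcnn` |

No DSP, SVM or deep-learning R package is required: the Butterworth/FIR
filters, Hilbert transform, SVM solver and CNN engine are implemented in
the package (C++ via Rcpp for the hot loops).

## Worked example

A one-command synthetic demo: an 8-subject cohort (4 HC, 4 PD) with a
planted 2× γ-power effect on Cz/C3/C4 and a κ = 50 β-band coupling on
C3–C4 and F3–F4, preprocessed, featurised, contrasted and classified with a
5-fold linear SVM on the γ-band PSD+PLV hybrid features:

```r
library(mpeeg)
cfg <- system.file("extdata", "demo_config.yaml", package = "mpeeg")
report <- run_pipeline(cfg, out_dir = tempfile("mpeeg_demo"))
```

```
[mpeeg synth] generating 8 subjects -> .../synth-889df45726
[mpeeg preprocess] band 0.5-50 Hz, epoch 1 s -> .../preprocessed-49f7711c97
[mpeeg features] 2 bands x 8 subjects -> .../features-6468362c2d
[mpeeg contrast] PSD/gamma PD vs HC: 28/32 significant
[mpeeg classify] svm PSD_PLV/gamma: acc 75.42%
[mpeeg run] report written to .../report.json
```

```r
cls <- report$stages$classify
sprintf("accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f",
        cls$accuracy, cls$sensitivity, cls$specificity, cls$auc)
#> "accuracy 75.42%, sensitivity 73.33%, specificity 77.50%, AUC 0.841"
```

Reading the numbers: with only 4 subjects per group and ~10% inter-subject
amplitude variability, the per-epoch t-test flags most channels (28/32) —
epoch-level pooling treats each second as independent, so subject-level
amplitude differences masquerade as group effects; `planted_effect_report`
uses per-subject means and Benjamini–Hochberg flagging instead and recovers
exactly the planted units on larger cohorts. The SVM's 75% accuracy /
AUC 0.841 reflects the genuine planted γ/β signal; sensitivity is the
recall of the PD class (class 1), specificity the recall of HC. Larger
cohorts and stronger effects drive both models above 95% (see
`tests/testthat/test-acceptance.R`).

The same pipeline from a shell:

```sh
inst/cli/mpeeg run --config inst/extdata/demo_config.yaml --out demo_out
```

## Reproducing published real-data results (optional)

The package's desk-scale validation is entirely synthetic. To run the
method on the public resting-state datasets it was designed around
(OpenNeuro `ds002778` — 32-channel BioSemi, 512 Hz, HC/PD_OFF/PD_ON; and
the University of Iowa dataset — 64-channel Brain Vision, 500 Hz, Pz
missing and imputed from P1/P2/CPz/POz), download the recordings locally
and run:

```sh
mpeeg preprocess --input <dir> --format bdf --band 0.5 50 \
      --montage inst/extdata/montage32.yaml --duration 180 --epoch 1.0 --out pre/
mpeeg features --in pre/ --bands all --psd --plv --out feat/
mpeeg classify --features feat/ --mode psd+plv --band gamma \
      --groups HC PD_OFF --folds 10 --seed 7 --out report.json
mpeeg train-mcnn --features feat/ --band gamma --groups HC PD_OFF \
      --folds 10 --seed 7 --out mcnn.json
```

Expect qualitative agreement with the published pattern — β/γ bands
outperform δ/θ, PSD+PLV beats either pattern alone, and the MCNN beats the
linear SVM — rather than exact percentages; artifact rejection (ICA) is out
of scope here and is assumed done upstream (or injected via the `hook`
argument of `preprocess_recording`).

See `vignettes/multipattern-eeg.Rmd` for the model, the synthetic
generator's assumptions, and every numerical choice.
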