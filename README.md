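# emgflow

Two-stage hand-gesture recognition from multichannel surface
electromyography (sEMG), for researchers in biosignal processing,
prosthetic control and human–machine interfaces who need a transparent,
fully scriptable reference implementation of a coarse-to-fine recognition
pipeline.

## What it implements

Given a samples × channels sEMG recording with per-sample gesture labels
(Ninapro-style MAT-files, HDF5, or the built-in synthetic generator), the
pipeline runs:

1. **Z-score normalization** per channel, then **Teager-energy
   relabeling**: the discrete Teager–Kaiser operator
   ψ(n) = x(n)² − x(n−1)·x(n+1) is averaged over channels, smoothed by a
   causal moving window of N samples, and thresholded with a
   minimum-duration hysteresis to locate true muscle activity; labels are
   rewritten to match the detected activity (correcting subject
   response-time lag in the cue-based labels).
2. **Fixed 400 ms windows** cut without overlap from label-pure runs.
3. **Multivariate variational mode decomposition (MVMD)**: each window is
   decomposed into K narrow-band multivariate modes u_k(t) with one joint
   center frequency ω_k per mode, by ADMM in the frequency domain —
   per-channel Wiener-filter mode updates
   û_k,c ← (x̂_c − Σ_{i≠k} û_i,c + λ̂_c/2) / (1 + 2α(ω − ω_k)²),
   a power-weighted joint ω_k update pooled over channels, and a dual
   update with step τ, iterated until the summed relative change falls
   below ε.
4. **Stage 1**: classical time-domain features (RMS, MAV, DASDV, and the
   rest of the standard eight) per channel route the window to a gesture
   *superclass* (finger / wrist / functional movements, separable by force
   level) with an RBF-SVM (penalty 18, gamma "scale") or RF/DT/KNN/NB/LDA.
5. **Stage 2**: one depthwise-separable convolutional network per
   superclass (Conv 32-64-128, two 2×2 max-pools, zero-padding, dense 128,
   softmax; dropout 0.5; Adam, batch 256, early stopping) classifies the
   window's K-mode stack into the exact gesture. Separable convolution
   needs k²c + cN + N trainable parameters against k²cN + N for standard
   convolution — a bias-free ratio of k²cN / (k²c + cN).

Evaluation runs seeded, gesture-stratified tenfold cross-validation with
confusion matrices, plus the class-consistency correlation analysis that
compares raw windows against the lowest-frequency ("modified EMG") mode.

## Worked example

The packaged benchmark simulates 3 superclasses × 4 gestures × 40
repetitions on 4 channels at 100 Hz, with superclass force scales 1/3/9
and 200 ms label misalignment, then cross-validates the full framework:

```r
library(emgflow)
bench <- run_benchmark(seed = 1)
bench$report
#> <eval_report> 10-fold CV over 480 windows, 12 gestures
#>   stage-1 (superclass) accuracy: 1.0000
#>   end-to-end gesture accuracy:   0.9563
#>   per-fold: 0.979 0.938 1.000 0.917 0.979 0.917 1.000 0.854 0.979 1.000
```

Stage 1 routes every window to the correct force-level superclass;
end-to-end accuracy (routing errors included) is 95.6% over 12 gestures.
The correlation analysis shows why the low-frequency mode is the right
network input — repetitions of one gesture agree far more strongly on it
than on the raw signal:

```r
ds  <- bench$dataset
round(class_consistency_correlation(ds, use_modified = FALSE), 2)[1:4]
#>    1    2    3    4
#> 0.31 0.30 0.30 0.30
round(class_consistency_correlation(ds, use_modified = TRUE), 2)[1:4]
#>    1    2    3    4
#> 0.74 0.76 0.80 0.85
```

The parameter accounting of the stage-2 network is available without
training:

```r
build_scnn(scnn_spec(c(30, 10, 1), n_classes = 12))$layers
#>          layer      size channels params_standard params_separable
#>   Convolution2     (3,3)       64           18496             2400
#>   Convolution3     (3,3)      128           73856             8896
#>          Dense       128       NA          344192           344192
#>   ...
```

A thin command-line interface wraps the same functions
(`inst/cli/emgflow simulate|relabel|decompose|features|train-stage1|train-stage2|evaluate|predict`).

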