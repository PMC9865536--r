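# anescore

Depth-of-anesthesia (DoA) estimation from 4-channel frontal EEG, expressed
as the 0–100 patient state index (PSI; 100 ≈ fully awake). The package is a
complete, self-contained experimental pipeline for people studying
EEG-based sedation monitoring:

* **Synthetic ground truth** — a multi-subject EEG generator in which a
  latent depth `d(t) ∈ [0,1]` drives the δ/θ/α/β/γ band mixture of every
  channel and defines `PSI = round(100·(1−d))`. Blink artifacts (biphasic,
  <5 Hz, synchronized across frontal channels), 50 Hz line noise, baseline
  drift and per-subject lognormal gain provide realistic nuisance
  structure.
* **Preprocessing** — 4 s / 50% overlap segmentation (4×712 samples at
  178.2 Hz), a 1–51 Hz linear-phase FIR bandpass with group-delay
  compensation, and ocular-artifact removal by a wavelet → ensemble
  empirical-mode decomposition → ICA → sample-entropy screening chain.
* **The regressor** — a 1-D deep residual shrinkage network (DRSN) with
  channel-wise learned soft thresholds
  `τ_c = sigmoid(z_c) · mean(|x|_c)` applied to each residual branch,

  ```
  y = sign(x) · max(|x| − τ_c, 0)
  ```

  a 1×1-convolution head, global average pooling, and
  `p = 100 / (1 + e^{−v})` so predictions always lie in (0, 100). Training:
  Adam on MSE, batch 64, lr 0.005 decaying 10% every 20 epochs, L2 weight
  decay. Forward and backward passes are implemented in the package (R +
  compiled kernels), with gradients verified against finite differences.
* **Baselines** — SVR (RBF), random forest (300 trees) and a 14–64–16–1
  MLP on a 14-feature vector (multitaper band powers, hemisphere SEF95,
  per-channel sample entropy).
* **Evaluation** — random and subject-grouped five-fold cross-validation
  with MSE, macro-averaged one-vs-rest state metrics (AW/LA/NA/DA), and
  Spearman rank correlation.

## Worked example

```r
library(anescore)

spec <- sim_spec(n_subjects = 3, duration_per_subject = 120, seed = 1)
ds <- generate_dataset(spec)
samples <- prepare_samples(ds)          # segment + 1-51 Hz FIR bandpass
samples
#> 177 samples of 4 x 712 (3 subjects); PSI range [17, 98]

## clean one blink-contaminated window
seg <- bandpass_fir(segment_record(ds[[1]]$record)[[5]])
clean <- remove_eoa(seg, cleaning_config())

## features and a baseline
feats <- features_table(samples)
std_f <- standardize(feats)
rf <- baseline_fit("rf", std_f$train, samples$psi)
rf
#> Baseline PSI regressor: random forest (300 trees)

## the deep model
std <- standardize(samples$x)
fit <- drsn_fit(std$train, samples$psi,
                drsn_config(max_epochs = 32, seed = 1))
fit
#> Deep residual shrinkage PSI regressor
#>   stages: 8-8-16-16 channels, kernel 3, 11369 parameters
#>   trained 32 epochs on 177 samples; final train MSE 3.81

## cross-validated comparison of all four models
ev <- run_experiment(samples, models = c("svr", "rf", "ann", "drsn"),
                     cv = "random", k = 5, seed = 1)
print(ev)
```

`run_experiment()` reports mean ± SD over folds for MSE, macro accuracy,
macro sensitivity, macro F1 and Spearman correlation, per model, on
identical folds. `psi_to_state()` maps PSI to the four anesthetized states
(AW 81–100, LA 51–80, NA 26–50, DA 0–25).

A command-line interface covering the same stages
(`simulate`, `preprocess`, `extract-features`, `train`, `baselines`,
`evaluate`) is installed at `inst/scripts/anescore`; every stage writes a
JSON manifest with its configuration and seed.

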