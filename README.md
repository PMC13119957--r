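# mmrepair

Self-supervised **detect-and-repair** for multimodal wearable time series in
R. Wearable systems fuse several sensor streams — IMU acceleration, ECG,
electrodermal activity (EDA), respiration, skin temperature — but deployed
sensors drop out: poor contact, battery saving, artifacts. `mmrepair` trains
representations that (1) stay informative when modalities are missing,
(2) **detect** which modalities are missing, and (3) **reconstruct** the
missing streams from the ones that remain.

## Method

Each modality `m` is windowed (10 s, 50% overlap) and encoded by its own
shallow 1-D CNN `f_θ(m)` (kernels (5, 3, 3), channels (64, 128, 128), ReLU +
batch norm, global average pooling → embedding `z(m) ∈ R^128`). Additive
attention restricted to the *present* modalities fuses them:

    α ∝ softmax over present m of  w·tanh(W_a z(m) + b_a),
    z_f = Σ_m α_m (W_v z(m) + b_v),      α_m = 0 exactly for absent m.

Training simulates sensor failure by dropping each (window, modality)
independently with probability `rate` (≥ 1 modality always kept) and filling
dropped tensors with zeros or unit gaussian noise. The self-supervised
objective is

    L_total = λ_rec·L_masked + λ_con·L_contrastive + λ_pres·L_presence

with λ_rec = 1.0, λ_con = 0.5, λ_pres = 0.1, where `L_masked` is the MSE of a
conditioned decoder `d_ψ([z_f, mask])` on the *dropped* windows only,
`L_contrastive` is NT-Xent (τ = 0.5) between the projections (D → D → 64) of
modality pairs on windows where both are present, and `L_presence` is the
binary cross-entropy of a presence head `g_φ(z_f)` that learns to detect
missing modalities. Training runs in three phases: unimodal SimCLR
pretraining of one encoder, multimodal masked pretraining, and joint
fine-tuning (Adam, lr 1e-3, batch 32, seed 42). A BYOL-style momentum target
(m = 0.996) is available for phase 1.

All network layers and reverse-mode gradients are implemented in the package
(BLAS matrix ops + small C++ kernels) and are verified against finite
differences and a brute-force NT-Xent in the test suite. No external dataset
is required: a synthetic generator produces multimodal recordings driven by
a shared Markov latent state, which supplies the cross-modal redundancy the
method relies on.

## Worked example

```r
library(mmrepair)

# 1. synthetic study: 5 subjects, 3 latent states, 5 modalities
cfg  <- synthetic_config(n_subjects = 5, duration_s = 300, rate = 64, seed = 42)
recs <- generate_dataset(cfg)

# 2. preprocess: resample to 8 Hz, z-score per recording, 10 s windows
batches <- lapply(recs, preprocess_recording, rate = 8, window_s = 10, overlap = 0.5)
train <- bind_batches(batches[1:4])   # subjects S01-S04
test  <- batches[[5]]                 # held-out subject S05

# 3. train phases 2-3 with 30% modality dropout
tc  <- train_config(epochs = c(phase1 = 3, phase2 = 4, phase3 = 6), seed = 42,
                    dropout = dropout_policy(rate = 0.3, fill = "zeros", seed = 42))
fit <- phase3_joint_finetune(train, tc, init = phase2_masked_pretrain(train, tc))

# 4. evaluate on the held-out subject
ev <- evaluate_model(fit$model, train, test, rates = c(0, 0.1, 0.3, 0.5),
                     n_repeats = 3, seed = 42)
ev
#> <mm_eval fold1: probe acc 0.983, macro-F1 0.981>
#> reconstruction RMSE (single dropped modality):
#>  modality  rmse rmse_zero rmse_mean
#>       acc 1.004      1.00      1.00
#>       ecg 1.003      1.01      1.01
#>       eda 0.594      1.00      1.00
#>      temp 0.546      1.00      1.00
#>      resp 1.011      1.00      1.00
ev$robustness
#>    rate mean_accuracy sd_accuracy n_repeats
#> 1   0.0         0.983      0.0000         3
#> 2   0.1         0.977      0.0098         3
#> 3   0.3         0.949      0.0169         3
#> 4   0.5         0.938      0.0353         3
```

Reading the numbers: signals are z-scored, so an all-zeros (or per-channel
mean) imputation scores RMSE ≈ 1. The trained decoder reconstructs a dropped
EDA-like modality at RMSE 0.59 and the temperature-like one at 0.55 — the
carrier-free physiological channels are recoverable from the shared latent
state, while oscillatory channels (acc, resp) have random carrier phase and
stay near the imputation floor, as expected. The linear probe on fused
embeddings classifies the held-out subject's latent state at 98% with all
modalities and degrades gracefully (94% when half the modalities are dropped
at test time).

`tidy()`, `glance()` and `autoplot()` work on fits and evaluation reports;
`project_embeddings()` exports PCA/t-SNE coordinates.

## Command line

A thin CLI over the same functions lives at `inst/cli/mmrepair`
(subcommands `simulate`, `preprocess`, `pretrain`, `train`, `evaluate`,
`repair`, `visualize`; YAML config with strict validation):

```sh
Rscript inst/cli/mmrepair simulate --config run.yaml --out data/
Rscript inst/cli/mmrepair train    --config run.yaml --out runs/a/
Rscript inst/cli/mmrepair repair   --config run.yaml --manifest data/S01_manifest.json --out runs/a/
```

`repair` detects which modalities of a recording are corrupted (presence
probabilities per window) and writes reconstructed CSVs for the missing
streams.

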