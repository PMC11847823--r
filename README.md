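# eegattn

Subject-independent EEG emotion recognition with attention network layers,
and — the reason this package exists — a statistical pipeline that turns the
learned attention weights into tested, ranked statements about **which EEG
channels drive the prediction**.

## Who this is for

Researchers in affective computing / EEG analysis who want to (a) train a
subject-independent emotion classifier whose features are made
subject-invariant by domain-adversarial training, and (b) interrogate the
trained model about channel relevance instead of inspecting features before
training. Everything runs from R; no restricted datasets are needed to
exercise any stage, because the package ships a synthetic-EEG generator with
known ground truth.

## The model and analysis in brief

Recordings are decimated to 200 Hz, band-passed to 0.5–50 Hz (4th-order
zero-phase Butterworth), and cut into non-overlapping 4 s windows. Each
window becomes a channels × 50 matrix of Hilbert–Huang power (EMD →
analytic signal → marginal spectrum in 1 Hz bins, 0–50 Hz). Per-video
window stacks are zero-padded to a common width `w` and fed to the network:

- layer normalization per channel over frequency;
- dual self-attention, `Z = (softmax(XXᵀ/50)X + X) + (softmax(XᵀX/62)Xᵀ + Xᵀ)ᵀ`;
- graph layer `H = ELU(S Z W_graph)` over the montage adjacency
  `S = D̃^{-1/2}(A+I)D̃^{-1/2}`, `A_ij = 1/‖x_i − x_j‖`;
- spatial attention over channels: weights `φ` (a simplex per window);
- BiLSTM over windows plus temporal attention: weights `ψ` (a simplex per
  video) and pooled vector `t = Σ_w ψ_w g_w`;
- a softmax emotion head, and a sigmoid domain head behind a
  gradient-reversal layer trained with
  `λ(p) = 2/(1+e^{−10p}) − 1` ramping over training progress `p`.

Evaluation is leave-one-subject-out: the held-out subject's videos enter
training only through the unsupervised domain term. Afterwards, per video,
spatial weights are aggregated over the first `W̄` windows (the dataset
mean window count): `ω_k = Σ_{t≤W̄} Φ_{t,k} Ψ_t`. Per-channel Wilcoxon
tests between every emotion pair, adjusted jointly by Benjamini–Hochberg
(FDR 0.05), plus a ranking by mean `ω`, form the relevance report.

## Worked example

Bookkeeping quantities are instant and deterministic:

```r
library(eegattn)

n_pairwise_tests(3); n_pairwise_tests(4); n_pairwise_tests(5)
#> [1] 186
#> [1] 372
#> [1] 620

s <- summarize_segment_counts(segment_count_table("seediv"))
s$class_means
#>  neutral      sad     fear    happy
#> 37.66667 37.94444 34.16667 29.33333
s$dataset_mean_windows   # aggregation horizon W-bar
#> [1] 34
s$pad_length             # maximum observed window count
#> [1] 64
```

The montage and its normalized adjacency (62-channel 10/20-extended layout,
idealized positions in mm):

```r
adj <- build_normalized_adjacency(channel_montage())
dim(adj$S)
#> [1] 62 62
signif(adj$S["T7", c("C5", "CZ")], 3)   # near neighbour vs far channel
#>      C5      CZ
#> 0.01930 0.00508
```

Spectral features concentrate where they should — a pure 10 Hz tone puts
all its marginal Hilbert power into the [10, 11) Hz bin:

```r
t <- (0:799) / 200
pw <- hht_psd(rbind(T7 = sin(2 * pi * 10 * t)))
round(pw[1, 11] / sum(pw), 3)
#> [1] 1
```

The end-to-end claim — that aggregated attention finds the channels
carrying emotion information — is exercised by the synthetic recovery
benchmark: 6 subjects, 16 channels, 3 classes, with a 3× alpha-band boost
injected at T7/T8 for one emotion and a 3× beta boost at O1/O2 for
another:

```r
rb <- recovery_benchmark(synthetic_spec(seed = 1))  # ~10 min on one CPU
rb$accuracy$mean        # LOOCV macro accuracy (chance = 1/3)
rb$carrier_ranks        # where T7, T8, O1, O2 land in the attention ranking
head(rb$tests[order(rb$tests$p_adj), ])  # BH-adjusted channel contrasts
```

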