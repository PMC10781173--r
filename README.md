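# stseize

Automatic seizure detection for long-term multichannel scalp EEG,
combining Stockwell-transform time-frequency features with a small
Transformer encoder that treats each EEG channel as a token. It is
aimed at researchers building patient-specific detectors on
CHB-MIT-style recordings (23 bipolar 10–20 channels, 256 Hz) and at
anyone who needs a tested, self-contained reference implementation of
this detection pipeline — including a seeded synthetic EEG generator,
so the whole chain runs and is verifiable without any external data.

## Method

Each 4-s epoch (1024 points at 256 Hz) is processed as follows.

**1. S-transform.** The Stockwell transform

$$S_x(\tau, f) = \sum_t x(t)\,\frac{f}{\sqrt{2\pi}}\,
  e^{-(\tau-t)^2 f^2/2}\, e^{-i2\pi f t}\,\Delta t$$

uses a Gaussian window of width $1/f$: wavelet-style multiresolution
with STFT-style absolute phase. One row per integer Hz and one column
per sample give a 128 × 1024 matrix over 1–128 Hz. `stockwell()` is an
FFT-accelerated implementation; `stockwell_direct()` evaluates the
defining sum and serves as its oracle (they agree to machine
precision).

**2. Rhythm-band compression.** Within 1–50 Hz, $|S|^2$ is summed over
six clinical bands — delta (1–4 Hz), theta (4–8), alpha (8–12), beta
(12–30), gamma1 (30–40), gamma2 (40–50) — crossed with two 2-s time
halves: 12 energies per channel, an $n \times 12$ feature map per
epoch.

**3. Transformer encoder.** Channel embedding (each channel's 12-vector
is a token, $d_{model} = 12$, no positional encoding), $L = 6$ layers
of multi-head self-attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})\,V$ with $h = 3$ heads and
$d_k = d_v = 4$, in the residual form
$S_i = S_{i-1} + y_i + \mathrm{MLP}(\mathrm{LN}(y_i))$ with
$y_i = \mathrm{MSA}(\mathrm{LN}(S_{i-1}))$; then max-pooling over
channels, an MLP head and a softmax over (non-seizure, seizure).
Averaging the columns of the summed final-layer attention matrices
yields per-channel attention weights (`channel_attention()`).

**4. Post-processing.** The per-epoch probability stream passes through
a moving-average filter, a threshold, collar extension, and K-of-N
discrimination ($K = 5$ positives within a sliding $N = 10$-epoch,
40-s window mark the whole span), and contiguous positive runs become
events.

**5. Scoring.** Segment-based accuracy / sensitivity / specificity /
precision and Mann–Whitney AUC; event-based sensitivity, false
detections per hour (FDR), and detection latency.

## Worked example

```r
library(stseize)

# a 20-minute synthetic recording with three seizures
rec <- generate_eeg_record(duration_s = 1200, n_channels = 23,
                           n_seizures = 3, seed = 42)
rec
#> EEG record: 23 channels x 307200 samples (1200 s @ 256 Hz), 3 annotated seizure(s)

ds <- segment_record(rec, mode = "balanced", seed = 42)
ds
#> Segment dataset: 180 windows of 4 s (90 ictal, 90 interictal)

ft  <- featurize_dataset(ds)
fit <- seizure_transformer(ft$maps, ft$labels, encoder_config(seed = 42))
fit
#> Seizure-detection Transformer encoder
#>   layers: 6  heads: 3  d_model: 12  block: printed
#>   parameters: 11570
#>   trained 45 epochs (best epoch 35 ), final val loss 0.0002

# detect events on an unseen half-hour recording
test_rec <- generate_eeg_record(duration_s = 1800, n_channels = 23,
                                n_seizures = 2, seed = 43)
det <- detect_seizures(test_rec, fit)
event_metrics(det$events, test_rec$annotations, test_rec$duration_s / 3600)
#> Event-based score: 2/2 seizures detected (sensitivity 100.00%)
#>   false alarms: 0 over 0.50 h (FDR 0.00/h)
#>   mean detection latency: 0.00 s

# which channels does the model attend to?
w <- channel_attention(fit, ft$maps[ft$labels == 1][1:5])
round(sort(w, decreasing = TRUE)[1:5], 3)
#>    T7-P7    P3-O1   FP1-F7   FP1-F3 FT9-FT10
#>    0.148    0.144    0.142    0.139    0.136
```

The event score reads: both injected seizures were recovered, no false
alarm was raised in 0.5 h, and detection began at (or, after the
collar/K-of-N widening, slightly before) the annotated onsets, hence
the zero latency. The attention weights are near-uniform here because
the synthetic seizures are broadcast to all channels — on focal
recordings they concentrate on the involved electrodes.

A command-line front end wraps the same functions:

```sh
stseize=$(Rscript -e 'cat(system.file("scripts/stseize", package="stseize"))')
Rscript $stseize simulate  --duration 3600 --seizures 4 --seed 1 --out rec.edf
Rscript $stseize featurize --edf rec.edf --out features.csv
Rscript $stseize train     --features features.csv --out model.rds
Rscript $stseize predict   --edf rec.edf --model model.rds --out events.csv
Rscript $stseize score-events --events events.csv --annotations rec.csv --hours 1
```

## Layout

- `R/stransform.R` — direct and FFT S-transform, plans, spectrograms
- `R/features.R` — band scheme, compression, normalisation, CSV cache
- `R/model.R`, `R/model-fit.R` — encoder, backprop, Adam training,
  S3 methods (`predict`, `summary`, `coef`, `plot`, `channel_attention`)
- `R/postprocess.R` — MAF, threshold, collar, K-of-N, event extraction
- `R/evaluate.R` — segment metrics, AUC, event scoring
- `R/synthdata.R` — synthetic records, segmentation, splits
- `R/io.R` — EDF read/write, annotation/event/feature CSVs, YAML config
- `src/st_energies.cpp` — compiled band-energy kernel
- `vignettes/seizure-detection-methods.Rmd` — modelling assumptions,
  parameter choices, limitations
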