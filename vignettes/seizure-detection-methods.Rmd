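---
title: "Methods: S-transform features and a channel-token Transformer for seizure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S-transform features and a channel-token Transformer for seizure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stseize)
```

## The detection problem

Long-term scalp EEG review for epilepsy is dominated by the search for
rare ictal episodes inside many hours of background. `stseize`
implements a patient-specific detector for multichannel recordings
(CHB-MIT-style: ~23 bipolar 10--20 channels, 256 Hz, 16-bit): the
recording is cut into 4-s epochs, each epoch is mapped to a compact
time-frequency feature map, a small Transformer encoder scores each
epoch, and a post-processing chain turns the score stream into seizure
events that are evaluated both per segment and per event.

## Time-frequency representation

The Stockwell transform (S-transform) of a segment $x(t)$ is

$$S_x(\tau, f) = \sum_t x(t)\,\frac{f}{\sqrt{2\pi}}
  e^{-(\tau-t)^2 f^2/2}\, e^{-i2\pi f t}\,\Delta t,$$

a Fourier-modulated Gaussian window whose width scales as $1/f$: slow
rhythms are analysed with long windows, fast activity with short ones,
while the phase stays absolutely referenced as in the short-time
Fourier transform. For a 4-s, 1024-point epoch at 256 Hz analysed over
1--128 Hz the result is a 128 x 1024 complex matrix — one row per
integer frequency, one column per sample.

Discretisation choices (the printed matrix shape pins down the grid,
but not the edge handling, so these are package decisions):

* **Grid.** One row per integer Hz; frequency $f$ sits on DFT bin
  $f\,n/f_s$ (bin 4$f$ for the 4-s epoch). Every sample index is a
  $\tau$ column. Zero and negative frequencies are excluded.
* **Edges.** The window is periodised (circular convolution). The
  direct evaluation of the defining sum (`stockwell_direct()`) and the
  FFT-accelerated form (`stockwell()`) share this periodisation, so
  they agree to machine precision rather than merely asymptotically —
  the direct form is the test oracle for the fast one.
* **Normalisation.** The window carries the $\Delta t = 1/f_s$ factor,
  giving it unit mass; consequently summing any frequency row over all
  columns reproduces the unnormalised DFT coefficient of the segment
  at that frequency (the collapse property), which the tests assert at
  $10^{-6}$.
* All arithmetic is double precision.

The per-epoch band-energy kernel (50 voice transforms per channel per
epoch) runs in compiled code with a radix-2 FFT for power-of-two epoch
lengths; `stockwell()`/`compress_subbands()` in R are the reference
path, and the test suite checks both routes against each other.

## Rhythm-block compression

Within 1--50 Hz (above power-line interference concerns, and covering
the 3--30 Hz range where ictal rhythms concentrate), the matrix is
divided into the six clinical rhythm bands — delta (1--4), theta
(4--8), alpha (8--12), beta (12--30), gamma1 (30--40), gamma2
(40--50 Hz) — and the 4-s axis into two 2-s halves. Summing $|S|^2$
over each of the 12 units gives a 12-value vector per channel and an
$n \times 12$ feature map per epoch. The printed band boundaries
overlap at their endpoints; the package disambiguates them as
half-open $[low, high)$ intervals on the integer-Hz grid (delta = rows
1--3, ..., gamma2 = rows 40--49), which tiles 1--50 Hz exactly: the 12
units partition the total band energy, a property the tests assert.

Whether the band energies are transformed before classification is not
specified by the source description; the package's default
(`normalize_features()`) is $\log_{10}(1+x)$ followed by per-feature
z-scoring with training-set statistics, because raw band energies span
several decades between background and ictal activity and the
compressed scale keeps the small encoder's optimisation stable. Both
steps are optional (`log = FALSE`, `method = "none"`).

## The channel-token Transformer encoder

Each channel's 12-value vector is one token ("channel embedding"); the
token width equals the model width, $d_{model} = 12$, so there is no
input projection. No positional encoding is applied: channel identity
is deliberately not positional, which makes the network equivariant
under channel permutation. Each of $L = 6$ layers applies multi-head
self-attention with $h = 3$ heads and $d_k = d_v = d_{model}/h = 4$
(enforced at construction):

$$\mathrm{SA}(S) = \mathrm{softmax}\!\left(QK^\top/\sqrt{d_k}\right)V,
\qquad Q = SW_Q,\; K = SW_K,\; V = SW_V,$$

with the $h$ head outputs concatenated through $W_O$. The layer update
is implemented exactly in the published residual form

$$y_i = \mathrm{MSA}(\mathrm{LN}(S_{i-1})), \qquad
  S_i = S_{i-1} + y_i + \mathrm{MLP}(\mathrm{LN}(y_i)),$$

which differs from the conventional pre-LN block (where the MLP
branch is fed from the accumulated state, not from $y_i$ alone);
`encoder_config(block = "standard")` switches to the conventional
block for ablation. The attention logits are scaled by $\sqrt{d_k}$ —
the source prints $d_k$, but cites the original Transformer whose
mechanism is $\sqrt{d_k}$; we follow the citation. After the last
layer the state is max-pooled over channels (again
permutation-invariant) and passed through a one-hidden-layer MLP and a
softmax over (non-seizure, seizure).

Unspecified pieces, fixed as package defaults and exposed in
`encoder_config()`: per-layer feed-forward width 48 ($4\,d_{model}$,
the conventional ratio), head hidden width 32, dropout 0 (the model is
tiny — 11,570 parameters — and the tests prize bit-exact determinism),
Adam with learning rate $10^{-3}$, minibatch 32, at most 200 epochs
with early stopping (patience 10 on a 20% validation split, minimum
improvement $10^{-4}$ in validation cross-entropy). The forward and
backward passes are written directly in R (the parameter count is
asserted against its closed form, and the gradients against numerical
differentiation).

Interpretability: summing the final layer's $h$ attention matrices and
averaging each column yields one nonnegative weight per channel
(`channel_attention()`), indicating which electrodes the model relies
on.

## Post-processing

The per-epoch probability stream is converted to events by four stages
in fixed order: centered moving-average filter, threshold
(`>=` convention), collar extension of each positive run, and K-of-N
discrimination in which a sliding window of $N$ epochs is marked
seizure in full whenever at least $K$ of its epochs are positive
(published operating point $K=5$, $N=10$, i.e. a 40-s window;
overlapping triggered windows union). The MAF width (3 epochs), collar
(1 epoch per side) and threshold (0.5) are not published; they are
package defaults, all configurable. Edge handling: the MAF truncates
its window at the trace boundaries; the collar clips at the bounds.

## Evaluation

Segment-based: accuracy, sensitivity, specificity, precision (percent;
a zero denominator yields `NA`, never 0) and AUC computed as the
Mann-Whitney pairwise statistic with ties counted one half.
Event-based: a predicted event overlapping an annotated
[onset, offset] interval counts that seizure as detected. Any overlap
suffices (the verbal definition does not pin down partial-overlap
handling); each annotated seizure is credited at most once; one
prediction spanning two annotations credits both; latency is the first
correct prediction time minus onset, clamped at zero; predictions
overlapping no annotation are false alarms, reported per hour (FDR).

## Synthetic study conditions

The generator (`generate_eeg_record()`) emulates the structure of the
CHB-MIT recordings: 23 bipolar channels at 256 Hz, background
1/f-weighted noise at 30 uV RMS, and sparse ictal episodes in which
rhythmic 3--30 Hz oscillations (a 3--12 Hz fundamental plus its
harmonic, raised-cosine ramps, per-channel phase jitter and gain
variation) are added at 3x the background RMS — an amplitude ratio
chosen once to reflect the markedly higher ictal amplitudes of
clinical recordings. Segmentation follows the published protocol:
ictal windows with 50% overlap, interictal without, boundary-straddling
windows discarded (their handling is unspecified in the source; a
window of mixed provenance has no clean label), balanced subsampling
of interictal windows, seeded 3:1 train/test split.

What the generator does *not* emulate: artifacts (eye blinks, EMG,
electrode pops), inter-patient morphology differences, evolving
seizure frequency dynamics, or channel-specific seizure foci. Passing
the end-to-end tests therefore demonstrates that the pipeline's
machinery — features, classifier, post-processing, scoring — recovers
a separable ictal signature under controlled conditions; it does not
certify clinical performance, which on real data is limited by exactly
the phenomena the generator omits.

Problem sizes for the end-to-end checks, chosen as the smallest that
exercise every stage meaningfully: a one-hour training record with 8
seizures (about 330 balanced segments) and an independent two-hour
test record with 6 seizures, all 23 channels.

## Numerical and degenerate-input choices

* Training seeds drive initialisation (Glorot uniform), the validation
  split, shuffling and dropout; the caller's RNG state is saved and
  restored.
* Zero-variance features clamp their scale to 1 with a warning.
* Max-pool backward routes gradient to the first maximising channel on
  ties.
* Non-finite activations abort with the offending layer index;
  non-finite samples are rejected at validation.
* A validation split that ends up single-class falls back to
  monitoring training loss.
* EDF export quantises to 16 bits with a per-channel symmetric
  physical range; round-trip error is bounded by one quantisation
  step.

## Known limitations

* The direct S-transform oracle is $O(Fn^2)$ and intended for tests,
  not production use.
* Training is CPU-bound R; the intended regime is the published one —
  small patient-specific models on hundreds of segments — not
  large-scale training.
* Event scoring implements any-overlap crediting only, not OVLP/TAES
  variants from other evaluation traditions.
* Non-256 Hz records are accepted throughout, but no resampler is
  included; `read_edf(expect_fs = )` can enforce a rate.
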