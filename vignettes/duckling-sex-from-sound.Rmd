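---
title: "Identifying duckling sex from vocalisations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying duckling sex from vocalisations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drakecall)
```

## The problem

Commercial duck production rears males and females separately, because the
sexes grow at different rates and have different nutritional needs. The
standard way to sex day-old ducklings — manual vent examination — is slow,
requires trained staff and stresses the birds. Day-old ducklings, however,
vocalise constantly, and experienced breeders can sex them by ear: the two
sexes differ in the *shape* of their call's frequency contour even though
both call in the same band around 2.5 kHz. Female calls hold a stable
fundamental and rise slightly at the end; male calls start high and decay
onto a stable plateau.

`drakecall` implements a complete automatic pipeline built on that cue:

1. read mono 16-bit PCM WAV recordings (44.1 kHz), one bird per file;
2. pre-emphasise, cut into 25 ms frames every 10 ms;
3. find the calls with zero-product endpoint detection (energy × zero-crossing
   rate, dual threshold);
4. convert each voiced frame into a 36-dimensional MFCC + Δ + ΔΔ vector;
5. classify every frame with a small neural network (three architectures are
   provided);
6. call the bird's sex by majority vote over its frames, and score the result
   with confusion-matrix metrics.

Because no public corpus of labelled duckling recordings exists, the package
also ships a seeded synthetic-call generator that emulates the documented
contour shapes with per-bird variation; every quantitative claim the test
suite makes is made on that synthetic corpus, and the limits of that are
discussed at the end.

## Signal chain

### Pre-emphasis

High frequencies lose energy in air faster than lows, so the raw signal is
sharpened with the first-order filter

$$y(n) = x(n) - \alpha\,x(n-1), \qquad \alpha = 0.95,$$

with $y(0) = x(0)$ (the filter has no history before the first sample, and we
do not invent one). $\alpha$ is configurable in $[0, 1)$; 0.95 is the
conventional speech value and suits the ~2.5 kHz calls well.

### Framing and windowing

Duckling calls are quasi-stationary over 10–30 ms, so analysis uses 25 ms
frames ($L = \lfloor 0.025 \cdot 44100\rfloor = 1102$ samples; the floor makes
the non-integer sample count deterministic) with a 10 ms hop — the standard
short-time compromise between temporal resolution and per-frame stability.
Frames destined for spectral analysis are tapered with the Hamming window

$$w(n) = 0.54 - 0.46\cos\!\left(\tfrac{2\pi n}{N-1}\right), \quad 0 \le n \le N-1,$$

which suppresses spectral leakage at the frame edges. Framing happens on the
pre-emphasised signal (the pipeline order is pre-emphasis → framing →
endpoint detection → windowing → spectrum).

### Endpoint detection

Per unwindowed frame $i$ the detector computes short-term energy
$E(i) = \sum_n x_i^2(n)$ and zero-crossing rate
$Z(i) = \tfrac12\sum_n |\mathrm{sgn}\,x_i(n) - \mathrm{sgn}\,x_i(n-1)|$ with
$\mathrm{sgn}(x) = 1$ for $x \ge 0$ and $-1$ otherwise, and their product
$K(i) = E(i)\,Z(i)$ — the *zero-product* statistic. A call frame is both loud
(high $E$) and high-pitched (high $Z$), so $K$ separates calls from
low-frequency cage noise far better than either factor alone.

Two details are deliberate:

* detection runs on **unwindowed** frames — the Hamming taper would crush
  the frame-edge crossings $Z$ counts;
* each frame is treated as an independent unit: the $n = 0$ term of $Z$ uses
  $x_i(-1) \equiv x_i(0)$ and contributes nothing, rather than reaching into
  the previous frame.

Segmentation is hysteresis thresholding: thresholds are fractions of the
per-recording maximum ($T_\text{high} = 0.10\,\max K$ seeds a segment,
$T_\text{low} = 0.02\,\max K$ extends it), so they are scale-invariant and
adapt to recording gain; both fractions are exposed as configuration knobs.
Segments closer than `merge_gap = 5` frames are merged and segments shorter
than `min_frames = 10` (~115 ms) are discarded — long enough to reject
impulsive stepping noise, short enough to keep every plausible call (the
generator's shortest call, 150 ms, spans ~14 frames). Relative (per-recording)
rather than global thresholds were chosen because recordings of different
birds differ in gain; nothing in the method requires comparability of $K$
across files.

### MFCC features

Each voiced, windowed frame is zero-padded to $N_\text{FFT} = 2048$ (the next
power of two above 1102), transformed, and squared to spectral line energies
$E(i,k) = |X(i,k)|^2$. A bank of $M = 26$ triangular filters, equally spaced
on the Mel scale $\mathrm{mel}(f) = 2595\log_{10}(1 + f/700)$ between 0 Hz and
Nyquist, pools these into band energies
$S(i,m) = \sum_k E(i,k) H_m(k)$, floored at $\varepsilon = 10^{-10}$ so the
log of a silent frame stays finite. The cepstrum is the cosine transform of
the log energies,

$$c(i,n) = \sqrt{\tfrac{2}{M}} \sum_{m=0}^{M-1} \log S(i,m)\,
  \cos\!\left(\tfrac{\pi n (2m-1)}{2M}\right), \qquad n = 1\ldots 12,$$

keeping 12 coefficients and dropping $n = 0$ (overall log-energy, which mostly
encodes recording gain). Two conventions for the cosine argument circulate —
$(2m-1)$ and the textbook DCT-II $(2m+1)$ with $m$ from 0; the package
implements both (`dctPhase = "shifted"` / `"standard"`, default shifted) and
the test suite pins each against an independent double-loop oracle. The
$\sqrt{2/M}$ scale is the standard orthonormalising factor. 26 filters and a
2048-point FFT are conventional for 44.1 kHz audio; both are configurable.

Temporal dynamics are added as regression deltas with half-window 2,

$$d_t = \frac{\sum_{\tau=1}^{2} \tau\,(c_{t+\tau} - c_{t-\tau})}
  {2\sum_{\tau=1}^{2}\tau^2},$$

with edge frames replicated, and delta-deltas as the delta of the delta.
Deltas are computed *within* each voiced segment, so dynamics never straddle
a silence. The result is the fixed 36-column layout
$[c_{1..12}\,|\,\Delta_{1..12}\,|\,\Delta\Delta_{1..12}]$. The delta columns
are what make the sexes separable even where their static spectra overlap:
a male's falling onset and a female's terminal rise are slope features.

Features are z-scored per column using statistics of the training frames
only; validation and test material receives the identical affine transform
(the standard leakage guard, asserted in the tests). Standard deviations are
floored at $10^{-8}$ so constant columns map to zero.

### Classifiers

Three frame-level architectures are provided, all ending in a 2-way softmax
with male as the positive class, all trained with Adam (learning rate
$10^{-3}$), minibatch 256, cross-entropy loss, default 100 epochs:

| name | structure | dropout |
|------|-----------|---------|
| `bpnn` | dense 18–9–4, ReLU | none |
| `dnn`  | dense 48–32–16–8, ReLU | 0.1 per layer |
| `cnn`  | conv 3×3: 128–128–64–32 channels, ReLU; flatten → dense(2) | 0.3 per block |

The convolutional net consumes each 36-dim frame reshaped to a 6×6
single-channel grid (stride 1, zero padding, no pooling). Feeding a
*per-frame vector* to 2-D convolutions is under-determined; the 6×6 reshape
preserves the single frame as the classification unit, and an optional
`context_window` mode instead stacks $w$ consecutive frames into a $w\times36$
map for users who want genuine temporal context. Dropout follows every
convolution block; whether it should follow only the last is not settled, so
the rate is configurable per spec. Dropout is active only
during training — two inference passes are bit-identical, which the tests
assert. All randomness (initialisation, shuffling, dropout masks, splits)
is derived from explicit seeds, so a run is reproducible end to end.

The engine behind these models (dense and im2col convolution layers on BLAS
matrix products, softmax/cross-entropy, Adam) is part of the package, written
against closed-form gradient checks and the separable-toy sanity suite.

### From frames to birds, and scoring

A bird's sex is decided by majority vote over its frames' argmax labels; the
male vote fraction is recorded as the per-bird confidence. An exact 50/50 tie
is called male — an arbitrary but fixed and documented rule, so results are
deterministic (`method = "mean_prob"` averages probabilities instead).
Scoring uses the confusion matrix with male positive: accuracy, recall
(= male recognition rate), specificity (= female recognition rate),
precision, and F1 (harmonic mean of precision and recall). Splitting
(default 120 birds/sex train, 30/sex test) and 5-fold cross-validation are
stratified **at the bird level**: a bird's frames never appear on both sides
of any split. Balanced training sets draw exactly 3000 frames per bird by
default — without replacement when the bird has enough voiced frames, with
replacement (and a warning) when it does not.

## The synthetic corpus

The generator (`synthCall`, `synthRecording`, `synthDataset`) emulates the
documented qualitative structure of duckling calls:

* **female**: stable fundamental near 2500 Hz, linear upward glide of
  150–300 Hz over the final 15% of the call;
* **male**: onset 300–500 Hz above the plateau, exponential decay onto it
  (time constant 15% of the call length); plateau default 2300 Hz;
* 4 harmonics with $1/h$ rolloff, phase-continuous additive synthesis,
  linear 15 ms attack / 20 ms decay envelope, peak 0.8;
* calls 0.15–0.4 s long, separated by 0.15–0.5 s silences;
* background: band-limited noise below 1 kHz (the stepping/cage noise that
  dominates real rearing-pen recordings) at a configurable SNR (default
  20 dB), plus an optional faint broadband floor; alarm (2800–2900 Hz) and
  distress (>3000 Hz) call modes exist for endpoint-detection stress tests.

Choices worth flagging. The absolute male/female fundamentals are *synthetic
conventions*: the literature documents the ~2.5 kHz band and the contour
shapes but not sex-specific ranges. The 200 Hz plateau separation with
per-bird jitter $\sigma = 50$ Hz (drawn once per bird) leaves the sexes
slightly overlapping — roughly 4σ apart — so the classification task is
learnable but not saturated, and contour dynamics still matter. The
background is deliberately *not* white: broadband noise at equal power would
be unrepresentative of a rearing pen, and after pre-emphasis (which
amplifies it while attenuating the 2.5 kHz band) it would disable any
energy-based voice-activity detector, this one included — a physical
limitation of the zero-product statistic, not an implementation artefact.

What passing tests on this corpus does **not** show: robustness to
reverberation, overlapping birds, recorder compression, or real duckling
vocal variety (syrinx physiology is not modelled). Synthetic results bound
the pipeline's correctness, not its field performance.

## Numerical and scale choices

* Frame counts follow $1 + \lfloor (n-L)/\text{hop}\rfloor$; trailing samples
  are dropped.
* FFTs use the stock radix implementation; the test suite checks the full
  front-end against a naive basis-matrix DFT + explicit triangle sums +
  double-loop DCT at $10^{-8}$ relative tolerance.
* Mel boundary bins use $\lfloor (N_\text{FFT}+1) f / f_s \rfloor$; a
  degenerate triangle (equal adjacent bins, only possible at coarse FFT
  sizes) keeps a unit peak at its centre bin.
* All-zero activity ($\max K = 0$) yields an empty segment list, not an
  error; birds with no voiced segments are excluded from corpora with a
  warning listing their IDs.
* Problem sizes in the shipped tests and acceptance script are chosen for a
  single desktop CPU: the end-to-end benchmark trains the convolutional net
  for 12 epochs on 120 frames/bird from 40 training birds (it converges in
  3–5 epochs on this task), the bookkeeping corpus uses 2 calls/bird, and
  toy-sanity training stops early once training accuracy reaches 100%. At
  these scales the full suite runs in minutes; all sizes are arguments, so
  larger studies are one call away.

## Known limitations

* The WAV codec is deliberately minimal: 16-bit PCM mono only; stereo and
  other encodings are rejected, never silently converted. Off-rate input is
  rejected unless resampling is explicitly requested.
* Endpoint thresholds are per-recording fractions of $\max K$; a recording
  consisting *only* of noise will still seed segments at the noise maximum
  unless `min_frames` filters them — the intended guard in practice.
* The classifiers are frame-level; no temporal model (HMM/RNN) links frames,
  and the majority vote treats frames as exchangeable.
* Per-bird decisions need enough voiced frames for the vote to stabilise;
  with very few frames the vote fraction is a coarse statistic.
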