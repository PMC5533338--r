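---
title: "Detecting syllables in stereotyped birdsong: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting syllables in stereotyped birdsong: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adult male zebra finches sing a short, highly stereotyped motif hundreds of
times a day. Closed-loop experiments — song-contingent stimulation, noise
feedback, pitch-shift paradigms — need a detector that fires at a chosen
instant of that motif while the bird is singing, with low latency, low
trial-to-trial timing variability (jitter), and false-positive rates low
enough to survive hours of cage noise, calls and wing flaps. `syldetect`
implements such a detector as an offline-trainable model plus a simulated
streaming runtime, and quantifies it exactly: per-frame accuracy, signed
detection latency, and jitter defined as the standard deviation of latency.

## The detection model

**Spectral front end.** Audio at sample rate $1/t_{\mathrm{sample}}$ is
consumed through a circular buffer of the most recent $N$ samples
($N = 256$ by default). Every *hop* new samples a Hamming window is applied
and the squared magnitudes of the one-sided FFT bins whose centre
frequencies lie in a fixed band (1–8 kHz by default) are appended to a
second ring. The hop is the requested frame interval quantized to whole
samples: at 44.1 kHz a requested 1.5 ms becomes
$\mathrm{round}(66.15) = 66$ samples, an effective interval of
$t_{\mathrm{fft}} = 66/44.1 \approx 1.4966$ ms. All timing downstream —
recognition-window depth, frame timestamps, de-bounce clocks — uses this
effective interval, and every `frame_config()` prints the resolved hop so
the quantization is never invisible. Frames are timestamped by their
*newest* sample: a frame exists only once its last sample has arrived, which
is what makes latency measurements causal, and the first frame is emitted
only when a full buffer of real samples exists (no zero-padded warm-up).

**Recognition region.** At each frame the classifier sees the last
$|T| = \mathrm{round}(50\,\mathrm{ms}/t_{\mathrm{fft}})$ frames of the
band-limited spectrogram — a $|F| \times |T|$ rectangle reshaped into a
vector $\xi_t$ of length $|F||T|$ (1353 at the defaults), ordered as $|T|$
frame blocks from oldest to newest.

**Two normalizations.** Each window is z-scored over its own elements
($\hat\xi_t$), removing level differences from bird position and gain;
exactly constant windows (digital silence) map to the zero vector, the only
scale-free choice, which keeps silence maximally distinct from song. Then
each element is z-scored across the training set — each row of the training
matrix $\Xi$ — giving $\check\xi_t$; that row transform is stored in the
model and applied unchanged at run time. Both stages use the sample
($n-1$) SD convention, and the per-row SD is floored at $10^{-8}$ so rows
constant across a corpus cannot divide by zero. The streaming detector
normalizes its single window by calling the same column-matrix code path as
training, so the two pipelines agree summation-for-summation, bit for bit.

**Network.** A two-layer perceptron with a linear output layer:
$$y_t = W_1 \tanh(W_0 \check\xi_t + b_0) + b_1,$$
with 4 hidden units per target syllable by default — for stereotyped song a
very small hidden layer is the right accuracy/training-speed compromise.
Training minimizes mean squared error against smoothed targets, full batch,
with analytic gradients driven by `stats::optim`'s L-BFGS-B in rounds of 40
iterations; after each round the MSE on a held-aside 20% validation split is
checked, the best-validation parameters are retained, and optimization stops
after 5 stale rounds or 400 total iterations. The split is stratified so
positive-target columns appear on both sides. Everything is deterministic
given the training seed; run-to-run variability across seeds is real (it
reflects weight initialization) and deliberately exposed.

**Smoothed targets.** A strict 0/1 target would ask the network to call two
practically identical frames opposite classes, so each canonical time $t^*$
is spread by a Gaussian kernel of SD 2 ms, truncated at $\pm 3\sigma$. The
kernel is centred *causally*: on the end time of the first frame at or after
$t^*$, never on an earlier frame, so the network is not trained to announce
an event before the audio through $t^*$ has been heard. With an on-grid
centre, the peak frame carries exactly 1. (Centring on the nearest frame —
which can precede $t^*$ — would bias the detector half a frame early; the
causal convention instead yields the small positive latency one expects of a
detector that must wait for its evidence.)

**Thresholds.** After training, one detection threshold per syllable
minimizes $\mathrm{FP}(\theta) + C_n\,\mathrm{FN}(\theta)$ over the full
training corpus, with $C_n = 1$ and an acceptance half-window
$\Delta t = 10$ ms: an event is detected if any frame with output above
$\theta$ falls within $t^* \pm \Delta t$; every above-threshold frame inside
no acceptance window is one false-positive frame. The cost is piecewise
constant in $\theta$, changing only at observed output values, so the grid
of midpoints between consecutive sorted unique outputs (plus one point above
the maximum) is an exact linear search, not an approximation — the test
suite verifies equality against a dense brute-force scan. Ties are broken
toward the largest minimizing threshold: large stretches of the cost surface
are flat, and the high end of a flat stretch is conservative against false
positives on unseen data. When acceptance windows overlap (targets closer
than $2\Delta t$), one frame may satisfy at most one event, assigned
greedily in time order; the optimizer then falls back from its sorted-counts
fast path to exact per-candidate counting.

**Streaming and de-bouncing.** The runtime consumes audio in arbitrary
chunks (8–32 samples emulates realistic audio-hardware buffers); the event
stream is invariant to the chunking, which the tests check exactly. A
detection is an *upward* crossing — previous output at or below $\theta$,
current above — after which the syllable is suppressed for 100 ms, counted
in effective-interval units rounded up; outputs are still computed during
suppression, only emission is withheld, and suppressed crossings do not
re-arm the clock. Accuracy is always measured on the raw, un-de-bounced
outputs.

## Evaluation definitions

Per-frame accuracy reports $100\cdot\mathrm{TP}/n_{\mathrm{events}}$ and
$100\cdot\mathrm{FP}/n_{\mathrm{negative\ frames}}$, the denominator being
all frames outside every acceptance window — a definition that stays
meaningful on unsegmented streams of calls and cage noise. Latency is the
signed offset from the canonical time to the trigger (canonical 200 ms,
trigger 203 ms → latency 3 ms); negative latencies are legitimate, because
output rises toward its peak and can cross threshold just before it. Jitter
is the sample SD of matched latencies; undetected events contribute none.
The *ideal detector* is the offline zero-buffer path: frames at exact hop
positions, trigger at the first above-threshold frame in the window. Its
latency and jitter reflect only the FFT size, the hop, and the target-kernel
width — a bound on any live implementation of the same model. Evaluation
requires a corpus disjoint from training (asserted via corpus ids).

## What the synthetic corpora emulate

No public corpus of aligned songs ships with the package, so the generator
is first-class, tested code:

* **Songs** are a fixed motif (harmonic stack, silent gaps, band-limited
  noise burst, downward sweep in the demonstration spec) rendered once per
  corpus, then per song: an onset shift (Gaussian, SD 2 ms by default,
  quantized to whole samples), a multiplicative gain (SD 10%), and white
  noise at 30 dB SNR. Canonical times are the nominal targets shifted by
  each song's realized onset shift — emulating the aligned, equal-length
  clips an offline alignment pipeline produces.
* **Noise-burst syllables are "frozen noise"**: their realization is a
  deterministic function of the syllable parameters, not of the corpus
  seed. A real bird's noisy syllable is a stereotyped motor pattern, the
  same acoustic object on every rendition and in every recording session; a
  held-out corpus must therefore contain the *same* syllable, not a fresh
  white-noise draw.
* **Non-song clips** cycle through silence, cage-like broadband noise,
  band-limited noise bursts and short call-like harmonic tones, at the 1:1
  song:non-song ratio that suffices in practice; none contains the motif.
* **The δ-syllable corpus** isolates pipeline timing from acoustics: each
  song is one full-scale unit impulse in a silent clip, the canonical target
  5 ms after it, with the impulse position stepped across one frame hop so
  that the detector experiences every frame phase. Full scale and digital
  silence maximize determinism; a faint noise floor is available but off by
  default.

What passing tests on these corpora do *not* show: robustness to real
recording-chain variation (microphone placement, room reverberation),
directed-vs-undirected song differences, gradual vocal drift during
feedback experiments, or imperfect upstream alignment. The synthetic
corpus is more stereotyped than a real bird; real-data accuracy will be
bounded by those factors, not by the pipeline mechanics tested here.

## Numerical and design choices

* Hop rounding is half-away-from-zero (`round_half_away(4.5) = 5`); any
  nearest-integer rule is consistent with the quantization arithmetic, but
  half-cases must be fixed and documented.
* Band-bin selection is inclusive of both band edges.
* Power spectra carry no $1/N$ or window-gain normalization — the
  per-window z-scoring makes absolute scale irrelevant; what matters is that
  training and runtime are identical, which is enforced structurally.
* Model files are JSON with numeric payloads at 17 significant digits, the
  precision that round-trips IEEE doubles exactly; save → load → forward is
  bit-for-bit, and files carry a format version checked on load.
* WAV I/O is implemented in-package (RIFF PCM 16/24-bit and IEEE float
  32/64-bit); corpora are written as float64 by default so that generated
  samples round-trip losslessly.
* The optimizer is a full-batch quasi-Newton method over hand-derived
  gradients (verified against finite differences); any competent gradient
  method is equivalent here — the contribution is the pipeline, not the
  optimizer — and the trainer's identity is recorded in the model file.

## Problem sizes

The package's own evaluation uses 200 songs + 200 non-song clips for
training and a held-out corpus from a different seed for scoring — the
lower end of what yields acceptable results for this architecture, chosen
so the full pipeline (including the δ-corpus timing characterization at
its default 1.5 ms frame interval and the synthetic-song recovery run)
trains in minutes on one core. Larger corpora (the 1000/1000 regime) only
improve the statistics. The measured behaviour at these sizes: held-out
δ-corpus accuracy of 100% TP / 0% FP, ideal δ latency ≈ 0.7 ms with jitter
≈ 0.43 ms (close to the frame-quantization floor
$t_{\mathrm{fft}}/\sqrt{12} \approx 0.43$ ms), and synthetic-song recovery
at 100% TP / 0% FP with jitter well under 1 ms — all recomputed, not
asserted, by the test suite and `scripts/acceptance.R`.

## Known limitations

* Mono, single-rate processing; resampling is out of scope and rate
  mismatches are refused.
* The streaming loop is a faithful software simulation; OS scheduling,
  audio-hardware buffers and trigger-output latency are outside the model
  (the ideal-detector numbers are exactly the part of timing that survives
  those effects).
* One detector per frame configuration: models refuse audio at a different
  sample rate rather than adapting.
* `simulate()`/`residuals()` methods are not provided: a thresholded
  streaming detector has no natural residual structure; the evaluation
  module's accuracy and timing reports are the model-criticism tools.
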