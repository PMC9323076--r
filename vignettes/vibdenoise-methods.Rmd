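---
title: "Methods: waveform-domain enhancement of borer vibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform-domain enhancement of borer vibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and the model

Substrate-borne pulses from wood-boring larvae are sparse, impulsive, and
weak; field recordings bury them under wind, bird, babble, and
instrumentation noise at SNRs around −10 dB. `vibdenoise` maps the noisy
waveform directly to an estimate of the clean waveform — no spectrogram
mask, no phase reconstruction — with a convolutional encoder/decoder and a
recurrent bottleneck.

**Encoder.** `L` layers. Layer `i` applies a strided 1-D convolution
(kernel `K`, stride `S`, `2^(i-1)·Ch` output channels), ReLU, a 1×1
convolution doubling the channels, and a GLU halving them again. The latent
therefore has `2^(L-1)·Ch` channels and roughly `S^L` times fewer time
steps than the input. With the full-size defaults (`L = 5`, `K = 8`,
`S = 4`, `Ch = 48`) the latent has 768 channels.

**Bottleneck.** A stack of SRU++ layers run over the latent time sequence.
The SRU recurrence uses elementwise state products, so everything except a
single scan over time is batched matrix algebra; SRU++ replaces the input
projection with single-head scaled-dot-product self-attention
(`Q = W_q X`, `K = W_k Q`, `V = W_v Q`, attention dimension `d′`) followed
by `W_o · layernorm(Q + α·A)`. The residual scalar `α` starts at zero, so a
freshly initialized layer is a plain linear projection whose output is
provably independent of `W_k` and `W_v` — a property the test suite asserts
bitwise. Plain SRU and a 2-layer LSTM are selectable baselines.

**Decoder.** Mirrors the encoder: skip addition from encoder layer
`L−i+1`, 1×1 channel-doubling convolution, GLU, transposed convolution
(`K`, `S`), ReLU — except the last layer, which emits a single channel with
no activation so the output can take both signs.

**Assumptions.** The model is unidirectional in time but not causal (the
attention sees the whole clip); normalization is per clip; signals are mono.
Whether the original formulation normalized per clip or per batch, and
whether its recurrence was bidirectional, is not documented — per-clip and
unidirectional are this package's choices.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `L` / `K` / `S` / `Ch` | 5 / 8 / 4 / 48 | — | full-size architecture; `K > S` so receptive fields overlap |
| `seq_layers` | 2 | — | the deployment-oriented depth: close to best quality at a fraction of the cost of deeper stacks |
| `attention_dim` (`d′`) | latent/4 | — | only constrained to be "much smaller than the input"; a quarter is this package's default, recorded in config |
| `normalize` / `floor_eps` | TRUE / 1e-3 | — | per-clip standard-deviation normalization; the floor guards silent clips |
| learning rate | 3e-4 | — | Adam; `β₁ = 0.9`, `β₂ = 0.999` (only the rate is prescribed; the moments are Adam defaults) |
| epochs / eval cadence | 150 / 5 | epochs | full-protocol schedule; the desk-scale preset shortens it |
| mixing SNR | −10 | dB | the low-SNR regime the task targets |
| `train_fraction` | 0.94 | — | 94/6 split by clean-clip identity, so no clean clip leaks across splits |
| segment length | 5 | s | recordings are cut into 5-s segments; the trailing remainder is dropped |
| loss | log-cosh | — | behaves like L2 near zero error and L1 far from it; the best performer among the six implemented |
| SegSNR frame / clamp | 1024 samples / [−10, 35] dB | — | standard segmental-measure practice; the frame length is not prescribed by the source material |
| LPC order | 16 | — | suited to 44.1 kHz frames; configurable |

## What the synthetic generator emulates — and what it does not

No public recordings of the study system exist, so the package ships a
generator that reproduces the *spectral* structure reported for the real
signals:

* **Pulse trains** — exponentially damped sinusoid bursts (decay constant
  4 ms, pulse length 20 ms) at carriers defaulting to 1.8 kHz and 17 kHz,
  placed at Poisson onset times (larval gnawing is aperiodic; a
  jittered-regular grid is available). Pulse rate and duration are nowhere
  quantified for these larvae; the defaults (6 pulses/s) are engineering
  placeholders, not biological claims.
* **Noise scenes** — wind as low-pass noise (≤ 5 kHz) with slow (< 2 Hz)
  random amplitude modulation; birds as 50–300 ms linear FM sweeps inside
  1.5–4 kHz; babble as band-limited noise below 1.4 kHz with syllabic-rate
  modulation; floor as white noise. Band edges scale down when the Nyquist
  frequency requires it.

Band limiting uses brick-wall FFT filters: exact energy localization
matters more here than realizable filter responses, and the test suite
integrates FFT band energy to assert that each component keeps ≥ 90% of its
energy in band.

The generator does **not** model wood propagation (dispersion, resonances,
attenuation), overlapping pulse statistics of real colonies, or recording
chain nonlinearities. Passing tests on synthetic data therefore demonstrate
that the pipeline, gradients, and optimization work and that the
architecture can learn band-selective denoising — they do not certify field
performance on real trunks.

## Numerical choices

* **Mixing** solves the gain in closed form,
  `g = sqrt((Σc²/Σn²)·10^(−SNR/10))`, so the measured SNR matches the
  request to well under 0.01 dB; pairs are jointly rescaled before 16-bit
  writing so quantization, not clipping, is the only round-trip error.
* **The SNR/SegSNR error term is the squared difference** `(s − ŝ)²`. A
  literal difference of squares `s² − ŝ²` is not an error energy (it can be
  negative and breaks the logarithm); a regression test pins this choice.
* **Spectral subtraction** uses 1024-sample Hann frames at 50% overlap with
  noisy-phase resynthesis by plain overlap-add — the periodic Hann window at
  half-window hop satisfies constant overlap-add exactly, and dividing by
  the summed squared window instead would amplify modified frames where the
  window vanishes.
* **log-cosh** is computed as `|e| − log 2 + log1p(exp(−2|e|))`; the naive
  form overflows beyond |e| ≈ 350.
* **Softmax** subtracts the row maximum; **Levinson–Durbin** inflates the
  zero-lag autocorrelation by 1e-9 to regularize ill-conditioned frames and
  is tested to 1e-8 against a direct Toeplitz solve.
* **Ties and degenerate inputs**: energy selection keeps the
  earlier-indexed clip on ties; segmentation drops the trailing remainder;
  all-zero LLR frames are skipped with a warning; `l1_snr` on identical
  signals is an error (log of zero L1); the SNR cap is ±60 dB so no
  NaN/Inf escapes the metrics API.
* **Length handling**: inputs are zero-padded at the end to the smallest
  admissible length (every encoder stage ≥ 1 step and the mirrored decoder
  returning at least the input length), and the decoder output is trimmed
  back. Because the encoder's floor division can shorten the returning
  stream relative to a skip, skip and stream are added over their common
  prefix.
* **Initialization** is Kaiming-style fan-in for convolutions and uniform
  `±sqrt(1/fan_in)` for recurrent weights, with zero biases and `α = 0`;
  the scheme is recorded in the model object so it can be swapped.
* **Gradients**: every backward pass (convolutions, transposed
  convolutions, GLU, layer norm, attention, SRU/SRU++/LSTM recurrences, all
  six losses including the multi-resolution STFT term) is hand-derived and
  checked against central finite differences at relative tolerance 1e-4 or
  better in the test suite.

## Problem sizes

The shipped desk-scale preset (`tiny_preset()`) uses `L = 3`, `Ch = 8`, a
2-layer SRU++ bottleneck, and 1-second clips at 8 kHz; its benchmark
dataset is 200 synthetic pairs mixed at −10 dB with babble-plus-floor noise
chosen spectrally disjoint from the pulse carriers (1.8 and 3.4 kHz at this
rate), which makes the denoising task solvable in principle and lets a
10-epoch CPU run demonstrate learning. These sizes are the package's chosen
benchmark conditions; the full-size preset (`full_preset()`) keeps the
5-layer, 48-channel, 44.1 kHz configuration, whose training is GPU-scale
work and whose CPU use here is forward-pass only. Batch size defaults to 8
at desk scale — published batch sizes in this literature (56–64) are tied
to multi-GPU memory and are not meaningful on one CPU.

## Known limitations

* Training is single-threaded R; it is fast enough for the desk-scale
  preset (minutes) but not for full-scale training.
* No causal/streaming variant: enhancement needs the whole clip.
* The LSTM baseline shares the training loop but has received less tuning
  attention than the SRU++ path.
* Checkpoints are R serializations (`saveRDS`), not a cross-language
  format.
* The synthetic benchmark's spectral disjointness makes it easier than
  field data; treat reported improvements as pipeline verification, not
  field accuracy.
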