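---
title: "Gaussian-of-differences fusion: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-of-differences fusion: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdfusion)
```

## The model and its assumptions

`gdfusion` fuses $K \ge 2$ co-registered images by per-pixel convex
weighting. The weight of image $k$ at a pixel is its *local edge
activity*: the first-order column/row differences are combined into an
edge magnitude, smoothed with a sampled Gaussian window, and normalized
across the $K$ images so weights sum to one at every pixel. The fused
image is the weighted sum of the original intensities.

The method assumes:

* **Registration.** Inputs are pixel-aligned. There is no alignment step;
  misregistration directly produces ghosting, since weights are compared
  pixel by pixel.
* **Activity = gradient.** Information content is proxied by first-order
  gradient magnitude. Sources whose useful content is smooth (e.g. a
  uniformly bright but diagnostically relevant region) are under-weighted.
* **Convexity is desirable.** The output never leaves the per-pixel
  intensity interval spanned by the inputs, so the method cannot
  hallucinate contrast, but also cannot exceed the dynamic range of any
  source.

For RGB inputs, activity is computed on the unweighted channel mean and a
single weight map per image is applied to all channels. The plain mean
(rather than luma weights) is the symmetric default; keeping one map per
image avoids color fringing from per-channel weight disagreement.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `s` | 10 | half-size of the Gaussian window (pixels); window side is $2s+1$ |
| `sigma` | `"auto"` = $s/3$ | Gaussian spread (pixels); the auto rule keeps the window's effective support matched to its size |
| `magnitude_rule` | `euclidean` | how column/row differences combine: $\sqrt{cd^2+rd^2}$, $|cd|+|rd|$, or $cd^2+rd^2$ |
| `boundary` | `replicate` | out-of-image handling for differences and smoothing |

Larger `s` pools activity over a wider neighborhood, which stabilizes
weights near strong edges at the cost of blurring the weight transition
between differently informative regions. The presets `gd5`, `gd10`,
`gd15` store $(s,\sigma)$ = (5, 1.6), (10, 3.3), (15, 5) — the $s/3$
spreads as conventionally printed at one decimal, not recomputed.

The directional-difference rendering admits more than one reading
(raw, halved or squared differences; Euclidean vs plain sum of the two
terms). Because the weights are ratios, all monotone variants are closely
related but not identical; the package exposes the three combination
rules explicitly rather than declaring one reading correct, with the
gradient magnitude (`euclidean`) as the default since it is the stated
intent of the activity measure.

### Pattern search (GDPS)

The adaptive variant maximizes a fusion-quality objective (`qabf`, `qcb`,
or negated `qcv`) over $(s, \sigma)$ by classic compass search: start at
$(10, 3.3)$, bounds $[5, 80] \times [1, 100]$, at most 20 polling
iterations. Within each poll the four axis neighbors at the current mesh
size are visited in the fixed order $(+s, -s, +\sigma, -\sigma)$ with
first-improvement acceptance, so runs are deterministic; the mesh doubles
on success and halves on failure, stopping early below $10^{-3}$. Initial
mesh 1, expansion 2, contraction 0.5 are the textbook compass defaults;
only the budget and bounds are prescribed by the method's standard setup.
`s` is searched as a real number and rounded to the integer grid only
when the kernel is built — the bounds say nothing about integrality, and
keeping the space continuous is what a generic pattern search expects.
The evaluation budget is at most $1 + 4 \times \texttt{max\_iter}$
objective calls, and the incumbent never worsens, so the optimized result
is never below the starting preset on its own objective.

## Numerical conventions

* **Boundaries.** Differences at the last row/column are zero under the
  default replicate rule (the virtual neighbor equals the edge pixel);
  smoothing replicates edge values. Zero-padding is selectable but
  creates spurious activity along the frame.
* **Kernel normalization.** Window coefficients are normalized to unit
  sum. This is mathematically irrelevant to the fused image — the weight
  ratio cancels any positive scale, which the tests assert explicitly —
  but keeps smoothed maps on the scale of the difference maps.
* **Zero-activity pixels.** Where all $K$ smoothed responses are below
  $10^{-12}$ the weights fall back to the uniform $1/K$: a flat region in
  every source carries no preference, and uniform averaging is the
  information-free choice.
* **Quantization for histogram metrics.** Entropy, mutual information
  and cross entropy quantize the unit range to the 256 levels
  `round(v * 255)`, which recovers the exact gray levels of images read
  from 8-bit files. Amplitude metrics (PSNR, SSIM, Qcb, Qcv) work on the
  0–255 scale with $L = 255$.
* **PSNR cap.** Zero error is reported as 100 dB — a finite, sortable
  sentinel for ranking tables.
* **SSIM.** Standard single-scale form: 11×11 Gaussian window,
  $\sigma = 1.5$, $c_1 = (0.01 \cdot 255)^2$, $c_2 = (0.03 \cdot 255)^2$,
  averaged over valid window positions. The fusion-level score *sums* the
  per-source values (two identical sources fused perfectly score 2),
  matching the convention under which published fusion tables show SSIM
  well above 1; a `mean` aggregation is selectable. Mutual information is
  likewise summed over sources, while PSNR, cross entropy and RMSE are
  averaged.
* **Qabf.** Sobel strength/orientation per image; per-pixel preservation
  through the published sigmoid constants
  ($\Gamma_g = 0.9994, \kappa_g = -15, \sigma_g = 0.5$;
  $\Gamma_\alpha = 0.9879, \kappa_\alpha = -22, \sigma_\alpha = 0.8$),
  weighted by source gradient magnitude. The literal sigmoids saturate at
  $\approx 0.9748$ for perfect preservation; by default the score is
  rescaled by that saturation value so a fused image identical to both
  sources scores exactly 1 (`saturate_one = FALSE` gives the literal
  model; the rescaling is a constant factor and cannot change any
  ranking). All-constant images have zero total edge weight and score 0
  by convention.
* **Qcb / Qcv.** The perceptual metrics follow their cited models with
  standard constants, all exposed in `perceptual_params()`:
  Mannos–Sakrison contrast sensitivity applied in the frequency domain at
  an assumed 32 pixels per degree; local band-limited contrast from a
  center/surround Gaussian pair ($\sigma$ = 2 and 4); contrast masking
  $|c|^3 / (|c|^2 + 10^{-4})$; Qcv windows of 16×16 pixels with local
  edge energy (squared Sobel magnitude) as region saliency. Bit-exact
  agreement with any specific third-party metric library is not a goal;
  each implementation is instead verified against an independent
  straight-line transcription of its model (naive DFT and per-pixel
  loops) on small fixtures.
* **Cross entropy.** Empty fused-histogram bins are floored at
  $10^{-12}$ so divergence stays finite on disjoint supports; the floor
  is applied to the fused histogram only.
* **Ranking.** Per metric, rank 1 is best respecting the metric's
  orientation; ties receive averaged ranks; a method's score is its mean
  rank across metrics.

## What the synthetic fixtures emulate — and what they do not

`make_stack()` generates seeded, bit-reproducible stacks for the four
application regimes from one ground-truth scene (low-frequency
background, geometric shapes, band-limited texture):

* *multifocus*: each member is Gaussian-blurred outside its own vertical
  band and equals the truth exactly inside it;
* *multiexposure*: exposure shifts of ±1.5 stops, the bright member
  clipping at white;
* *multimodal*: complementary shape subsets with bone-like vs
  tissue-like contrast;
* *irvisible*: a low-texture thermal member with bright "hot" objects vs
  a fully textured visible member.

Retaining the ground truth enables reference-based checks (RMSE against
truth) that the referenceless metric suite cannot provide. The fixtures
deliberately do **not** model sensor noise, misregistration, compression
artifacts, nonlinear camera response, or the content statistics of real
CT/MR or surveillance imagery — passing fixture tests demonstrates
algorithmic correctness and the expected qualitative behavior (the sharp,
well-exposed, or structure-bearing source dominates the weights), not
clinical-grade performance on real data.

Default fixture size is 128×128: comfortably larger than the biggest
preset window ($s = 15$, 31×31) and small enough that the whole suite and
the reproduction script run in seconds. The reproduction script uses the
same 128×128 stacks, 20 seeds for the efficacy rate, and the full
20-iteration search budget.

## Known limitations

* Weight maps follow gradient magnitude; smooth-content sources are
  systematically under-weighted.
* Pairwise-only metrics (Qabf, Qcb) are applied to the first two inputs
  of larger stacks, with a warning — the proper $K > 2$ extension is
  left undefined rather than improvised.
* The convex combination cannot extend dynamic range beyond the inputs
  (relevant for extreme multi-exposure stacks).
* Pattern search is local: it guarantees dominance over its starting
  preset, not a global optimum of the objective surface.
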