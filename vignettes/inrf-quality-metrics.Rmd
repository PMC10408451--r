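---
title: "Perceptual image and video quality with a nonlinear receptive-field transform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual image and video quality with a nonlinear receptive-field transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inrfqa)
```

## The model

Classical receptive-field models of visual neurons are linear filters
followed by a pointwise nonlinearity. The *intrinsically nonlinear
receptive field* (INRF) departs from this by letting the nonlinearity's
operating point shift with the local mean of the stimulus. Applied to a
grayscale image $I$ with values in $[0,1]$, the transform produces

$$O(x) = (m \star I)(x) \;-\; \lambda \sum_i w_i\,
  S\!\big(I(y_i) - (g \star I)(x)\big),$$

where $m$, $w$, $g$ are isotropic 2-D Gaussians of standard deviations
$\sigma_m$, $\sigma_w$, $\sigma_g$ (pixels), $\lambda$ is a scalar gain,
$S$ is an `atan` sigmoid, $\star$ is 2-D convolution, and the sum runs over
the support of $w$ centred at $x$. Because the sigmoid argument is offset
per *output* pixel by the locally averaged signal $(g \star I)(x)$, the
second term is **not** a convolution: that is the model's essential
nonlinearity, and the reason quality prediction benefits from it. The
transformed image behaves like an estimate of the *perceived* image, so
two images can be compared with a plain Euclidean statistic after the
transform:

$$\mathrm{score}(I, I_D) = \mathrm{MSE}\big(O, O_D\big),$$

computed by `inrf_iqa()`. For video, `inrf_vqa()` applies the image metric
frame by frame and pools by the arithmetic mean, after (a) aligning frame
counts between a high-rate reference and a lower-rate distorted sequence
and (b) rescaling the three kernel widths by the ratio of the frame width
to the 512-pixel width at which the parameters were calibrated
(`scale_params()`; a 1920-wide frame gives $f = 1920/512 = 3.75$).

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `sigma_m` | width of the linear summation kernel $m$ | px | 1.74 |
| `sigma_w` | width of the nonlinear weight kernel $w$ | px | 25 |
| `sigma_g` | width of the operating-point kernel $g$ | px | 1 |
| `lambda`  | gain of the nonlinear term | — | 3 |
| `truncate` | kernel radius in units of $\sigma$ | — | 3 |
| `n_levels` | level-set resolution of the fast path | — | 64 |

The defaults are the grid-search optimum obtained by maximizing the
correlation between the metric and observers' opinion scores on a large
natural-image quality database; they are meaningful only for luminance in
$[0,1]$ at a 512-pixel frame width, which is why `inrf_vqa()` rescales
them and why all readers normalize 8-bit data by 255.

## Design choices where the model description is open

* **Sigmoid scale.** The nonlinearity is stated only as "an atan-shaped
  sigmoid". We use $S(z) = \mathrm{atan}(z)$ with no gain: any fixed input
  gain is partially absorbed by $\lambda$ during calibration, so the
  simplest reading is also the least redundant parameterization.
* **Intensity range.** Images are normalized to $[0,1]$ (8-bit values
  divided by 255). Transform outputs are *not* clipped: the metric
  compares transforms, and clipping would discard signal.
* **Kernel discretization.** Gaussians are sampled at integer offsets on
  an odd support of radius $\lceil 3\sigma \rceil$ and normalized to unit
  sum. Unit sum is what makes a constant image a fixed point of the
  transform ($m \star c = c$, $g \star c = c$, every sigmoid argument 0).
* **Boundaries.** All three terms use mirror (symmetric) padding, applied
  by periodic folding so that kernels wider than the image — routine at
  $\sigma_w = 25$ on small test images — remain well defined. Mirror
  padding preserves the constant fixed point and avoids dark borders.
* **Luminance.** Rec. 601 luma ($0.299R + 0.587G + 0.114B$) by default,
  matching the era of the standard test databases; CIE/Rec. 709 Y from
  linearized sRGB is available as an option.
* **MSE vs RMSE.** The image metric is defined as MSE; RMSE is exposed as
  an option for comparison with related work. Rank correlations are
  invariant to the choice.
* **Frame alignment.** Reference-frame dropping with the index rule
  $\mathrm{ref}[i] = \lfloor i \cdot n_\mathrm{ref}/n_\mathrm{dist}
  \rfloor$ is the default (it performs better than duplicating distorted
  frames); duplication is retained behind a flag. Decimation is by frame
  index, not timestamp, which matches the integer-ratio cases (120→60,
  120→30) exactly.
* **Scaling by width.** $f$ is the *width* ratio: the worked example
  1920/512 = 3.75 is consistent with widths and inconsistent with heights
  (1080/384 = 2.8125). Scaled $\sigma$ values are used as-is; the radius
  is re-derived as $\lceil 3\sigma f \rceil$.

## The level-set fast path and its error

`inrf_transform_naive()` evaluates the per-pixel sum directly — it is
$O(N \cdot |w|)$ and serves as the ground-truth oracle.
`inrf_transform()` accelerates it in the style of fast bilateral
filtering: the range of $c(x) = (g \star I)(x)$ is discretized into
`n_levels` values $c_k$ spanning $[\min c, \max c]$; for each level that
actually brackets some pixel, the *true convolution*
$(w \star S(I - c_k))$ is computed (separably, in C++); each pixel then
interpolates linearly between its two bracketing levels. The
approximation error is controlled by the curvature of $\mathrm{atan}$
between adjacent levels; with the default 64 levels on $[0,1]$ images the
observed maximum deviation from the exact path is below $10^{-5}$, well
under the $10^{-3}$ bound the tests assert, and doubling the levels never
increases it. A constant-range image degenerates to a single exact level.

All arithmetic is double precision; the tolerance ladder used in the
tests ($10^{-10}$ for exact identities, $10^{-8}$ for the gray-shift
covariance, $10^{-3}$ for the fast path) assumes it.

## Evaluation protocol and the grid search

`srcc()` is the Spearman rank correlation (average ranks for ties).
`plcc_after_fit()` first maps the metric through the standard
four-parameter logistic

$$\hat y(x) = \beta_2 + \frac{\beta_1 - \beta_2}
  {1 + e^{-(x - \beta_3)/|\beta_4|}},$$

fitted by nonlinear least squares, then reports the Pearson correlation
between $\hat y(\mathrm{metric})$ and the subjective scores. The fit is
initialized at $\beta_1 = \max(y)$, $\beta_2 = \min(y)$, $\beta_3 =
\mathrm{median}(x)$, $\beta_4 = \mathrm{sd}(x)$, with $(\beta_1,\beta_2)$
swapped when the raw correlation is negative — a distance metric
anti-correlates with opinion scores, and the logistic absorbs that
orientation. `stats::nls` (port algorithm) is tried first; a
Nelder-Mead-then-BFGS least-squares fallback covers starts where `nls`
fails. During parameter calibration (`grid_search()`) the same
logistic-mapped PLCC is used as the criterion, keeping the optimizer
consistent with the reporting protocol; with the `"srcc"` criterion the
*absolute* rank correlation is maximized, for the same orientation
reason. Ties break to the lexicographically smallest
$(\sigma_m, \sigma_w, \sigma_g, \lambda)$, making the scan reproducible
bit for bit.

## What the synthetic world does and does not establish

The package ships generators (`make_image()`, `apply_distortion()`,
`make_video()`, `make_scored_dataset()`) so that every code path is
testable without downloading subjective-score databases. The image
generators include a $1/f$-spectrum noise field as a crude natural-image
surrogate; the distortion families (additive Gaussian noise, Gaussian
blur, contrast compression, luminance quantization, block averaging)
emulate the families used by the standard databases, with quantization +
block averaging standing in for codec compression so the tests stay
dependency-free. Each distortion is exactly the identity at level 0 and
strictly stronger at higher levels; `quantization`'s level is the
quantization *step* in luminance units, so that larger levels are
stronger (a bits-style parameter would invert that ordering).

`make_scored_dataset()` plants a known relationship: surrogate opinion
scores are a fixed *decreasing* four-parameter logistic of the metric
computed under known planted parameters ($\beta = (1, 5,
\mathrm{median}, \mathrm{sd}/2)$), plus optional Gaussian noise. With no
noise this makes SRCC exactly $-1$ and PLCC-after-fit exactly 1 under the
planted parameters — which is what the protocol-recovery and
planted-optimum tests assert. A green run therefore establishes that the
transform, metric, alignment, fitting and optimizer plumbing are correct
and self-consistent; it does **not** establish perceptual validity, which
requires the real databases and their observer scores. An evaluation
subcommand (`inrfqa eval`, `inrfqa grid`) is provided for exactly that
use when such data are available locally; deviations from published
correlations are possible through the open design choices above (sigmoid
scale, luminance transform, boundary handling) and should be reported,
not assumed away.

## Known limitations

* No color-difference modelling: only the luminance channel is scored.
* No motion-aware temporal processing; pooling is the plain mean.
* Frame-rate alignment only for distorted rates at or below the
  reference rate (dropping/duplication; no interpolation).
* PNG I/O is not provided (no PNG decoder in the dependency budget);
  frames are exchanged as PGM/PPM, Y4M, or raw planar YUV.
* The logistic fit can legitimately fail on degenerate score sets
  (constant columns); such failures carry context and map to a distinct
  CLI exit code rather than being silently swallowed.
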