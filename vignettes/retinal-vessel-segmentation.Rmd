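---
title: "Multiscale Hessian vessel segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale Hessian vessel segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaseg)
```

## The image model

A fundus photograph is modelled as a bright circular retinal disc (the field
of view, FOV) on a dark frame, with blood vessels appearing as *dark
curvilinear tubes* of diameter roughly 2–12 px on a brighter, unevenly
illuminated background. Every stage of the pipeline encodes part of this
model: the green channel is where the dark-tube contrast is strongest; CLAHE
flattens the slow illumination field while bounding noise amplification; the
Hessian response is a matched detector for tubes of a given radius; the
oriented openings encode "vessels are line segments of some length 2–12 px
and some orientation"; Otsu assumes the final response histogram separates
into vessel and background classes.

## The vesselness response

At scale $s$ the image is smoothed by a Gaussian of standard deviation $s$
and the per-pixel Hessian is computed from second-derivative-of-Gaussian
kernels, multiplied by $s^2$ (second-order scale normalization) so that
responses at different scales are commensurate. With eigenvalues ordered
$|\lambda_1| \ge |\lambda_2|$, a dark tube of radius $\approx s$ gives
$\lambda_1$ large and positive (strong positive curvature across the vessel)
and $\lambda_2 \approx 0$ (none along it), while blobs give
$\lambda_2/\lambda_1 \approx \pm 1$ and bright tubes give $\lambda_1 < 0$.
The single-scale response is

$$
f(p, s) \;=\; \exp\!\big(-\arctan(\lambda_2/\lambda_1)^2\big)\;
\frac{\lambda_1}{d}, \qquad d = 2s,
$$

for $\lambda_1 > \lambda_{\text{floor}}$ and $0$ otherwise, clipped to
$[0,1]$. The $\arctan$ factor is a smooth penalty on the eigenvalue ratio
(the direction angle of the eigenvector pair): $1$ for a perfect tube,
$\exp(-(\pi/4)^2) \approx 0.54$ for an isotropic blob. The division by the
vessel-diameter equivalent $d$ equalizes response *amplitudes* across
scales: $\lambda_1$ grows with vessel caliber at the matched scale, and
without this factor the multiscale maximum would be dominated by the largest
vessels. The multiscale map is the per-pixel maximum over the sampled
scales.

Two details deserve comment.

* **The $\lambda_{\text{floor}}$ cutoff** (default $10^{-10}$) exists
  because the eigenvalue ratio is undefined at $\lambda_1 = 0$; since the
  response is proportional to $\lambda_1$, the filter output vanishes
  continuously on flat regions anyway and the floor only guards the
  division. It is exposed in `pipeline_config()` for completeness.
* **Scale selection bias.** For a tube with a Gaussian cross-section of
  standard deviation $\sigma$, the centerline response as a function of $s$
  is proportional to $s\,\sigma/(\sigma^2+s^2)^{3/2}$, which peaks at
  $s = \sigma/\sqrt{2} \approx 0.71\,\sigma$, not at $s = \sigma$. This is a
  known property of the chosen normalization ($s^2$ on the Hessian followed
  by division by $2s$): the per-pixel *maximum* still tracks caliber
  monotonically, which is what the multiscale maximum needs, but the
  reported `best_scale` attribute systematically underestimates the profile
  width by a factor $\approx \sqrt 2$. A $s^{3/2}$ (γ = 3/2) normalization
  would center the peak at $s = \sigma$ exactly; we keep the $s^2$
  normalization with amplitude equalization because the response amplitude,
  not the argmax, is what the downstream threshold consumes.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `clip_limit` | 0.01 | fraction of tile pixels | community-standard CLAHE clip; bounds the equalization slope |
| `tile_grid` | 8 × 8 | tiles | standard CLAHE tiling; each tile must be ≥ 8 × 8 px |
| `clahe_bins`, `otsu_bins` | 256 | bins over [0, 1] | one bin per 8-bit gray level |
| `s_min`, `s_max`, `s_step` | 1, 6, 0.5 | px (vessel radius) | vessel diameters span 2–12 px and the scale is the radius; 0.5 px steps sample each caliber within ~25% |
| `lambda_floor` | 1e-10 | intensity · px⁰ | guards the eigenvalue ratio at λ₁ → 0 |
| `noise_floor_q` | 0.99 | quantile | see below; 0 disables |
| `morphology` | TRUE | — | the 198-template opening |
| `baseline` | FALSE | — | classic two-term vesselness instead of the improved response |

The structuring-element bank is deliberately not configurable: lengths
2–12 px × angles 0–170° in 10° steps are part of the method definition
(198 templates).

## The noise-referenced response floor

Min–max normalization of the response over the FOV (needed so the Otsu
histogram is well populated regardless of absolute response magnitude) has a
side effect: it is *scale-free*, so on an image containing no vessels at all
it stretches pure-noise responses over the full [0, 1] range, and Otsu —
which always splits its histogram — then binarizes noise into spurious
vessels covering a third of the FOV. No choice of threshold parameters fixes
this, because after normalization a noise map and a vessel map look alike.

The pipeline therefore restores the absolute scale before normalizing: it
estimates the noise standard deviation of the enhanced image with the
Laplacian-residual median estimator (the 3 × 3 operator annihilates locally
planar structure and has a known gain on white noise, and the median makes
the estimate robust to vessels and edges), pushes white noise of that level
through the *identical* filter bank by a small fixed-seed simulation (a
96 × 96 patch; the response is linear in the noise amplitude, so one
simulation serves all levels), and zeroes raw responses at or below the 99th
percentile of that pure-noise response. Responses below this floor are, by
construction, indistinguishable from the image's own noise, so zeroing them
is a statement of evidence, not a tuning knob. On noise-free images the
estimated level and hence the floor are negligible and the stage is inert;
on vessel-free noisy images at most ~1% of FOV pixels survive the floor, so
the subsequent Otsu split cannot mark more than that. The honest cost is
sensitivity to vessels whose contrast sits at or below the image noise
level — those are suppressed along with the noise.

## Numerical choices

* **Kernels** are sampled analytically and truncated at ±4 s, rounded to an
  odd length. The smoothing kernel is normalized to unit sum (constants are
  preserved exactly); second-derivative kernels are forced to zero sum so
  flat patches give exactly zero curvature despite truncation. With these
  corrections the scale-normalized second derivative of a quadratic ramp is
  accurate to better than 1% for s ≥ 1.
* **Convolution borders** are symmetric reflections (edge pixel repeated).
* **Morphology borders** clip the min/max windows to the image domain
  (out-of-image samples are ignored). Reflective padding here would break
  the erosion/dilation adjunction and with it the *exact* idempotence of the
  opening, which the test suite asserts bit-for-bit; domain clipping is the
  standard lattice-theoretic choice and keeps idempotence a theorem.
* **Eigenvalue order** is by magnitude, $|\lambda_1| \ge |\lambda_2|$; on
  exact magnitude ties the larger *signed* value is taken as $\lambda_1$, so
  a dark ridge keeps its positive eigenvalue first.
* **Line rasterization**: a centered digital-differential walk along the
  major axis; "length" counts set pixels (matching pixel-denominated vessel
  diameters), even lengths put the extra pixel on the positive-x side, and
  half-integer minor coordinates round toward +∞. Angles are measured
  counterclockwise from the +x (column) axis; because the angle set
  0–170°/10° is closed under transposition (0 ↔ 90, 10 ↔ 100, …), the bank
  as a whole does not depend on this convention.
* **Otsu**: histogram restricted to the FOV (the dark surround would
  otherwise dominate the lower class), 256 uniform bins over [0, 1],
  exhaustive scan of all 255 splits, smallest maximizer on ties,
  binarization strictly above the threshold. A region whose histogram
  occupies a single bin has no valid split and raises an error rather than
  returning an arbitrary threshold.
* **Degenerate inputs**: empty FOV masks, all-dark images (no FOV
  recoverable), structuring elements larger than the image, and empty scale
  sets or template banks all raise labelled errors; `segment()` prefixes
  every error with the failing stage.

## What the phantom emulates — and what it does not

`make_phantom()` renders the assumptions the method itself makes: a bright
disc with a radial illumination falloff, dark vessels as Gaussian-profile
tubes along smooth random splines (widths drawn thin-skewed from 2–12 px;
with the default six vessels the vessel fraction lands near the 10–15%
typical of fundus photographs), red/blue channels as scaled copies of green,
and additive white noise (default σ = 0.02 of full scale, on the noisy side
of realistic sensor noise). Ground truth marks pixels within half a width of
a centerline.

It deliberately does **not** model: the optic disc and fovea, central vessel
light reflexes, lesions and exudates, vessel branching and crossing
topology, correlated sensor noise, or JPEG artifacts. Passing the phantom
tests therefore demonstrates that the pipeline recovers dark curvilinear
structure under noise and uneven illumination — it does not certify
performance on pathology-bearing clinical images, where in particular the
optic disc rim is a known source of false positives for Hessian filters.

Test and acceptance problem sizes are 256 × 256 phantoms (FOV radius 110 px)
for end-to-end runs and 160 × 160 for per-stage tests; these sizes keep every
vessel caliber representable while the full suite runs in well under a
minute.

## Known limitations

* Sensitivity degrades for vessels at or below the image noise level — the
  noise floor suppresses them by design; on noisy phantoms the thinnest
  (2–3 px) vessels account for most missed pixels.
* The Otsu stage produces exactly one global threshold; locally adaptive or
  hysteresis thresholding (out of scope here) is known to recover more of
  the fine vasculature.
* The FOV estimator assumes the retinal disc is the single largest bright
  region of the red channel; montages or severely vignetted images violate
  this.
* `best_scale` underestimates profile widths by ≈ √2 (see above); treat it
  as an ordinal caliber indicator, not a diameter measurement.
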