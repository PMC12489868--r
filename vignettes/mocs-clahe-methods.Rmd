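---
title: "Methods: multi-objective cuckoo search tuning of Rayleigh CLAHE"
author: "mocsClahe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective cuckoo search tuning of Rayleigh CLAHE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocsClahe)
```

## The problem

The bulbar conjunctiva is the one place where superficial microvessels can be
filmed directly and non-invasively, which makes it attractive for studying
vascular changes in systemic disease. Slit-lamp acquisitions of it are
difficult material for automatic analysis: the scleral background is bright
and vignetted, the vessels are thin dark curvilinear structures, the
intensity histogram is negatively skewed, and small eye or operator movements
produce large exposure swings and defocused frames.

Contrast-limited adaptive histogram equalization (CLAHE) is the standard
remedy for local contrast, but its outcome depends strongly on three
hyperparameters — the tile grid, the clip limit, and (when the transfer
function is shaped to a Rayleigh output histogram) the Rayleigh shape
parameter α. Fixed values cannot suit images whose exposure varies this much.
This package tunes the four-dimensional parameter vector *per image* with a
multi-objective cuckoo search (MOCS) that maximizes a texture-contrast
objective while minimizing a noise-amplification objective, and applies the
balanced middle solution of the resulting Pareto front.

## Pipeline

1. **Luminance extraction.** RGB frames are reduced to the HSV value channel,
   V = max(R, G, B) per pixel (`rgbToValue()`); all further processing is on
   [0, 1] luminance. Conversion to and from 8-bit happens only at file I/O
   and inside the quality metrics, whose printed constants are defined on the
   gray-level scale.
2. **Frame selection.** For short video sequences, each frame is scored by
   the variance of its Laplacian-of-Gaussian response
   (`sharpnessLogVariance()`) and only the sharpest frame is analysed. The
   LoG scale defaults to σ = 2 px with kernel half-width ⌈3σ⌉ (the 3σ support
   captures >99% of the Gaussian mass) and reflect padding, which avoids the
   artificial edge response that zero padding would add to the variance.
   Neither σ nor the padding is prescribed by the method itself; they are
   package defaults, exposed as arguments. Ties go to the lowest frame index.
3. **Exposure classification.** Mean luminosity V̄ classifies the frame:
   V̄ ≤ 0.6 underexposed, 0.6 < V̄ ≤ 0.8 correct, V̄ > 0.8 overexposed
   (boundaries belong to the lower class). The thresholds are empirical and
   reflect the negatively skewed histograms of bright-background imagery,
   where a properly exposed image averages well above mid-gray.

## CLAHE with a Rayleigh-shaped output

The image is reflect-padded to a multiple of the tile grid, split into
non-overlapping tiles, and each tile's 256-bin histogram is clipped at
`clipLimit × (tile pixel count)` (floored at one count so tiny tiles remain
well defined). The clipped-off mass is redistributed **equally over all
bins**; since redistribution can push bins back over the limit, the
clip/redistribute sweep is iterated (up to 50 times, stopping when the
remaining excess is below 10⁻¹² of the mass). When the limit is feasible
(clip × bins ≥ mass) this converges to the exact fixed point — saturated
bins at the limit, the rest sharing the excess equally; e.g. the histogram
(10, 0, 0, 0) with clip 4 becomes (4, 2, 2, 2). When the limit is
infeasible (clip × bins < mass) no histogram can satisfy it and the
iteration settles near the uniform histogram, which is the sensible limit —
maximal clipping, minimal equalization. Mass is conserved in every case.

Each tile's cumulative distribution c is mapped through a Rayleigh transfer
function. The Rayleigh quantile is g(c) = √(2α² ln 1/(1−c)). Used raw and
then affinely rescaled to [0, 1], α would be a pure scale factor and the
rescale would cancel it exactly, leaving α without any effect — at odds with
its documented role of steering the brightness of the enhancement. The
package therefore uses the range-normalized form standard in adaptive
equalization implementations:

  g(c) = g_min + (g_max − g_min) · √(−2α² ln(1 − v_max·c)),
  v_max = 1 − exp(−1/(2α²)),

which spans [g_min, g_max] exactly, needs no clamp (the logarithm's argument
is bounded away from zero by construction), and lets α genuinely shape the
curve: large α approaches the brighter √c mapping, small α darkens the
midtones. The raw closed form remains available via
`rayleighTransfer(..., rescale = FALSE)`.

Per-tile mappings are blended by bilinear interpolation between the four
nearest tile centers; outside the outer ring of centers both neighbor
indices clamp to the same node, so edges extend linearly and corners fall
back to the nearest tile mapping. A constant image maps to a constant image,
and outputs never leave [0, 1].

## The two objectives

**GLCM contrast** (maximize): the gray-level co-occurrence matrix is
accumulated at 8 quantization levels with the single displacement (0, 1)
(distance 1, horizontal) and symmetric counting, then contrast is
Σᵢⱼ (i−j)² p(i,j). Levels, offset and symmetry are the most widespread
defaults for Haralick features; none is intrinsic to the method and all are
exposed through `glcmConfig()`.

**FNVE** (minimize): the fast noise-variance estimate convolves the image
with N = [1 −2 1; −2 4 −2; 1 −2 1] — the difference of the two 3×3
Laplacian approximations, which annihilates constant and affine intensity —
and averages absolute responses over interior pixels:

  σ̂ = √(π/2) · Σ|I∗N| / (6 (W−2)(H−2)).

The √(π/2) factor converts the mean absolute value of a Gaussian response to
its standard deviation, and 6 = √36 is the operator's coefficient norm (the
response variance is 36σ²). The estimate is on the [0, 1] luminance scale;
multiply by 255 to compare against 8-bit-scale numbers. Its consistency is
verified in the tests: on i.i.d. Gaussian fields the error shrinks with
image size and is within 5% of truth at 512².

## The optimizer

The search space is the box (tilesX, tilesY, clipLimit, α) ∈
[4, 12]² × [0.001, 0.01] × [0.5, 0.9] (the package defaults). Optimizer
defaults are 50 nests and 20 iterations with a 25% survival probability,
i.e. a discovery/abandonment probability P_a = 0.75. The classical
cuckoo-search default is P_a = 0.25; both the bounds and P_a are plain
configuration fields. Internally both objectives are minimized as
(−contrast, noise); all reported values keep natural signs.

Design points where the method leaves room, decided once here:

* **Lévy flights** use the Mantegna sampler u/|v|^(1/β) with β = 1.5 and a
  step scale of 0.01 of the per-dimension bound range — the customary
  cuckoo-search settings.
* **Guides.** Each proposal walks from its nest toward a random member of
  the current non-dominated archive, drawn with crowding-weighted
  probability so sparse front regions attract more search.
* **Replacement.** A proposal replaces a uniformly random nest if it
  dominates it; if the two are mutually non-dominated it replaces with
  probability 1/2, a diversity-preserving analogue of the single-objective
  "keep if better" rule.
* **Integer tiles.** Tile counts are searched as continuous values and
  rounded half-up only at decode/evaluation time, keeping the walk
  continuous. Evaluations are cached on the decoded tuple, since rounding
  collapses many vectors onto one CLAHE setting.
* **Elitism.** After each iteration the populations before and after the
  abandonment walk are merged and truncated back to the population size by
  non-dominated sorting with crowding distance; a separate archive keeps the
  non-dominated set of everything population-resident, also truncated to the
  population size by crowding. The tests assert that the archived front
  never regresses.
* **Failures.** Non-finite or failed evaluations are treated as dominated by
  everything (with a warning), so they can never enter the front.
* **Selection.** The applied solution is the *middle* of the front sorted by
  the contrast objective (0-based index ⌊(n−1)/2⌋; ties broken by larger
  crowding distance, then lower noise) — a balanced trade-off rather than
  either extreme.

Everything is driven by one seed, and runs are bitwise reproducible.

## Quality metrics

PSNR = 10 log₁₀((L−1)²/MSE) with MSE on the (L−1)-scaled representation;
identical images report +∞ with a warning. SSIM is computed **globally** —
one window spanning the image, from whole-image means, variances and
covariance with C₁ = (K₁L)², C₂ = (K₂L)², K₁ = 0.01, K₂ = 0.03 — exactly as
the printed formula states, with a Gaussian sliding-window variant available
as an option (`windowed = TRUE`). Note the deliberate asymmetry, kept as
printed: PSNR uses (L−1)² while the SSIM constants use L. NIQE needs a
pretrained natural-scene-statistics model and is not reimplemented; the
quality report accepts an external evaluator and records its value verbatim.

## The phantom generator

`generatePhantom()` emulates the features of slit-lamp conjunctival frames
that the pipeline is sensitive to: a bright background (default 0.75) with a
quadratic radial vignette; dark curvilinear vessels built as random walks
with momentum and Gaussian cross-sections (crossings take the deeper value,
not the sum); optional defocus blur; then additive Gaussian sensor noise,
clipped to [0, 1] (the ground-truth σ is recorded pre-clipping, so it
slightly overstates the realized noise near saturation). The defaults were
chosen once as a plausible correct-exposure acquisition: 128×128 px, six
vessels of ~3 px width and 0.35 contrast, vignette 0.15, noise σ = 0.01.
The resulting histograms are negatively skewed, as real conjunctival frames
are, and `exposureSuite()` produces one phantom per exposure class by a few
fixed-point adjustments of the background level.

What the phantoms do *not* model: specular highlights, eyelash occlusion,
anatomical branching statistics, motion blur anisotropy, spatially
correlated sensor noise. Tests passing on phantoms therefore demonstrate
the machinery — the estimators, the optimizer, the directional behavior of
the two arms — not clinical image quality; absolute contrast or noise
numbers on phantoms are not comparable to values measured on real cohorts.

```{r phantom, fig.width = 5, fig.height = 5, eval = FALSE}
b <- generatePhantom(phantomSpec(seed = 1))
image(t(pixels(b@image))[, nrow(pixels(b@image)):1],
      col = gray.colors(256), asp = 1, axes = FALSE)
```

## Numerical choices and degenerate inputs

* 256 histogram bins (8-bit acquisition); clip count floored at 1.
* Reflect padding everywhere a filter or the tile grid meets a border.
* A constant image passes through the whole pipeline with a warning: CLAHE
  returns it unchanged, both objectives are 0, and the front collapses.
* `rayleighTransfer()` guards monotonicity with a running maximum against
  floating round-off; mappings are non-decreasing, so per-tile rank order of
  distinct levels is preserved.
* Tile grids must be at least 2×2 (bilinear blending needs four nodes), and
  FNVE needs at least 3×3 images.

Test and example problem sizes are chosen to keep the suite quick while
leaving the estimators in their asymptotic regime: 64–128 px phantoms for
optimizer runs (at 64 px, tiles hold under 100 px and the clip-count floor
mutes the clip limit, so comparisons that depend on the clip limit use
128 px), 512² fields for noise-recovery checks, and reduced optimizer
settings (15 nests, 8 iterations) where a full run is unnecessary.

## Known limitations

* Grayscale only: chroma is discarded; color-preserving enhancement would
  need to re-combine the enhanced luminance with the original chromatic
  channels.
* The optimizer is sequential and evaluates one CLAHE per candidate;
  full-size images take correspondingly longer than the phantom examples.
* On phantoms the optimized arm consistently wins on FNVE and SSIM while the
  fixed baseline reaches higher raw contrast — the expected trade-off — but
  the PSNR ordering between arms is not stable at phantom scale: α shifts
  global brightness, which PSNR penalizes heavily and SSIM (correctly)
  forgives. Conclusions about PSNR on real images should not be drawn from
  phantoms.
* Exposure thresholds are empirical for bright-background conjunctival
  imagery and will not transfer to dark-background modalities unchanged.
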