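---
title: "Rotational morphological contrast enhancement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational morphological contrast enhancement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmpenhance)
```

## The problem

Biomedical greyscale images — mammograms, chest radiographs, micrographs —
often contain diagnostically important structures whose intensity differs
from their surroundings by only a few grey levels, sitting on a background
that is itself spatially uneven. Global enhancement methods (histogram
modification, frequency filtering) amplify everything indiscriminately,
including the background trend. The approach implemented here instead
*extracts* candidate target structures with morphological top-hat
transforms — which respond to local shape and scale, not to absolute
intensity — amplifies only the extracted structures, and recombines them
with the original image.

## Flat greyscale morphology

An image is a function $f$ on the pixel grid; a structuring element (SE)
$B$ is a small binary mask with an origin. The package provides the four
flat operators:

* **dilation** $\delta_B(f)$: pixelwise maximum of $f$ over the SE
  neighbourhood;
* **erosion** $\varepsilon_B(f)$: pixelwise minimum;
* **opening** $\gamma_B = \delta_{\check B}\,\varepsilon_B$ (erosion then
  the adjoint dilation): removes bright features smaller than $B$;
* **closing** $\varphi_B = \varepsilon_{\check B}\,\delta_B$: fills dark
  features smaller than $B$.

SE shapes are `disc` (all lattice points within Euclidean radius
$(d-1)/2$), `square`, and `line` (a one-pixel-wide Bresenham segment
through the origin). Disc and square sizes must be odd so the origin is a
pixel centre; even sizes are rejected rather than silently re-centred.
All SEs are flat (binary) — the method never uses grey-weighted elements.

**Border rule.** Samples falling outside the frame are supplied by edge
replication (the sampling coordinate is clamped to the frame). This
avoids spurious top-hat responses along monotone borders: a pure intensity
ramp erodes and dilates to itself wherever the extremum over the clamped
window coincides with the in-frame extremum. With this rule, opening and
closing are exactly idempotent and anti-/extensive for disc, square and
axis-aligned line elements (the test suite asserts this on integer
images). For *oblique* line elements the interaction between diagonal
offsets and coordinate-wise clamping can violate both properties inside a
border band of roughly twice the element's reach; in the band's interior
they hold exactly. A padded-canvas composition was considered and
rejected: it restores ramp behaviour at borders but sacrifices exact
idempotence for discs, which we regard as the more important contract for
the default configuration.

**Arithmetic.** All morphology is performed on real-valued arrays; integer
images are promoted on read, and quantization (round half away from zero,
clip to the display range) happens only when an image is written out.

## Rotational morphological processing (RMP)

A single fixed-orientation SE leaves orientation-dependent artefacts at
object peripheries. RMP makes the filter effectively isotropic: the half
circle is divided into $N$ equal directions $\theta_i = \pi i / N$,
$i = 0, \dots, N-1$; for each direction the image is rotated clockwise by
$\theta_i$, opened (or closed) with $B$, rotated back, and the $N$
derotated results are combined pixelwise by maximum (opening) or minimum
(closing). With $N = 1$ both operators are bit-identical to the
conventional ones. The recommended direction counts — used as the
defaults — are $N = 8$ for disc and square elements and $N = 36$ for line
elements.

Implementation choices:

* **Rotation centre** is the geometric centre of the pixel grid,
  $((H-1)/2, (W-1)/2)$; output frames keep the input size (the combine
  step needs aligned rasters), and out-of-frame samples are filled by edge
  replication.
* **Interpolation** is bilinear by default; nearest-neighbour is available
  and is used by the exactness tests, because at multiples of $\pi/2$ a
  nearest-neighbour rotation of a square image is an exact pixel
  permutation.
* Monotonicity in $N$ is *not* claimed: interpolation breaks exact
  nesting for non-right angles. What does hold by construction is that the
  combined image bounds every individual derotated branch, and — since the
  $\theta_0 = 0$ branch is computed without any resampling — the
  rotational opening is bounded below by the conventional opening and
  above by $f$ wherever the branches are exact.

## Top-hats and the enhancement operator

The white top-hat $\mathrm{WTH} = f - \gamma_B(f)$ extracts bright
structures smaller than the SE; the black top-hat
$\mathrm{BTH} = \varphi_B(f) - f$ extracts dark ones. Both are independent
of the local background level ($\mathrm{WTH}(f + c) = \mathrm{WTH}(f)$
exactly), which is what permits extraction from an uneven background. The
rotational variants use the RMP opening/closing; because bilinearly
interpolated branches can overshoot $f$ by sub-quantum amounts, top-hat
outputs are clamped at zero so that extracted-structure images are
nonnegative, as their semantics require.

The classical top-hat contrast operator
$\kappa = f + \mathrm{WTH} - \mathrm{BTH}$ brightens bright targets and
darkens dark ones, but for genuinely low-contrast targets the top-hat
amplitudes are too small to matter. The full operator therefore applies a
two-stage **greyscale modification** $\nu$ to each top-hat image first:

1. *histogram equalization* over the display range with 256 bins
   (`out = min + (max - min) * cdf(level)`), then
2. *linear stretching* of the occupied range onto the full display range.

The enhanced image is
$\lambda = f + \nu(\mathrm{WTH}') - \nu(\mathrm{BTH}')$, restricted to the
display range.

Conventions that the formulas leave open, fixed here:

* **Featureless top-hats contribute nothing.** Equalization maps a
  constant image to the display maximum (the CDF of the occupied level is
  1), so a blindly equalized all-zero top-hat would inject a constant
  plane into $\lambda$. `greyscale_modify()` therefore returns zeros for a
  constant top-hat image. This also makes $\lambda$ the exact identity on
  constant images.
* **Equalization includes the zero background** of the top-hat image; no
  exclusion rule is applied. After the stretch the zero level maps back to
  zero (it is the minimum), so zero-background pixels are unaffected.
* **Range restriction is saturation clipping** by default: clipping
  preserves the absolute enhancement of mid-range structures, which is the
  point of the method; a `range_mode = "rescale"` option performs a
  min–max stretch instead for users who prefer a spanned output.
* **Pre-smoothing** (off by default): a rotational opening followed by a
  rotational closing with a small disc (diameter 3), available for noisy
  inputs. The greyscale modification amplifies *any* extracted structure,
  including noise residues, so denoising before enhancement is advisable
  for low-dose images.

## Contrast improvement ratio

Enhancement quality is scored by the contrast improvement ratio. The local
contrast at a pixel is $C = |p - a| / (p + a)$, with $p$ the mean
intensity of an $R_C \times R_C$ centre window and $a$ the mean of the
annulus between the $R_N \times R_N$ and centre windows ($R_C = 11$,
$R_N = 41$ by default, both interpreted as window side lengths). The
ratio over an evaluation region $R$ is

$$\mathrm{CIR} = \frac{\sum_{R} (C - \tilde C)^2}{\sum_{R} C^2},$$

with $C$ from the unenhanced and $\tilde C$ from the enhanced image. $R$
defaults to all pixels whose neighbourhood window fits inside the frame; a
mask argument allows target-restricted evaluation. Window means use
summed-area tables (exact to floating precision; the tests compare against
nested-loop sums at $10^{-12}$). Two degenerate cases are handled
explicitly: $C = 0$ where $p + a = 0$, and an original image with no
local contrast on $R$ raises a classed error (`rmp_degenerate_error`)
rather than returning an undefined ratio. Note that the ratio is
ill-conditioned when the original is *nearly* contrast-free (e.g. a pure
linear ramp, whose windowed contrast is pure floating-point residue); the
tests therefore check contrast-map equality directly in such cases.

## Baselines

Two standard enhancement methods are included for comparison, behind the
same image types:

* **Multiscale retinex (MSR)**: $\sum_k w_k [\log(f + 1) -
  \log(G_{\sigma_k} \!\ast\! f + 1)]$ with Gaussian surrounds
  $\sigma = 5, 15, 25$ pixels and equal weights $1/3$, followed by a
  min–max stretch to the display range (the log-domain output has no
  canonical scale; the stretch mirrors the enhancement module's
  convention). Blurring uses `EBImage::gblur` with replicated borders;
  images smaller than the kernel are replicate-padded and cropped.
* **CLAHE**: the image is tiled into 9 × 9-pixel blocks (edge tiles absorb
  the remainder); each tile's 256-bin histogram is clipped at a fraction
  (default 0.01) of the tile pixel count with the excess redistributed
  uniformly, and per-pixel output is bilinearly interpolated between the
  four nearest tile-centre equalization maps. The clip limit is exposed
  because the reference setting specifies only the block size. In the
  single-tile large-clip limit the implementation reduces exactly to
  global histogram equalization, which the tests assert.

## The synthetic phantom

No reference test image is distributed, so the package generates one: a
218 × 238 pixel 8-bit frame with six flat-disc blobs of radii 10–15 px and
amplitudes 10–30 grey levels on a base level of 100 with a left-to-right
linear ramp of 40 levels, plus additive Gaussian noise with $\sigma = 2$.
The design mimics the regime the method targets: multiple distinct
low-contrast targets (maximum windowed local contrast below 0.15; blob
amplitudes below 20% of the display range) on an uneven background. Blob
radii are capped at 15 px so that every target's base diameter stays below
the default 31-px SE diameter — the SE must be larger than the targets it
is meant to extract. The generator also returns the blob-support mask for
target-restricted CIR. All randomness flows through the spec's seed and
the caller's RNG stream is left untouched.

What the phantom does *not* emulate: anatomical texture, correlated
(quantum) noise, scatter, and modality-specific intensity calibration.
Passing the end-to-end ordering test (proposed $>$ MSR $>$ CLAHE in CIR)
on this phantom demonstrates the pipeline's behaviour in the intended
regime, not clinical performance; absolute CIR values depend strongly on
the phantom content and are not comparable across images.

## Problem sizes and runtime

The min/max filter kernel is a small C++ routine iterating offset-major
with column-sequential access; a full default enhancement (disc-31,
$N = 8$, 218 × 238) runs in about two seconds on one core. The test suite
verifies operators against naive double-loop oracles on batches of
random 15 × 17 to 20 × 20 integer images (over a hundred per batch),
property-style invariants on dozens of seeded cases, and the end-to-end
baseline comparison across five phantom seeds — sizes chosen so the whole
suite completes in well under a minute.

## Known limitations

* Oblique line SEs lose exact idempotence/extensivity in a border band
  (see above); disc and square defaults are unaffected.
* Without pre-smoothing, the greyscale modification amplifies noise along
  with targets; the CIR still increases, but visual quality on noisy
  inputs benefits from `presmooth = TRUE`.
* Rotation-based processing assumes the image frame is large relative to
  the SE; for frames comparable to the SE size the border band dominates.
* Colour images, weighted SEs, 3-D stacks and DICOM I/O are out of scope.
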