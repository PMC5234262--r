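---
title: "Wound segmentation by synthetic frequencies and toroidal contrast decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wound segmentation by synthetic frequencies and toroidal contrast decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torusseg)
```

## The problem

Pressure ulcers are chronic wounds caused by prolonged compression of soft
tissue over a bony prominence. Stage-IV ulcers, with full skin loss and
exposed muscle, are photographed during clinical follow-up, and delineating
the wound region in those photographs is the first step of any quantitative
assessment (area, shape, healing trajectory). Curve-evolution segmenters
(snakes, active contours without edges) need an initial contour and careful
parametrization; `torusseg` implements an alternative that needs neither: the
image itself is decomposed into a stack of contrast levels, and the wound
boundary is where those levels consistently place their class boundary.

## The model

### Grayscale amplitude

An RGB photograph is reduced to a single amplitude channel with the CIE 1931
luminance weights,

$$A = 0.2126\,R + 0.7152\,G + 0.0722\,B,$$

kept real-valued throughout: every later transform is continuous in $A$, so
8-bit re-quantization would only discard information. Stored 8-bit amplitudes
$[0,255]$ are shifted to the working range $\tilde A = A + 1 \in [1,256]$.
The shift removes the singularity of the frequency transform at $A = 0$ and
is exposed as `amplitude_offset` for users who want the raw convention.

### Synthetic frequencies

Each pixel is assigned a *synthetic frequency*

$$f(m,n;r) = \tilde A(m,n)^{-r}, \qquad r > 0,$$

a dimensionless quantity inversely related to amplitude (the analogy behind
the name: for a light sensor at fixed energy density, the wave frequency must
rise as the recorded amplitude falls). On $\tilde A \in [1,256]$ the field
satisfies $f \in (0,1]$, is strictly decreasing in $\tilde A$ for every $r$,
and is pinned at $f = 1$ for $\tilde A = 1$. The exponent $r$ — the
*frequency parameter* — controls how sharply $f$ spreads over the amplitude
range; sweeping it generates the contrast levels.

### Toroidal decomposition

The x/y parametric maps of a torus surface of major radius $R$, re-read with
the angular arguments expressed through the frequency field, give two
per-pixel image transforms,

$$\mathrm{THD}(u;f) = [R + \cos(2\pi f u)]\,\cos(2\pi\arctan f), \qquad
  \mathrm{TVD}(v;f) = [R + \cos(2\pi f v)]\,\sin(2\pi\arctan f),$$

evaluated on symmetric coordinate ramps $u$ (horizontal) and $v$ (vertical)
spanning $[-(M-1)/M,\,(M-1)/M]$ and $[-(N-1)/N,\,(N-1)/N]$. Two operators
combine the decompositions with the amplitude through elementwise (Hadamard)
products,

$$T_a = \tilde A \circ (\mathrm{TVD} + \mathrm{THD}), \qquad
  T_p = \tilde A^{2} \circ (\mathrm{TVD} \circ \mathrm{THD}),$$

each stored normalized: $\bar T = |T| / \max |T| \in [0,1]$. Everything is
strictly per pixel — no convolution, no neighbourhood — so levels can be
computed independently and in any order, and the transform commutes with
joint permutations of pixel positions.

Why this works as a contrast decomposition: the factor
$\cos(2\pi\arctan f)$ crosses zero where $2\pi\arctan f = 3\pi/2$, i.e. at
$f^\* = \tan(3/4) \approx 0.9316$, reached at amplitude
$\tilde A^\*(r) = (1/f^\*)^{1/r}$. Over
the default sweep $r \in [0.013, 0.015]$ this critical amplitude moves from
$\approx 232$ down to $\approx 112$: each level effectively splits the image
at a different amplitude, and dark wound tissue separates from lighter
peri-wound skin across many consecutive levels.

### Per-level thresholding

Each level is binarized with Otsu's criterion, implemented from its
definition rather than delegated, because the optimizer operates on the
method's own normalized operators. With bin probabilities $p_i$ over $L=256$
equal-width bins on $[0,1]$, the threshold $t$ maximizes the between-class
objective

$$J(t) = \omega_0(\mu_0-\mu_T)^2 + \omega_1(\mu_1-\mu_T)^2,$$

scanning all $t \in \{1,\dots,L-1\}$ with mass in both classes; ties take
the smallest $t$, so the result is deterministic. The returned result
always satisfies the mixture identities $\omega_0+\omega_1 = 1$ and
$\omega_0\mu_0 + \omega_1\mu_1 = \mu_T$.

The objective is optimized on the histogram of $\bar T_p$ and the threshold
value $t/L$ is then applied to $\bar T_a$:

$$\Omega_1 = \{(m,n) \mid \bar T_a(m,n) \le t/L\}, \qquad
  \Omega_2 = \Omega \setminus \Omega_1.$$

This cross-application (optimize on the product operator, cut the additive
one) is the printed form of the method. It may well be a transcription slip
for thresholding $\bar T_p$ itself, so `threshold_target = "tp"` switches to
the self-application reading; `"ta"` is the default. On wound-like images
the two behave similarly because $|\bar T_a|$ is nearly monotone in
amplitude, which also makes the cross-applied threshold an amplitude cut.

### Contours, fusion, refinement

For each non-degenerate level the inner boundary of $\Omega_1$ is extracted
(pixels of $\Omega_1$ with a 4-neighbour in $\Omega_2$; positions outside
the frame count as $\Omega_2$), and the boundaries are accumulated into an
edge map counting, per pixel, how many levels' contours pass through it.
The refinement then:

1. keeps pixels supported by at least `min_support` levels (capped at the
   number of levels available), excluding the 1-pixel image frame;
2. closes the support with a disk of radius `morph_radius`;
3. fills holes;
4. drops components smaller than `min_component_area`;
5. selects the component with the lowest mean amplitude (the ulcer is the
   darkest region of these photographs; `component_select = "largest"` is the
   alternative rule).

The refinement defaults were calibrated on the phantom suite — only the
intent of this stage (accumulate contours, dilate/erode into a single
segment) is fixed by the method; its operators are a design choice. Two
choices deserve justification:

* **Support threshold and frame exclusion.** Accumulating *every* boundary
  pixel of *every* level and closing is fragile: pixel noise produces
  scattered single-level contour speckle which disk closing welds into large
  blobs, and any $\Omega_1$ region touching the border contributes the frame
  itself, which, closed against a nearby isoline, creates spurious closed
  regions that hole-filling floods. On the stress suite this collapses the
  mask to most of the image. Requiring two levels to agree (`min_support =
  2`) and ignoring frame-induced boundary pixels removes both failure modes
  while leaving genuine wound boundaries — crossed by many consecutive
  levels — intact.
* **Pre-smoothing.** A Gaussian blur of the amplitude image
  (`smooth_sigma`, default 1 px) before the sweep suppresses sensor noise at
  the source. It is the one neighbourhood operation in the pipeline; set
  `smooth_sigma = 0` for the strictly pointwise variant.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `r_min`, `r_max` | 0.013, 0.015 | — | sweep bounds of the frequency parameter; chosen so the critical amplitude crosses the lesion/skin range |
| `levels` | 30 | — | contrast levels in the sweep |
| `R` | 100 | px | major torus radius; damps the periodic ripple of the decomposition |
| `amplitude_offset` | 1 | gray levels | shift to the working amplitude range $[1,256]$ |
| `threshold_target` | `"ta"` | — | field the Otsu cut is applied to |
| `bins` | 256 | — | histogram resolution of the optimizer |
| `smooth_sigma` | 1 | px | Gaussian pre-smoothing; 0 disables |
| `min_support` | 2 | levels | contour agreement required for edge support |
| `morph_radius` | 5 | px | disk radius of the closing element |
| `min_component_area` | 0.5% of image | px | smallest surviving component |
| `component_select` | `"darkest"` | — | wound selection rule |
| `max_side` | 1024 | px | downscaling bound (bilinear) |
| `saturation_std` | 2 | gray levels | saturation warning floor |

## Degenerate inputs and numerical choices

* A level whose additive or product operator is identically zero cannot be
  normalized; it is skipped and logged, never fatal, so a 30-level sweep
  survives individual pathologies.
* A *constant-amplitude* image is rejected with an
  `all-levels-degenerate` error. Strictly, the toroidal fields of a constant
  image still vary through the coordinate ramps, and Otsu would happily
  threshold them — but the resulting partition reflects only the grid, not
  the image, so the pipeline declares every level degenerate rather than
  return a mask made of coordinate artifacts.
* A *near*-constant image (all channels saturated, as happens with
  overexposed clinical photographs) triggers a warning of class
  `torusseg_saturation_warning` and proceeds; saturation skews the threshold
  toward the bright mass and the result should be treated as unreliable.
* The threshold is a bin boundary: `t_value = t / bins`. Pixels exactly at
  `t_value` land in $\Omega_1$, matching the $\le$ convention of the
  partition; $\Omega_2$ is always the exact complement.
* Otsu ties (exactly equal $J$) are resolved at the smallest threshold.
  Adjacent thresholds whose objectives differ below double precision are
  numerically genuine ties; the test suite's exhaustive oracle treats any
  candidate within $10^{-9}$ of the maximum as tied.
* Batch evaluation reports the sample (n−1) standard deviation by default
  (`sd_type = "population"` switches), and undefined correlations (e.g. an
  empty mask) are counted as failures rather than propagated as `NA`.

## The phantom generator

No public wound-photograph corpus with ground truth is available to this
package, so testing rests on synthetic phantoms: a dark reddish ellipse
(default RGB (120, 30, 25), mimicking debrided stage-IV tissue) on a
skin-tone background (default (210, 170, 150)) with a ±10% horizontal
illumination gradient, optional Gaussian blurring of the lesion boundary
(blurred edges are what growing tissue looks like), optional bright
distractor disks (gauze-like objects), and additive Gaussian channel noise.
The ground truth is the ellipse raster fixed *before* blur and noise, so
degradation never moves the reference. `phantom_suite()` spans semi-axes
15–60 px, blur 0–8 px, noise 0–10 gray levels and 0–2 distractors, with blur
and noise each covering their range on an even grid and everything else
drawn under one seed.

Phantoms emulate the gross photometric structure of wound photographs — a
dark compact lesion, smooth lighter surroundings, mild shading, foreign
bright objects — but not skin texture, specular highlights, rulers and
markers, color casts, or irregular lesion shapes. Passing the phantom suite
therefore demonstrates the mechanics of the method under controlled
degradation, not clinical performance.

## Problem sizes used by the tests

The test suite and the acceptance script work at 256×256 pixels with the
default 30-level sweep; the stress suite holds 20 phantoms. These sizes give
each phantom a fully resolved lesion (thousands of pixels) while keeping a
complete run in tens of seconds; the pipeline itself is resolution-independent
and downscales larger photographs to `max_side` before processing.

On that configuration the package measures (see `scripts/acceptance.R`)
mask-vs-truth correlations around 0.93 on the stressed suite and above 0.95
on a sharp noiseless phantom.

## Known limitations

* Calibration of the refinement stage is phantom-based; real clinical images
  (texture, specularity, compression artifacts) may need a larger
  `smooth_sigma` or `min_support`.
* The method assumes the wound is the darkest sizable region; dark clothing,
  shadows, or hair in frame can capture the selection rule. `component_select
  = "largest"` is the fallback.
* Saturated images are warned about but not corrected; histogram-based
  thresholds are unreliable there.
* One connected component is returned; multi-focal wounds are not split into
  separate segments.
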