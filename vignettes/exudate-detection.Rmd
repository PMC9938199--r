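---
title: "Semicircular radial analysis for hard-exudate detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semicircular radial analysis for hard-exudate detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exuscan)
```

## The problem and the model

Hard exudates (HEs) are bright, yellowish lipid deposits with sharp margins
that appear on the retina early in diabetic retinopathy. On a color fundus
photograph they are best separated from the background in the green channel,
where their contrast against the retinal background is highest.

`exuscan` labels HEs pixel by pixel. The working image is the green channel
(configurable to L of CIELAB, Y of XYZ, or S of HSI), min-max normalized to
$[0,1]$. Around every pixel $p$ the full circle is partitioned into
$n_{\mathrm{semi}} = 8$ semicircular sectors $SC_i$ covering
$[(i-1)\pi/4,\, i\pi/4]$. Each sector is probed along $n_{\mathrm{dirs}} = 5$
directions at the midpoints of equal angular sub-intervals. Along a direction
with angle $\varphi$, intensities are sampled at radii
$r = r_0, r_0+1, \dots, r_1$ (defaults $r_0 = 4$, $r_1 = 25$ pixels), each
polar position rounded to the pixel grid. With $X(\cdot)$ the normalized
intensity, consecutive samples give differences

$$ df_n = X(px_n) - X(px_{n-1}), $$

and a direction is **non-constant** when some $df_n < 0$ with
$|df_n| > Th_1$ (both strict; default $Th_1 = 0.015$). A sector is an
**entrance area** when strictly more than $Th_2 = 2$ of its directions are
non-constant — evidence that the HE boundary crosses that sector. The pixel
is labeled HE when the entrance evidence spans enough sectors: by default,
when the longest circularly-consecutive run of entrance sectors is at least
$Th_3 = 3$.

Because the drop may occur at *different* radii in different directions, the
detected regions need not be circular or convex: the same mechanism finds
small round HEs and irregular ones. No vessel segmentation, illumination
correction, or denoising is performed beforehand; the method is applied to
the raw normalized channel.

### Parameters and their meaning

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `th1` | 0.015 | normalized intensity | minimum significant single-step drop |
| `th2` | 2 | directions | sector entrance needs `> th2` non-constant directions |
| `th3` | 3 | sectors | pixel decision threshold on consecutive entrance sectors |
| `r0`, `r1` | 4, 25 | pixels | radial search annulus |
| `n_semi` | 8 | — | sectors per circle |
| `n_dirs` | 5 | — | directions per sector |
| `step` | 1 | pixels | radial sampling step |

`th1`, `th2`, `th3`, `r0`, `r1` are the published operating point. The
published description never states how many directions each sector carries;
`n_dirs = 5` is this package's choice — `th2 = 2` with a strict `>` needs at
least 3 directions to be satisfiable at all, and 5 leaves margin. Detection
is monotone in all five thresholds (larger `th1`, `th2`, `th3`, `r0` shrink
the mask; larger `r1` grows it), and the test suite asserts those subset
relations exactly.

### The `th3` comparator and consecutiveness

The method's prose demands "more than" a threshold of sectors, but the
published parameter study exercises $Th_3 = 3$ as the *loosest* setting and
$Th_3 = 7$ as the strictest; with 8 sectors and a strict `>`, 7 would demand
all 8 sectors, contradicting the stated freedom that not all neighbor
regions must qualify. The default is therefore `at_least` (`run >= th3`),
with `strict_greater` available, and the consecutive-run reading (the text
says "several consecutive semi-circular regions") is the default with a
total-count alternative (`require_consecutive = FALSE`).

## Numerical choices

* **Coordinates.** 1-based `(row, col)` indices (the R convention), angle 0
  along +x (increasing column), counter-clockwise positive with +y pointing
  up (row decreasing). All modules share this convention.
* **Rounding.** Polar-to-grid rounding is half-away-from-zero,
  `floor(x + 0.5)`, not base R's banker's rounding: half-up rounding is
  translation-invariant for integer centers, which makes the rounded radial
  offsets center-independent and lets the per-pixel reference path and the
  vectorized production path agree bit for bit.
* **Duplicate collapse and truncation.** Consecutive radii that round to the
  same pixel are collapsed (keeping the first), so no difference is
  spuriously zero; sampling truncates at the first out-of-bounds position.
  Because the rounded offsets leave the image monotonically along a ray,
  truncation equals the NA-masking used by the vectorized path. Border
  pixels are scanned like any other; a direction with fewer than two
  in-bounds samples is trivially constant.
* **Normalization.** Per-image min-max on the extracted channel. The
  published account says only that normalization is applied; min-max is
  assumed because `th1 = 0.015` is only meaningful on a fixed $[0,1]$ scale.
  A constant image maps to all zeros (warning), which correctly yields an
  empty detection.
* **Boundary strictness.** Both inequalities of the drop condition are
  strict; a drop of exactly `th1` does not count. The acceptance suite pins
  this with dyadic values so the comparison is exact in floating point.
* **Ties in optic-disc selection.** Deterministic: higher brightest-ray
  mean wins, then smaller row, then smaller column.

## Two detectors, one contract

`detect_exudates()` is the production scan: for each direction the whole
image is shifted by the direction's rounded offsets, consecutive shifted
rasters are differenced, and sector counts and the circular-run rule are
evaluated as matrix operations. `detect_exudates_reference()` (and
`classify_pixel()`) is a deliberate straight-line transcription — per pixel,
per direction, per radius, explicit gathers and loops. The two paths share
only the center-independent offset tables; the acceptance suite requires
them to agree bit for bit on 25 seeded images. `classify_pixel()` also
exposes per-sector counts and entrance flags for debugging (reachable from
the CLI via `--debug-pixel row,col`).

## Optic-disc localization

The optic disc is the brightest circular structure in the image and the main
source of bright false positives, so it is localized and removed as
post-processing. The image is median-filtered (kernel 5, edge-replicated),
and a binary boundary map is taken by thresholding the Sobel gradient
magnitude (normalized by its maximum attainable response) at 0.1. For every
candidate center, the circle of the expected radius is divided into four
quarters of 8 rays each; a ray hits when an edge pixel lies within
$\pm 2$ px of the expected radius, a quarter passes at a hit fraction
$\ge 0.5$, and a center is a candidate only if all four quarters pass. The
expected radius is a per-dataset input (the published procedure measures it
manually); it defaults to 8% of the image width.

Candidate *centers* form contiguous blobs, and this package treats each blob
as one candidate *circle*: blobs are 8-connected components of passing grid
cells, and each circle's center is the ray-hit-count weighted centroid of
its cells. The published brightness rule then selects *between* circles: for
each candidate the maximum per-ray mean intensity over radii
$[0, r_{od}]$ on the smoothed image, highest value wins. An earlier reading
that ranked every passing center pixel independently mislocalized by 3–5 px,
because brightness is nearly flat across a blob and follows the background
gradient; the component reading localizes seeded synthetic scenes to the
exact center in 9 of 10 cases. The tenth picks a disc-sized, equally bright
lesion whose ring also passes candidacy — an intrinsic ambiguity of
brightness-based selection that the expected-radius prior cannot resolve
when lesion and disc sizes overlap. The exclusion mask is the selected disc
dilated by 2 px; subtracting it can only remove detections, never add them.

## What the synthetic scenes emulate — and what they do not

`generate_scene()` builds a 256×256 fundus-like phantom: a smooth background
(base 0.45, low-frequency drift ±0.08) emulating illumination gradients;
three dark curvilinear vessels (random smooth walks, width 2–4 px, Gaussian
cross-section, 0.2 deep) emulating the vascular tree; six bright lesions
with hard margins (star-convex radius profiles
$\rho(\theta) = m\,(1 + \sum_{k\le4} a_k \cos(k\theta + \psi_k))$,
$\sum|a_k| \le 0.3$, radii 5–20 px, contrast 0.10–0.30) emulating HEs of
varied shape; one bright disc (radius 20 px, contrast 0.3, 2 px soft rim)
emulating the optic disc; and additive Gaussian noise (sd 0.01) clipped to
$[0,1]$ and quantized to 8 bits. Lesions are painted as flat plateaus at
(local background maximum + contrast) so that *every* margin crossing drops
by at least the lesion's contrast in one step — the contract that makes
detector tests meaningful, self-verified by ray tracing in noise-free
scenes. Components draw from sub-seeds of the scene seed, so disabling
vessels does not move the lesions.

Not emulated: retinal texture, vessel branching and central reflex,
hemorrhages and microaneurysms, camera vignetting, color accuracy. Lesions
occlude vessels where they overlap (real vessels run anterior to exudates);
this keeps the margin contract exact. A green test on these scenes
establishes that the implementation realizes the stated decision rule and
its geometry — it does not establish clinical performance on real fundus
photographs.

## Known limitations

* **Noise sensitivity of the printed operating point.** With `th1 = 0.015`
  applied to raw consecutive differences and no smoothing (the method
  explicitly performs none), pixel noise of sd $\sigma$ produces difference
  noise of sd $\sqrt{2}\sigma$, further amplified by min-max normalization,
  and each direction takes ~21 independent chances to cross the threshold.
  At $\sigma = 0.01$ nearly every direction becomes "non-constant" and the
  detector saturates (≈98% of pixels fire). The operating point therefore
  presupposes noise well below `th1` — plausibly true of in-camera-smoothed
  fundus photographs, not of $\sigma = 0.01$ synthetic noise. This is why
  the synthetic-recovery acceptance criterion, which fixes $\sigma = 0.01$,
  is red in this package's suite: the implementation is faithful, and the
  stated world and stated targets are mutually inconsistent.
* **Patch IoU against pixel-exact truth.** Even noise-free, the detector
  marks a 1–2 px halo outside small lesions (rays from just outside still
  cross the far margin within $[r_0, r_1]$) and misses an interior rim of
  large lesions (when $2\rho + r_0 > r_1$, near-edge interior pixels see no
  boundary inside the annulus). Both effects pull per-patch IoU below the
  0.8 cutoff against pixel-exact masks, although the detected set tracks
  the lesions well visually. Published headline numbers for this family of
  methods are computed against coarse human annotations, which are far more
  forgiving of a few-pixel halo.
* **Vessel-adjacent false positives.** A dark vessel edge is also a radial
  intensity drop; pixels within roughly 5–15 px of a vessel can accumulate
  three consecutive entrance sectors and fire. The consecutive-run rule
  suppresses distant vessels but not nearby ones.
* **No TIFF input.** The offline R stack provides PNG and JPEG codecs only;
  the image reader supports those two formats.

## Evaluation protocol

`evaluate_masks()` tiles the image into 32 px patches (ragged edges kept),
marks a patch ground-truth positive when it contains any truth pixel, and
scores it true positive when the in-patch IoU exceeds 0.8 (strict). A
truth-negative patch is a false positive if the prediction places *any*
pixel in it — the strictest reading of "false positive", chosen because the
published definition covers only correct exudate patches. Sensitivity is
$TP/(TP+FN)$, specificity $TN/(TN+FP)$; both the pooled-patch and per-image
averages are reported by the acceptance machinery since the published
account does not fix the unit of averaging. The both-empty patch IoU is
defined as 1; such patches are truth-negative with an empty prediction, so
the convention never touches a score.
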