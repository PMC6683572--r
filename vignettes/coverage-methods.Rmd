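---
title: "Color-threshold coverage quantification: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-threshold coverage quantification: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coverquant)
```

## The measurement model

`coverquant` quantifies how much of an image is covered by an object of
interest — a crop canopy over soil, leaves or washed roots on a scanner bed,
green versus senescent tissue of a potted plant, callus tissue on a petri
plate — by classifying every pixel independently of its neighbours. The user
*samples* a handful of representative shades from the images themselves. Each
sampled shade becomes a **channel** of a **selection**: up to 10 *include*
channels describe the measured object, and up to 10 *ignore* channels
describe foreign material (netting, plot labels, blanked regions) that
belongs to neither object nor background.

A pixel $p$ is "near" a channel color $q$ when the squared color measure is
strictly below the squared global tolerance $t$:

* **RGB metric**: $(r_1-r_2)^2 + (g_1-g_2)^2 + (b_1-b_2)^2 < t^2$
* **YCbCr metric**: $(Cb_1-Cb_2)^2 + (Cr_1-Cr_2)^2 + (Y_1-Y_2)^2/9 < t^2$

where $Y$ is luminance and $Cb$, $Cr$ the chroma components. Dividing the
luminance term by 9 makes the YCbCr metric concentrate on hue: one sampled
shade covers a whole brightness range of the same color balance, which is why
it usually needs fewer channels and lower tolerances than RGB.

Each pixel gets exactly one of three labels — FOREGROUND (near an include
channel), IGNORED (near an ignore channel), BACKGROUND (near neither) — and
with $N$ total pixels, $C$ foreground, $I$ ignored and $B = N - C - I$:

$$\text{coverage \%} = \frac{100\,C}{N - I} = \frac{100\,C}{C + B},
\qquad
\text{area} = \frac{C}{(\mathrm{DPI}/2.54)^2}\ \text{cm}^2 .$$

Ignored pixels are excluded from both numerator and denominator, which is
what makes netting or labels disappear from a coverage estimate rather than
diluting it. The area formula needs a physical scale: scanners embed it
(integer pixels-per-meter in the BMP header; `dpi = ppm × 0.0254`), cameras
do not, and the package then refuses to print an area rather than invent one.

The method is deliberately **per-pixel**: no morphology, connected
components, or spatial smoothing. Its statistical validity comes not from
perfect segmentation but from *uniformity* — one selection, one tolerance,
one metric applied to an entire image set, so the (subjective) color choice
biases every image identically and between-image comparisons remain fair.
Both batch drivers enforce this: every result row records the selection's
content hash, and a subset/total ratio refuses to run when the two
selections disagree on metric or tolerance.

## Parameters that matter

* **tolerance** (unitless, in squared-measure units of 8-bit channel
  values; default 35): the single most consequential knob. Too low leaves
  genuine object pixels unclassified (under-segmentation); too high bleeds
  into the background. The RGB metric typically needs values around 30–40,
  YCbCr substantially less for the same coverage. Choose it by inspecting
  `render_mask_overlay()` output at a few candidate values, then freeze it
  for the whole set.
* **metric** (`"rgb"` or `"ycbcr"`): RGB when brightness differences carry
  information; YCbCr when shading/illumination varies within one hue class.
  The YCbCr conversion is full-range ITU-R BT.601 (the JPEG convention),
  kept as reals and clamped to [0, 255]. The original Windows binary never
  documented its variant; this is our documented choice, not a claim of
  bit-identity with that binary.
* **conflict policy** (`"nearest"`, default): the published description
  never says what happens when a pixel is within tolerance of both an
  include and an ignore channel. We resolve by nearest measure, with exact
  ties going to IGNORED — conservative in the sense that it never inflates
  coverage. The policy is switchable (`"ignore-wins"`, `"include-wins"`) so
  behaviour could be matched against the original tool if it ever resurfaces.
  One nuance follows from the default: under `"nearest"` the foreground
  count is monotone in tolerance except on exact ties; the
  foreground-to-ignored flip that makes $C$ non-monotone arises under
  `"ignore-wins"` (both behaviours are property-tested).
* **dpi** (dots per inch, > 0): read from BMP metadata; an explicit value
  always wins; anisotropic embedded resolution (axes differing > 0.5%) is
  an error unless overridden, because the area formula assumes square
  pixels.

## What the synthetic fixtures emulate — and what they do not

No reference image sets are deposited with the original publication, so the
package generates its own, with ground truth exact by construction:

* `make_calibration_grid()` — the quality-control sheet: a 2 × 2 array of
  0.5 cm squares at 254 DPI is exactly 10 000 dark pixels = 1 cm²,
  reproducing the published self-check of the area formula (254 DPI is used
  because 1 cm is then exactly 100 px; at 300 DPI the answer is exact only
  up to integer-pixel quantization).
* `make_complex_calibration()` — a non-convex blob whose foreground count is
  exactly `round(target_cm2 · (dpi/2.54)²)`; the silhouette varies with the
  seed, the count never does.
* `make_two_phase_plant()` — green plus yellow-brown tissue with an exact
  pixel split, for senescence ratios and green/total escape rates.
* `make_canopy_plot()` — green canopy over soil with optional netting and a
  plot label in the ignore palette.

Pixels are perturbed by independent uniform integer jitter of amplitude $a$
per channel. Truth remains exact at tolerance $t$ whenever
$\sqrt{3}a < t < D - \sqrt{3}a$, with $D$ the minimum RGB distance between
base shades of different classes; the generators assert this window, so a
green test certifies the *pipeline*, not a lucky noise draw.

Two deliberate calibrations of the stated world:

* Class palettes are generally spaced far apart (≥ 100 RGB units) so that
  typical tolerances sit between the noise and confusion regimes.
* The canopy fixture includes one minority "dry litter" soil shade at
  distance ≈ 48 from the nearest canopy green. With jitter $a = 10$
  ($\sqrt{3}a ≈ 17.3$) the truth-faithful window is ≈ (17.3, 31.1): the
  calibrated tolerance 30 recovers truth exactly, tolerance 10 misses
  roughly half of the jittered canopy (severe under-segmentation, much worse
  under RGB than YCbCr), and tolerance 40+ starts absorbing litter-toned
  soil (over-segmentation). This reproduces, qualitatively, the published
  tolerance-sweep behaviour; no quantitative sweep figure exists to match.

What the fixtures do **not** emulate: scanner optics, specular highlights,
shadows, color gradients within an organ, JPEG artifacts. A green test
therefore establishes correctness of classification, counting, calibration
and batch plumbing — not that any particular real-world selection is a good
one, which remains the operator's judgement.

## Numerical choices and degenerate inputs

* The tolerance inequality is **strict** (`< t²`), exactly as printed in the
  original formulas; tolerance 0 classifies nothing, and the boundary case
  (measure exactly $t^2$) is excluded. Tests pin this with an exact integer
  boundary (distance² = 1225 = 35²).
* YCbCr components are kept as reals (no 8-bit re-quantization) before the
  measure, avoiding artifacts at tolerance boundaries; scalar and vectorized
  paths use identical elementwise expressions so they agree bit-for-bit
  (deliberately avoiding BLAS reductions, whose rounding may differ).
* `n == i` (every pixel ignored, e.g. an image fully blanked with an ignored
  color) yields a flagged `NA` coverage — an explicit `status` column entry,
  never a silent zero, and never an abort mid-batch.
* Both printed coverage forms, $100C/(N-I)$ and $100C/(C+B)$, are evaluated
  and asserted identical on every call.
* Coordinates are 0-based, half-open, top-left origin — the dominant raster
  convention, stated explicitly because the original publication never picks
  one.
* Selection files are small JSON documents serialized with 17 significant
  digits so a saved tolerance round-trips to the exact same double.
* CSV output prints percentages/areas/ratios to 2 decimals (matching the
  precision of the published area tables) while full precision is retained
  in returned data frames; result rows are sorted by path so repeated runs
  are byte-identical.

## Known limitations

* Only uncompressed 24-bit BMP is decodable. The original workflow routed
  every input through MSPaint to 24-bit BMP anyway; in this environment no
  PNG/TIFF/JPEG decoder is available to R, so other formats get an explicit
  conversion error instead of silent degradation.
* No statistical testing of results: the tool produces per-image quantities;
  downstream comparisons belong to a statistics package.
* Per-object splitting (several leaves on one sheet analyzed separately) is
  done by cropping or blanking per object, not by connected components —
  per-pixel semantics are the point, not a limitation we intend to lift.
* The published inter-tool validation against ImageJ on real Teff scans is
  not reproducible here (those scans are not deposited); the calibration
  fixtures above replace it as the accuracy evidence.
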