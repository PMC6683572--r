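# coverquant

Color-threshold coverage and area quantification for plant phenotyping
images.

## The problem

Many visual plant traits reduce to "how much of this image is covered by
*that*": ground cover by a wheat canopy photographed from above, projected
surface area of scanned leaves or washed roots, the senescent (yellow-brown)
share of a potted plant, the green-escape fraction of transformed callus on
a petri plate. `coverquant` answers these questions with a deliberately
simple, fully scriptable model: the analyst samples a few representative
pixel shades, and every pixel of every image is then classified
independently by color similarity — no morphology, no machine learning, no
per-image hand tuning. The subjectivity of the color choice is tamed by
*uniformity*: one saved selection, one tolerance, one metric applied to the
whole dataset, so any segmentation bias hits every image identically and
between-image comparisons stay statistically meaningful.

## The model

A **selection** holds up to 10 *include* channels (shades of the measured
object), up to 10 *ignore* channels (foreign objects: netting, labels,
blanked regions), a metric and one global tolerance *t*. A pixel is near a
channel color when the squared measure is strictly below *t*²:

* RGB: `(r1-r2)² + (g1-g2)² + (b1-b2)² < t²`
* YCbCr: `(Cb1-Cb2)² + (Cr1-Cr2)² + (Y1-Y2)²/9 < t²`

(the /9 de-emphasizes brightness, so YCbCr tracks hue across shading; RGB
needs higher tolerances). Each pixel gets one label — FOREGROUND, IGNORED or
BACKGROUND — and with N pixels, C foreground, I ignored, B = N − C − I:

```
coverage % = 100·C / (N − I) = 100·C / (C + B)
area (cm²) = C / (DPI / 2.54)²        — needs embedded or explicit DPI
```

Canonical input is uncompressed 24-bit BMP, whose header carries the
scanner's pixels-per-meter resolution (`dpi = ppm × 0.0254`).

## Worked example

No reference images are deposited anywhere, so the package ships generators
for ground-truthed synthetic scenes. Here: a 320 × 240 canopy plot with 30%
green cover over soil, plus white/orange netting and a black plot label to
be ignored.

```r
library(coverquant)

fx <- make_canopy_plot(cover_fraction = 0.3,
                       artifacts = c("netting", "label"), seed = 42)
write_raster(fx$raster, "plot1.bmp")

sel <- fixture_selection(fx, include = "canopy",
                         ignore = c("net_white", "net_orange", "label_black"),
                         name = "canopy-2026")       # tolerance 30, rgb
save_selection(sel, "canopy.json")

res <- analyze_image(read_raster("plot1.bmp"), sel, id = "plot1.bmp")
print(res)
#> <coverage_result> plot1.bmp: coverage 30.00%, area NA cm^2 [ok]
str(res$counts)
#> List of 4
#>  $ n: num 76800
#>  $ c: num 21199
#>  $ i: num 6138
#>  $ b: num 49463
```

Of 76 800 pixels, 6138 (netting + label) are ignored and drop out of both
numerator and denominator; 21 199 of the remaining 70 662 are canopy, i.e.
30.00% ground cover — the generator's truth is 30.0006%. The area is `NA`
with status `ok` because a field photo has no DPI; only percentages are
physically meaningful for it. A scanned calibration sheet does carry DPI:

```r
qc <- make_calibration_grid(seed = 1)   # 2x2 of 0.5 cm squares @ 254 dpi
qsel <- fixture_selection(qc, include = "square", ignore = "paper")
print(analyze_image(qc$raster, qsel, id = "qc-sheet"))
#> <coverage_result> qc-sheet: coverage 100.00%, area 1.00 cm^2 [ok]
```

The 2 × 2 array of 0.5 cm squares measures exactly 1 cm² — the standard
self-check of the DPI-based area calibration.

Batch work uses the same objects (`run_batch()`, `run_ratio_batch()` for
subset/total ratios and between-date senescence deltas,
`write_results_csv()`), or the CLI:

```sh
inst/cli/coverquant classify --selection canopy.json --out results.csv plots/*.bmp
inst/cli/coverquant ratio --selection total.json --subset-selection yellow.json \
    --late late/*.bmp --out senescence.csv early/*.bmp
inst/cli/coverquant inspect --selection canopy.json plot1.bmp
```

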