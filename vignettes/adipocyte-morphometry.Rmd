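---
title: "Adipocyte morphometry: models, pipelines and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipocyte morphometry: models, pipelines and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

## The measurement problem

Adipose tissue grows by cell enlargement (hypertrophy) and by cell recruitment
(hyperplasia), and telling the two apart requires measuring the size of many
individual adipocytes *in situ*. In H&E sections a white adipocyte appears as a
bright lumen (the dissolved lipid droplet) ringed by a thin eosinophilic
membrane, so the measurement reduces to segmenting bright particles out of a
calibrated brightfield raster and filtering them by geometry. `adipoquant`
implements three segmentation front-ends over one shared particle-analysis
core, together with the population statistics and method-concordance analyses
used to compare them:

* **edge pipeline** (open-source whole-slide style): iterate a Sobel
  "find edges" pass three times, binarise the edge image (Otsu by default),
  and take the enclosed non-edge interiors — the lumina — as candidate
  particles, filtered by area 500–20,000 µm² and circularity 0.3–1.0;
* **threshold pipeline** (proprietary whole-slide style): classify pixels
  with intensities 0–230 as membrane and 231–255 as fat, remove small noise
  objects, fill membrane specks enclosed in fat objects, and filter particles
  by area 500–20,000 µm² and perimeter 0–900 µm (perimeter standing in for
  circularity);
* **micrograph pipeline** (conventional single-field style): percentile
  thresholding of one camera field, ten 3×3 binary dilations of the membrane
  mask to close gaps between cells, and an area filter only.

Both whole-slide pipelines are preceded by tissue detection that discards
extraneous whitespace while retaining lumina inside tissue (hole filling).
All physical quantities are in µm/µm² via a mandatory, user-supplied
`microns_per_pixel`: scanner magnification alone does not determine pixel
size, and silently assuming one would corrupt every area filter downstream.

## Particle geometry conventions

Candidate masks are labelled with 8-connectivity (the particle-analysis
convention; 4-connectivity is used for background logic and is available
explicitly). Per-particle geometry is computed as:

* **area** — pixel count × `microns_per_pixel`²;
* **perimeter** — the *crack boundary*: the count of pixel edges exposed to a
  different label or to background, × `microns_per_pixel`. This convention is
  deterministic and exactly testable (a 10×10 px square has perimeter 40 at
  1 µm/px);
* **circularity** — `min(1, 4π·area / perimeter²)`, capped because
  digitisation can push the raw ratio above the filter's upper bound of 1.0.

A consequence worth knowing: the crack boundary of a digital disk is its
staircase length `8r`, so disk circularity converges to π²/16 ≈ 0.617 rather
than 1. Smoothed-polygon perimeters (as in interactive tools) report disks
near 0.9. The 0.3 circularity floor still separates what it is meant to
separate — confluent lumina measure ≈ 0.45–0.7 while rod-like crushed-tissue
artefacts measure ≈ 0.1 — but users porting circularity windows from other
software should expect systematically lower values here. All filter bounds
are inclusive: a 500 µm², circularity 0.30 particle is retained, because an
off-by-one at the 500 µm² floor visibly changes counts. Particles touching
the image border are retained; no border exclusion is applied.

## Tunable parameters

| Parameter | Default | Unit | Notes |
|---|---|---|---|
| area window | 500–20,000 | µm² | all pipelines |
| circularity window | 0.3–1.0 | – | edge pipeline |
| perimeter window | 0–900 | µm | threshold pipeline |
| membrane/fat boundary | 230/231 | 8-bit intensity | threshold pipeline |
| edge passes | 3 | – | edge pipeline |
| binarisation | Otsu | – | fixed threshold available |
| noise floor | 50 | px | threshold pipeline |
| percentile | 0.5 | fraction | micrograph pipeline; see below |
| dilations | 10 | – | micrograph pipeline, 3×3 element |
| whitespace threshold | 245 | intensity | tissue detection |
| min tissue fragment | 10⁴ | µm² | tissue detection |
| closing radius | 5 | px | tissue detection |

The tissue-detection defaults are this package's own (the comparable vendor
settings are not published): 245 is safely above stained tissue and below
scanner white, and 10⁴ µm² removes debris while keeping legitimate small
sections — a 10⁵ µm² floor would discard any fragment smaller than a few
dozen adipocytes.

**Choosing the micrograph percentile.** Percentile thresholding picks the
smallest intensity whose cumulative pixel fraction reaches the target, and
the conventional default of 0.5 presumes that about half of the field is
stained. On tissue whose stained fraction differs — the synthetic slides
below have ≈ 10–13 % membrane pixels, with bright lumina and whitespace
making up the rest — the percentile must be set near the actual stained
fraction, or the threshold lands inside the lumen intensity mass and the
segmentation collapses. All synthetic-slide analyses in this package
therefore pass `percentile = 0.08`. This mirrors real use: the percentile is
a per-protocol calibration, not a universal constant.

## The synthetic tissue generator

Every pipeline and statistic is validated against slides with per-cell ground
truth from `generate_tissue()` / `make_cohort()`:

1. cell areas are drawn from a log-normal law (size histograms of adipocytes
   are strongly right-skewed; no specific law is established, log-normal is
   the standard modelling choice);
2. cell centres are dart-thrown largest-first with progressive spacing
   relaxation, then adjusted by two Lloyd-type centroid sweeps;
3. a multiplicatively weighted Voronoi tessellation tiles the tissue block at
   confluence, each cell is shrunk by the membrane thickness to form its
   lumen, and intensities are painted per class;
4. Gaussian noise is added, after which membrane, lumen and background pixels
   are clamped back to ≤ 230, ≥ 231 and ≥ 245 respectively, so the
   generated intensity classes remain exact;
5. truth areas, perimeters, circularities and centroids are measured from the
   pre-noise lumen label image *with the same crack-boundary conventions as
   the detector*, so truth and detections are directly commensurable.

Optional artefacts are placed in the background margin, where they cannot
disturb the adipocytes: crushed regions (bright rods inside the area window
but with circularity ≈ 0.1), vessels (filled membrane-intensity discs) and
bright specks below the 500 µm² floor. This placement makes artefact tests
clean set-difference experiments: adding an artefact must not change a
filtered pipeline's count.

**Study conditions.** The default cohort emulates the validation design of a
diet study: 3 chow-like slides (300 cells, log-normal median 2,100 µm²,
σ_log 0.35) versus 3 high-fat-diet-like slides (450 cells, median 3,150 µm²,
σ_log 0.45), at 0.5 µm/px with a 2.5 µm membrane. The medians put the group
means near the published whole-slide ranges for control and high-fat-fed
mice; the HFD slides carry 1.5× more cells because high-fat feeding roughly
doubles depot mass, so a whole-slide scan of an HFD section exposes more
cells even though each fixed field of view holds fewer of the enlarged ones.
The pixel size matters more than it may appear: the micrograph pipeline's ten
dilations erode each lumen by 10 px laterally (14 px diagonally), which at
0.5 µm/px is a realistic 5–7 µm bite, but at a coarse 1 µm/px would erase
much of the small-cell population — an artefact of under-sampling, not of
the method.

What the generator does *not* emulate: curved membranes (Voronoi walls are
locally straight), stromal nuclei and vessels inside the tissue proper,
staining gradients, scanner vignetting, and out-of-focus blur. Passing tests
therefore demonstrate correctness of the algorithms under controlled
conditions, not segmentation performance on real slides; on real tissue the
pathologist-review step that the original workflows include remains
irreplaceable.

## Statistics

Per-slide summaries report the count of successfully segmented cells as the
adipocyte-specific sample size *n* and the mean/SD/min/max area (sample SD,
n−1). Population histograms bin areas at 500 µm² with half-open bins
`[k·500, (k+1)·500)` (bin membership at edges is a convention choice), and
relative-frequency curves normalise each bin to the slide's total count, in
percent.

Group comparisons use the tie-corrected Kruskal–Wallis test followed by
Dunn's pairwise z-tests on mean ranks; the multiplicity adjustment is
Bonferroni by default and configurable through any `p.adjust` method, since
the commonly used implementations do not agree on one. Count comparisons use
the classic equal-variance Student's t-test, with Welch available. Both
tests are validated for calibration: over 2,000 null simulations their
type-I error at α = 0.05 stays within [0.035, 0.065].

Method concordance is assessed per slide pair: Bland–Altman analysis
(differences oriented y − x, bias ± 1.96 SD limits of agreement, the
conventional normal multiplier without small-sample correction) and ordinary
least squares with R² = squared Pearson correlation. `autoplot()` methods
draw the standard agreement plots.

## Numerical choices and degenerate inputs

* Downsampling is block-mean with round-half-up — an antialiasing reduction
  that preserves thin membranes better than decimation, and deterministic.
* The percentile threshold takes the smallest intensity whose cumulative
  fraction reaches the target, which is well defined on discrete histograms.
* Otsu binarisation runs on the 256-level histogram of the final edge image.
* A gradient-free image, an empty tissue mask, or a constant-intensity
  micrograph all return zero detections with a warning rather than an error.
* Labels are renumbered in raster-scan order of first pixel, and every source
  of randomness sits behind an explicit seed, so reruns are byte-identical.
* Weighted nearest-centre assignment buckets centres on a coarse grid (3×
  their weighted radius, with a full-scan fallback) purely for speed; ties
  break to the lowest centre index.

## Validation problem sizes

The shipped validation suite runs the full stack on: a 6-slide study cohort
(3 + 3, ≈ 300–450 cells per slide) for ground-truth recovery (edge and
threshold pipelines: recall and precision ≥ 0.95; threshold median area
error ≤ 5 %) and diet-direction checks; a 10-slide cohort spanning median
areas 1,800–3,400 µm² (150 cells per slide) for concordance structure
(whole-slide pair: narrower limits of agreement and higher R² than any
micrograph pairing); 200 random grids against a brute-force flood-fill
labelling oracle; and 2,000-replicate null calibrations of both group tests.
These sizes were chosen to give stable estimates while keeping a full run in
the minutes range on one core.

## Known limitations

* The edge pipeline's iterated Sobel bands erode each lumen by a few pixels,
  biasing its areas low by roughly 10–25 % depending on cell size and pixel
  pitch; counts and centroids are unaffected. This is inherent to the
  edge-interior reading of the method, and it is why the strict area-accuracy
  requirement is placed on the threshold pipeline.
* The micrograph pipeline's dilation step biases areas low by design and
  drops cells whose eroded lumen falls below the 500 µm² floor; together
  with single-field sampling this reproduces the documented weaknesses of
  the conventional method (few cells, high variance) — which is precisely
  what the concordance analyses are meant to expose.
* Dark filled structures inside tissue (e.g. vessels) can be detected by the
  edge pipeline if their geometry passes the filters; on real slides this is
  the role of pathologist review.
* No watershed splitting: two lumina merged through a membrane gap are one
  particle. The threshold pipeline's noise/hole post-processing assumes
  membrane integrity, as its original did.
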