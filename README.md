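# adipoquant

Adipocyte morphometry from calibrated brightfield histology images.

Distinguishing adipose hypertrophy (bigger fat cells) from hyperplasia (more
fat cells) requires measuring the size of many individual adipocytes *in
situ*. In H&E sections each white adipocyte is a bright lumen ringed by a
thin stained membrane, so the task is particle analysis on a calibrated
raster: segment bright lumina, measure area `A = n_px · s²` (with `s` the
pixel size in µm), perimeter `P` by the crack-boundary convention, and
circularity `C = min(1, 4πA/P²)`, then keep particles with
`A ∈ [500, 20 000] µm²` and, depending on pipeline, `C ∈ [0.3, 1.0]` or
`P ∈ [0, 900] µm`.

`adipoquant` implements three segmentation front-ends over one particle
engine, for the three ways this measurement is done in practice:

* **edge** — whole-slide, open-source style: 3 iterated Sobel "find edges"
  passes, binarisation (Otsu), enclosed non-edge interiors as particles,
  area + circularity filters;
* **threshold** — whole-slide, intensity-classification style: membrane
  = intensities 0–230, fat = 231–255, noise removal and hole filling,
  area + perimeter filters;
* **micrograph** — conventional single camera field: percentile
  thresholding, 10 binary dilations of the membrane to close gaps, area
  filter.

On top sit per-slide summaries (cell count *n*, mean ± SD area), 500 µm²
area histograms with relative-frequency curves, group tests (Kruskal–Wallis
with Dunn post-hoc; Student's t for counts), and method concordance
(Bland–Altman bias and 95 % limits of agreement `bias ± 1.96·SD(diff)`;
OLS regression with R²). A seeded synthetic H&E-like tissue generator with
per-cell ground truth (weighted Voronoi lumina, dark membranes, whitespace,
optional crushed/vessel/speck artefacts) makes the whole stack testable
end to end. Results are tibbles; fitted objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

Simulate one slide with known truth, detect tissue, run the threshold
pipeline, and summarise:

```r
library(adipoquant)

s   <- generate_tissue(tissue_spec(n_cells = 120, seed = 42))
tis <- detect_tissue(s$image)
det <- segment_threshold(s$image, tissue = tis)

head(det, 3)
#>   pipeline  label area_um2 perimeter_um circularity
#> 1 threshold     1    3400.          247       0.700
#> 2 threshold     2    1836.          197       0.595
#> 3 threshold     3    1573.          186       0.571

summarize_slides(det)
#>   pipeline  n_cells mean_area_um2 sd_area_um2 min_area_um2 max_area_um2
#> 1 threshold     120         2200.        863.          649        5293.

score_detections(det, s$truth, s$image$microns_per_pixel)
#>   n_truth n_detections n_matched recall precision median_abs_rel_area_error
#> 1     120          120       120      1         1                         0
```

Every one of the 120 simulated adipocytes is found exactly once
(recall = precision = 1) and each detected area matches its ground truth
(median relative error 0): the threshold pipeline recovers the simulated
tissue perfectly, and the summary row is the slide-level record — cell
count as sample size, mean area 2,200 µm² — that downstream group
statistics consume. `area_histogram(det)` bins the same detections at
500 µm² (first populated bins: 7, 17, 33, 21 cells at 500–2,500 µm²,
relative frequencies 5.8/14.2/27.5/17.5 %), and for a two-method comparison
on matched slides:

```r
ag <- method_agreement(summaries, "edge", "threshold")
glance(ag$bland_altman)   # bias, SD, 95% limits of agreement
glance(ag$regression)     # slope, intercept, R^2
autoplot(ag$bland_altman)
```

A command-line front-end (`inst/cli/adipoquant.R`) exposes `simulate`,
`segment`, `summarize`, `compare` and `run` subcommands over the same
functions; `run_study()` orchestrates a whole cohort from one JSON
configuration into detection CSVs, summaries, histograms, agreement
reports and an indexing `report.json`.

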