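# pbtrack

Simulation and analysis of **tumor tracking with integrated-mode proton
radiography**. Lung tumors move with breathing; in pencil-beam-scanning
proton therapy that motion both degrades the delivered dose and interacts
with the sequential scanning of the beam. A radiograph formed from the
treatment beam itself — measured as the residual range of each pencil beam
in a monolithic scintillator viewed by cameras — offers a markerless way to
watch the tumor move. `pbtrack` implements that measurement chain as a
fully synthetic, tested pipeline for medical-physics researchers studying
image-guided particle therapy:

* **Scene** — geometric thorax and PMMA-slab phantoms with
  relative-stopping-power (RSP) materials, a periodic 1-D motion model, and
  exact water-equivalent-thickness (WET) line-integral queries
  (WET = path length × RSP along the ray).
* **Acquisition** — timestamped scan patterns (serpentine horizontal and
  vertical rasters, outside-in spiral, interleaved multi-pass), Gaussian
  pencil beams decomposed into sub-rays, an analytic Bragg depth–light
  curve with range–energy relation R₀ = αE₀ᵖ, top/lateral/distal camera
  views with cos⁴ vignetting and seeded noise.
* **Signal** — vignetting correction, pristine-peak extraction per camera
  column (distal 80% falling edge), depth-to-WET conversion
  WET = R₀ − d·RSP_scint.
* **Reconstruction** — weighted Gaussian back-deposition of per-beam WET
  samples into per-frame 2-D WET radiographs, timestamped at the median
  beam.
* **Tracking** — the strip-wise Otsu analysis: 11 strips perpendicular to
  the motion, per-strip thresholds, union of foregrounds, largest connected
  component, binary centroid, and per-frame comparison with the programmed
  motion summarized as MAE ± σ.
* **Artifacts** — scan-pattern interplay study on the slab phantom,
  quantifying shape distortion by the eccentricity
  e = √(1 − (minor/major)²) of the moment ellipse.

## Worked example

Track a 30 mm insert moving 20 mm peak-to-peak with a 24 s period over a
9 × 5 cm field (1.4 s per frame, 5 mm spot spacing):

```r
library(pbtrack)

cfg <- experiment_config(insert_diameter = 30, amplitude = 20, period = 24,
                         n_frames = 5, seed = 42)
res <- run_experiment(cfg)
res
#> <tracking_result> 5 frames tracked (0 excluded): MAE = 0.08 +/- 0.03 mm

glance(res)
#> # A tibble: 1 × 4
#>   mae_mm sigma_mm n_tracked n_excluded
#>    <dbl>    <dbl>     <int>      <int>
#> 1 0.0770   0.0290         5          0

tidy(res)
#> # A tibble: 5 × 6
#>   frame_index timestamp measured_mm expected_mm abs_error_mm tracked
#>         <int>     <dbl>       <dbl>       <dbl>        <dbl> <lgl>
#> 1           1     0.700      -9.89       -9.83        0.0575 TRUE
#> 2           2     2.10       -8.59       -8.53        0.0605 TRUE
#> 3           3     3.50       -5.99       -6.09        0.0974 TRUE
#> 4           4     4.90       -2.89       -2.84        0.0518 TRUE
#> 5           5     6.30        0.670       0.788       0.118  TRUE
```

Each frame's *measured* offset is the centroid of the segmented insert
relative to the field centre; the *expected* offset is the programmed
displacement at the frame's median-beam timestamp, re-centred to its time
mean. Here the simulated tracking error is about 0.1 mm — an idealized
detector with perfect optics and alignment, so well inside the millimetre
accuracy reported for physical systems. `autoplot(res)` plots measured vs
expected position over time; `autoplot(frames[[k]])` renders a WET frame
when `run_experiment(..., keep_frames = TRUE)` is used.

Supporting pieces:

```r
field_for_insert(30, 20)   # 90 50  (mm; the 9 x 5 cm study field)
max_beams_crossing(10, 5)  # 4     (beams that can cross a 10 mm tumor)
run_artifact_study()       # per-pattern, per-frame ellipse fits
```

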