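# ciliamotion

Quantification of ciliary beating from high-speed video of airway
epithelial surfaces.

Multiciliated cells clear mucus from the airway by coordinated,
directional ciliary beating. Recordings of a stained epithelial surface
(50 or 125 frames per second, a field of view of roughly 210 × 170 µm
containing 15 or more ciliated cells) carry two quantities this package
measures:

* **Ciliary beat frequency (CBF)** — estimated per pixel by FFT spectral
  analysis of each pixel's intensity trace (linear detrend, Hann window,
  zero padding, band-limited peak picking with a scale-invariant
  inclusion rule), summarized as the mean over included pixels. Healthy
  human tracheal epithelium beats at about 12 Hz.
* **Beat direction / beat axis** — one angle per ciliated cell,
  estimated from the structure tensor of the temporal-difference
  motion-energy image (the axis) and the temporal asymmetry of the
  fast power stroke versus the slow recovery stroke (which half-line
  of the axis). When the asymmetry is not discernible — short or
  damaged cilia — the cell is reported in axis (π-periodic) mode, as an
  analyst would.

Field-level coordination is summarized with circular statistics: each
angle θ becomes a unit vector *v* = cos θ + *i* sin θ; the mean
resultant length is *R* = |(1/N) Σ v<sub>j</sub>| and the circular
standard deviation is *S* = √(−2 ln R). *S* near zero means lockstep
beating; values above 1 mean a disorganized surface. Axial data use the
standard angle-doubling convention. Rose-diagram histograms (sector
area ∝ count) are produced for both modes.

Because patient videos of this assay are generally not shareable, the
package includes a synthetic video generator: fields of beating cilia
rendered as pivoting filaments with planted per-cell direction,
frequency and metachronal phase, written as multi-page 16-bit TIFF with
a JSON ground-truth sidecar. Every estimator in the package is
validated by recovering those planted parameters.

## Worked example

Simulate a well-coordinated field under default study conditions
(420 × 340 px ≈ 210 × 170 µm, 20 cells, 250 frames at 125 fps, beat
frequencies ~12 Hz, von Mises directions with κ = 400) and run the full
pipeline:

```r
library(ciliamotion)

cfg <- simulation_config(
  seed = 7,
  direction_distribution = list(mean_angle_rad = deg2rad(60),
                                concentration = 400))
report <- run_pipeline(pipeline_config(cfg, mode = "direction"))
report
#> RunReport
#>   mean CBF: 12.43 Hz (median 12.45, 5033 px)
#> CircularSummary (direction): n = 16, mean = 61.5 deg, R = 0.9894, S = 0.1461
#>   warnings:
#>    - 4 of 20 cells flagged (ambiguous power-stroke direction)
```

Reading the output: the per-pixel spectral analysis found 5033 pixels
with a genuine oscillation and their mean beat frequency, 12.43 Hz,
recovers the planted ~12 Hz. Sixteen of the twenty cells yielded an
unambiguous power-stroke direction; their mean direction (61.5°)
recovers the planted 60°, and the circular standard deviation
S = 0.146 is the near-lockstep regime expected at κ = 400 (planted
dispersion ≈ 0.05 plus a few degrees of per-cell measurement error).
The four ambiguous cells are reported, not silently dropped. With
`output_dir` set, the run also writes `report.json`, `angles.csv`,
`rose.csv`, `cbf_pixels.csv`, a rose-diagram PNG and the echoed
`config.json`.

A disorganized field — `concentration = 1` — run the same way yields
S above 1, the contrast that separates damaged from healthy epithelium.

A command-line front end with subcommands
`simulate | cbf | direction | stats | rose | run` is installed at
`system.file("scripts", "ciliamotion-cli.R", package = "ciliamotion")`.

## Package layout

* `R/simulate.R`, `R/vonmises.R`, `R/ground_truth.R` — synthetic field
  generator and ground-truth I/O
* `R/spectral.R` — per-pixel CBF estimation (`cbf_map()` and its
  building blocks)
* `R/motion.R` — per-cell axis/direction estimation and manual-angle
  ingestion
* `R/circstats.R` — circular statistics and rose diagrams
* `R/video.R`, `R/pipeline.R` — TIFF/JSON/CSV I/O and the end-to-end
  `run_pipeline()`
* `vignettes/ciliary-motion-analysis.Rmd` — the methods vignette: model
  assumptions, parameter defaults and their rationale, validation
  design, limitations
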