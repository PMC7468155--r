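---
title: "Quantifying ciliary beat frequency and beat direction from high-speed video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ciliary beat frequency and beat direction from high-speed video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliamotion)
```

## The measurement problem

Multiciliated cells of the airway epithelium propel mucus by coordinated,
directional ciliary beating. High-speed video of a stained epithelial
surface (typically 125 frames per second over a field of view of roughly
210 × 170 µm holding 15 or more ciliated cells) gives access to two
quantities per sample:

* the **ciliary beat frequency** (CBF), around 12 Hz in healthy human
  trachea, read from the temporal oscillation of pixel intensities; and
* the **beat direction** of each ciliated cell — or, when the
  power-stroke side cannot be discerned (short or damaged cilia), the
  **beat axis**, the same line without an arrowhead.

The dispersion of per-cell directions across a field quantifies the
*disorganization* of the epithelium: a healthy surface beats in near
lockstep, while damaged epithelium (after irradiation, or regenerating
after tracheotomy) shows cells beating every which way.

`ciliamotion` implements the complete measurement chain: per-pixel FFT
spectral estimation of CBF, per-cell direction/axis estimation from
motion energy, circular statistics with rose-diagram output, and — since
raw patient videos of this kind are generally not shareable — a synthetic
video generator with planted ground truth, so that every estimator in
the chain is validated by parameter recovery.

## Circular statistics

Each cell contributes one angle $\theta_j$. The angles are mapped to
unit vectors in the complex plane,

$$v_j = \cos\theta_j + i\,\sin\theta_j,$$

the **mean resultant length** is the modulus of their average,

$$R = \left|\frac{1}{N}\sum_{j=1}^{N} v_j\right| \in [0, 1],$$

and the **circular standard deviation** is

$$S = \sqrt{-2\ln R}.$$

$R = 1$ (hence $S = 0$) iff all angles coincide; $R \to 0$ sends
$S \to \infty$, and the package reports `Inf` rather than erroring when
$R$ is numerically zero (e.g. three angles 120° apart), because a
downstream report must still be produced. $R$ within a few ulp of 1 is
snapped to exactly 1 so that perfectly aligned data give $S = 0$ rather
than the square root of a rounding residue.

```{r circ-example}
summarize_angles(angle_set(deg2rad(c(10, 25, 17, 9, 21, 14, 12, 20,
                                     16, 11, 23, 19, 15, 13, 18)),
                           mode = "direction"))
```

**Axial data.** An axis is $\pi$-periodic: $\theta$ and $\theta + \pi$
are the same observation. All axial statistics use the standard
angle-doubling device: $R$ and $S$ are computed on $2\theta_j$ (which
are $2\pi$-periodic), and the mean axis is the doubled-angle circular
mean halved back into $[0, \pi)$. The reported axial $S$ is therefore
the doubled-angle dispersion and is not numerically comparable to a
directional $S$ on the same cells; the summary carries a `mode` field
for this reason.

No small-sample bias correction is applied to $S$; the quantity is the
plain plug-in estimator, which is how it is conventionally reported for
this assay. Sets with fewer than 15 angles are accepted with a warning,
since dispersion on very few cells is unstable.

**Rose diagrams** bin the angles into uniform half-open sectors
(`[edge, edge + width)`, an angle exactly on an edge going to the higher
bin; the implementation adds a relative epsilon of 10⁻⁹ before flooring
so that degree/radian round-trips do not drop edge angles into the
lower bin). The default width of 15° gives 24 direction bins or 12 axis
bins, a sensible granularity at the typical 15–30 cells per field.
Plots draw sector radius proportional to $\sqrt{\text{count}}$ so that
sector *area* is proportional to count.

## Spectral CBF estimation

Every pixel's intensity trace is processed identically:

1. **Linear detrend** — removes offset and slow drift (focus, lamp,
   slow intensity decay) that would otherwise leak into low-frequency
   bins.
2. **Hann window**, then **zero padding** to the next power of two at
   least twice the trace length. A 2-s recording at 125 fps has a native
   resolution of 0.5 Hz; padding interpolates the peak position to
   ~0.24 Hz bins.
3. **Periodogram peak** inside a physiological band, default **3–30 Hz**
   — wide enough to bracket the ≈12 Hz human airway CBF with margin on
   both sides, while excluding sub-3-Hz drift. The band must lie below
   the Nyquist frequency (half the frame rate); the map refuses bands
   that reach it, and undersampled beats appear aliased (a 12 Hz beat
   "recorded" at 20 fps shows up at 8 Hz — the package cannot and does
   not unfold aliases).
4. **Inclusion rule**: a pixel enters the field summary only if its
   in-band peak exceeds `min_power_ratio` (default 30) times the median
   in-band power. The rule is scale-invariant, which makes the whole
   map invariant under affine intensity rescaling of the video. The
   default is calibrated from the null: the maximum of a ~50–110-bin
   noise periodogram is routinely 4–6× its median, so small ratios
   admit large numbers of noise pixels; at 30× the expected number of
   false inclusions is a few per megapixel, while genuinely beating
   pixels exceed the threshold by orders of magnitude.
5. **Fundamental preference**: the reported frequency is the *lowest*
   in-band local maximum with at least `fundamental_ratio` (default
   0.4) of the peak power. Pixels near the tip of a cilium are swept
   briefly twice per cycle; their spectra carry strong power at twice
   the beat frequency, and for duty cycles near one half the
   fundamental is notched below the harmonic. Without this guard a few
   percent of pixels lock to $2f$ and bias the arithmetic mean CBF
   upward by several tenths of a Hz.

The field summary is the arithmetic **mean over included pixels** (the
conventional "mean CBF"), with the median reported alongside; both are
`NA`, never a crash, when no pixel passes inclusion (e.g. a noise-only
video).

## Beat direction and axis from motion energy

The automated estimator reproduces what an analyst measures by hand on
the playing movie, one angle per ciliated cell, on circular ROIs
(automatic segmentation is out of scope; ROIs come from the simulation
ground truth or a user CSV).

**Axis.** Consecutive frames are differenced, isolating moving cilia
from static background. The per-pixel sum of squared differences over
time — the motion-energy image — traces the streak each cilium sweeps.
The axis is the principal orientation of that image: gradients of the
Gaussian-smoothed amplitude image (σ = 1.5 px; finite-difference
gradients on pixel-thin filaments are rotationally biased by 10° or
more without smoothing) are accumulated into a 2 × 2 structure tensor,
and the axis is perpendicular to the dominant gradient orientation.
The tensor's normalized eigenvalue contrast is reported as an
anisotropy in [0, 1]; a static ROI yields a flagged-absent axis, not an
error. Because ROIs of neighbouring cells overlap on crowded epithelia,
all ROI statistics are weighted by a Gaussian taper (σ = half the ROI
radius) so the centre cell dominates.

Angles follow the mathematical convention throughout: counterclockwise
from the +x image axis with y increasing upward. Rotating a video by
90° rotates every estimate by 90°, and mirroring reflects it (both are
tested properties).

**Direction.** The axis leaves a two-fold ambiguity; the power stroke
resolves it. Two independent signals are combined:

* *Temporal asymmetry*: the power stroke is the fast phase of the beat
  cycle, so intensity transitions it causes are large and brief while
  recovery transitions are small and sustained. For each
  high-motion-energy pixel the cubed magnitudes of rising and falling
  temporal derivatives are summed after zeroing derivatives below 3×
  the robust (MAD-based) noise floor; the asymmetry score is the median
  of per-pixel rise/fall log-ratios, folded to ≥ 1. The median resists
  the minority of pixels where several desynchronized cilia superpose,
  and the noise threshold keeps sensor noise from diluting the ratio
  toward 1. A time-symmetric beat scores exactly 1.
* *Distal side*: a cilium pivots about its basal body, so motion energy
  sits distally while time-averaged intensity sits proximally; the
  offset between the two centroids, projected on the axis, marks the
  tip side.

A direction is reported only when the asymmetry score reaches
`asymmetry_threshold` (default 1.2); otherwise the cell is flagged
ambiguous and the caller falls back to axis mode — exactly the fallback
an analyst makes for short cilia whose power stroke cannot be seen. The
pipeline falls back to axis statistics for the whole field when more
than half the cells are ambiguous, and records the event in the run
report.

## The synthetic video generator

The generator's defaults emulate the recording conditions of the assay:
a 420 × 340 px field at 0.5 µm/px (≈210 × 170 µm), 20 non-overlapping
ciliated cells (above the 15-cell measurement minimum), 250 frames at
125 fps (2 s), beat frequencies normal with mean 12 Hz and cell-to-cell
sd 0.5 Hz, truncated to stay positive and below Nyquist.

**Kinematics.** The beat cycle is an asymmetric triangular angular
waveform: deflection sweeps from +A to −A during the power stroke (a
fraction `power_stroke_fraction`, default 0.3, of the cycle) and
returns during the recovery. The pivot is modelled in the *vertical*
plane containing the beat direction, and the video renders the top-view
projection: each cilium appears as a bright segment lying along its
cell's beat direction whose projected length oscillates — extending
fast during the power stroke, retracting slowly during recovery. This
projection is what overhead microscopy of a pivoting cilium actually
shows, and it makes the three estimator contracts simultaneously
satisfiable: the rendered filament lies along the planted angle (axis
recovery), the fast stroke transports distal mass toward the planted
direction (direction recovery), and a symmetric split
(`power_stroke_fraction = 0.5`) leaves extension and retraction
statistically indistinguishable (the ambiguity contract).

**Coordination structure.** Per-cell directions are von Mises draws
(`concentration` κ; κ = 0 is uniform — the sampler is a Best–Fisher
rejection implementation, written here because no installed package
provides circular distributions). A metachronal phase gradient (default
0.1 rad/µm along the beat direction) staggers beat timing across the
field, and a per-cilium phase jitter (default 0.8 rad) desynchronizes
cilia within a cell. The jitter matters beyond realism: with all of a
cell's cilia rendered as exact phase clones, their superposition is
almost static frame-to-frame and the cell's interior carries no motion
energy — a degenerate texture no real recording shows.

**Rendering and noise.** Cilia are rendered as anti-aliased segments by
bilinear splatting of fixed sample points (spacing ≈0.5 px) whose
masses follow the current projected extension; deposited intensity is
≈1 unit per pixel of filament, scaled by `cilium_intensity` (150) on a
constant `background_level` (100), with additive Gaussian noise
(`noise_sd`, default 15 — 10 % of peak signal) and clamping at zero.
The fixed-sample scheme keeps the advancing tip a smooth sub-pixel ramp;
resampling the segment each frame would inject sub-pixel jitter that
dominates temporal derivatives. There is no photobleaching, no mucus,
no hydrodynamic coupling, and the background is featureless. Passing
recovery tests on these fields therefore demonstrates estimator
correctness under the modelled conditions — moving-filament geometry,
metachronal timing, Gaussian noise — not robustness to out-of-focus
layers, debris, drift, or flickering illumination in real recordings.

Identical configuration and seed give bit-identical videos and ground
truth; the per-cell ground truth (centers, directions, frequencies,
phases) round-trips through JSON at 17 significant digits, i.e.
losslessly for doubles.

```{r sim-example, eval = FALSE}
sim <- simulate_field(simulation_config(seed = 7))
report <- run_pipeline(pipeline_config(
  simulation_config(seed = 7), mode = "direction", output_dir = "run7"))
report
```

## Validation design and problem sizes

Every estimator is tested by recovery against planted truth. The
statistical core is additionally checked against an independent
brute-force complex-arithmetic oracle on a thousand random angle sets
(agreement to 10⁻¹²), and von Mises sampling against the Bessel-ratio
closed form $S_\infty(\kappa) = \sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}$.

The recovery suites run on full-size 20-cell fields. CBF recovery uses
2-s recordings; the treated-vs-control contrast (planted frequencies
scaled by 0.85) is run *paired* — same seed, hence identical cell
placement and scaled-identical frequency draws — because at 20 cells an
unpaired comparison confounds the planted 15 % effect with ±1.3
percentage points of sampling noise. The organization contrast
(κ = 400 vs κ = 1) uses 1-s recordings and 20 replicate seeds per
condition; the ordering of the two dispersions is required on every
seed, and the absolute levels (S below 0.15, above 1.0) on the medians,
since the sampling sd of S on a single 20-cell field is substantial at
κ = 1. With 20 estimated cells an S of ~0.1 for a κ = 400 field is
expected even for a perfect field: roughly 0.05 of planted dispersion
plus ~5° of per-cell measurement error.

## Known limitations

* ROIs are user- or ground-truth-supplied circles; no cell detection.
* The direction statistic needs several beat cycles and a visible
  fast/slow contrast; beats with `power_stroke_fraction` near 0.5, very
  low SNR, or heavily overlapping cells fall back to axis mode.
* The per-pixel spectral analysis reports one dominant frequency; it
  does not decompose mixtures within a pixel, and it cannot recover
  beats above Nyquist (aliases are reported as such).
* The axial circular SD is the doubled-angle convention; compare axial
  S only with axial S.
* The generator is a geometric, not hydrodynamic, model: no fluid
  coupling, no cilium bending, no mucus load. It is a test harness for
  estimators, not a physical simulation of ciliary propulsion.
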