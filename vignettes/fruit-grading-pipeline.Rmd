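---
title: "Methods: glove-style fruit grading from pressure and vision sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glove-style fruit grading from pressure and vision sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitglove)
```

## The problem

Harvest workers judge fruit ripeness by eye and by touch, with large
worker-to-worker variability. A glove instrumented with fingertip pressure
sensors, finger-bend sensors, a palm camera pair and a laser pointer can
grade a fruit non-destructively while the worker simply points at it and
grasps it: turgor pressure (the pressure difference between the interior of
the plant cells and barometric pressure) proxies firmness and hence
ripeness, while the camera and laser measure the fruit's projected area and,
under a spherical model, its volume.

`fruitglove` implements that grading computation as plain software. All
hardware is replaced by a synthetic scene/sensor simulator that produces the
same kinds of inputs (images with a projected laser dot, multi-finger
pressure traces, noisy calibration tables) together with machine-readable
ground truth, so every stage of the pipeline can be scored.

## Sensor calibration

Four transfer functions map raw sensor readings to physical quantities.

* **Pressure transducer** (fingertip probe): the manufacturer transfer
  function `P0 = ((X - A) / 0.064290) * 0.101972` with `X` the output
  tension in volts and `A` the 0.2 V offset; 0.101972 converts kPa to
  kgf/cm². The probe assembly is then linearly calibrated against a bench
  gauge, `P = 0.83 P0 - 0.02`. The negative intercept means near-zero
  readings can map slightly below zero; these are returned unclamped so the
  caller can distinguish "no contact" from noise.
* **Force sensitive resistor** (FSR): resistance falls with force following
  an inverse power law, and the calibrated transfer function is
  `P = 3.29 x^-2.061` (kgf/cm², `x` in volts). A degree-2 polynomial fit
  (`0.0802 x² - 0.77 x + 2.606`) is retained for comparison; on FSR-style
  data the power form fits better, which `fit_model()` reproduces.
* **IR distance sensor**: `D = 2736.24 adc^-0.9909` cm, with a 5–25 cm
  activation range that gates the vision pipeline.
* **Finger-bend sensor**: a linear map between the ADC readings of the
  fully closed and fully open hand. The angular endpoints are a pure
  convention (the hardware defines only the two postures); the package
  defaults to closed → 0°, open → 180°, both configurable.

Fits are ordinary least squares (`stats::lm`); power laws are fitted on the
log–log scale, the standard "power regression", and the coefficient of
determination is always reported on the original scale so that functional
forms are comparable.

### The sphere-diameter spline

Wrapping a finger around a sphere relates the bend reading to the sphere's
diameter. The calibration passes an interpolating **natural cubic spline**
(`stats::splinefun(method = "natural")`) through the four reference points
(readings 887, 859, 826, 809 against diameters 25, 50, 100, 150 mm). The
spline family is a design choice: the natural cubic interpolant is the
simplest curve through four points, and it reproduces the recorded bench
diameters at readings between the knots to within a millimetre — eight of
the nine recorded bench rows to 0.01 mm. The ninth bench row (reading 812)
is inconsistent with any smooth interpolant through the calibration points
(its recorded diameter corresponds to a reading near 810); the package
reports the spline value and the validation table keeps the row so the
discrepancy stays visible. Readings outside the knot span are clamped to it
and flagged rather than extrapolated: a cubic spline diverges quickly
outside its support.

## Geometry

The camera is an ideal pin-hole: focal length in pixels
`f = (width/2) / tan(FOV/2)`, principal point at the image centre, 0-based
pixel coordinates. Three depth sources are supported, in order of
preference:

1. **Laser triangulation.** The laser beam runs parallel to the optical
   axis at baseline `H`, so the projected dot appears `f H / Z` pixels from
   the principal point; inverting gives `Z = f H / offset`. With the
   glove's short baseline this is accurate only in a small working range
   (3–7.3 cm by default, kept as configuration constants), outside which
   the estimate is flagged.
2. **IR sensor**, within its 5–25 cm activation range.
3. **Stereo**, `Z = f H / (xL - xR)` on a rectified pair, computed by block
   matching only inside a *moving fovea* window centred on the laser dot —
   restricting the expensive disparity search to the object of interest.

**Distance-invariant area.** A segmented object of `a_CI` pixels at depth
`Z` yields `t = a_CI Z² / f²`, which no longer depends on the distance (the
projection's image-inversion sign is dropped; areas are magnitudes). For an
ideal pin-hole camera with `f` in pixels and `Z` in cm, `t` is numerically
the physical area in cm², so the default configuration uses the identity
conversion. Real optics need a calibrated polynomial on top:
`eq_area_default_coefficients` stores the original bench camera's cubic
(its constant term read as −3.95·10⁻¹; raw negative outputs near `t = 0`
are clamped to zero and flagged), and `fit_area_calibration()` /
`simulator_area_calibration()` re-enact the bench procedure — circles of
known size, least-squares polynomial of degree 2 — for any other camera.

Under the spherical-fruit assumption the projection is a circle, so
`r = sqrt(A/π)` and `V = (4/3) π r³`.

**RGB+NIR fusion** assumes the object of interest is planar at known depth:
every NIR pixel is then displaced from its visible counterpart by the
stereo shift `f H / Z`, and the fused 4-channel image keeps R, G, B
unchanged while resampling the I channel under that shift (linear
interpolation along the row; out-of-bounds columns get I = 0 and a flag).

## Laser-seeded segmentation

The user points the laser at the fruit; segmentation must extract exactly
the pointed object from an unstructured scene.

* **Dot detection** scores each pixel by redness `s = R - max(G, B)` and
  takes the argmax subject to `s ≥ 60` and `R ≥ 200` (8-bit defaults,
  configurable), with ties broken deterministically by smallest `(y, x)`.
  Because the dot is a blob several pixels wide, the argmax quantizes its
  position; `refine_dot()` takes the redness-weighted centroid of the
  blob's neighbourhood, and the pipeline uses that sub-pixel position for
  triangulation (a one-pixel error on a ~20 px offset would otherwise cost
  ~5% in depth and ~10% in area).
* **Seeds and TTL.** Each detected dot becomes a seed. While the hand
  moves, seeds are carried between frames by pyramidal Lucas–Kanade
  optical flow (window half-width 7, 3 pyramid levels, iterative
  refinement). Every seed carries a time-to-live, decremented once per
  frame, so spurious or stale seeds expire; the default TTL of 30 frames
  (~1 s of video) is a package choice, as is everything about the flow
  implementation except its contract: small rigid translations must be
  recovered to within half a pixel.
* **Fuzzy-connectedness growing.** A pixel joins the object if some
  4-connected path from a seed has min-link affinity at least `theta`,
  with Gaussian link affinity
  `mu(p,q) = exp(-(I(p)-I(q))² / (2 sigma²))` on per-channel mean
  intensity. Because the path criterion is a max–min, membership is
  equivalent to reachability over links whose intensity step is at most
  `sigma * sqrt(-2 log(theta))`, and the implementation is a vectorised
  frontier flood fill over exactly those links — identical output,
  linear-time. Defaults `sigma = 25` grey levels and `theta = 0.7` admit
  steps up to ~21 grey levels: comfortably above the neighbour differences
  produced by noise of sd 10 inside a uniform fruit, comfortably below a
  fruit/background contrast of ~77. `theta = 1` degenerates to the seed
  pixels themselves; masks are monotone (non-increasing) in `theta`, and
  all live seeds always lie inside the mask.

## Grading

* **Grasp events.** An event is a maximal interval where the maximum
  pressure across fingers exceeds `on_kPa` (default 20, the bottom of the
  ripe band) for at least `min_duration_s` (default 1 s). The per-finger
  plateau is the median over the middle 80% of the event, trimming the
  rise/release ramps.
* **Valid fingers.** Fingers that did not seat properly on the fruit read
  markedly low; a finger is kept when its plateau is at least half
  (`ratio = 0.5`) of the event's maximum plateau, and the grasp pressure
  is the mean of the valid fingers' plateaus — robust to one or two
  low-contact fingers.
* **Ripeness bands.** `p < 20` kPa → inadequate (fruit too soft to be
  consumable); `20 ≤ p ≤ 100` → ripe; `p ≥ 150` → unripe. The literature
  ranges leave 100–150 kPa unassigned; the package reports it as an
  explicit "ripening" class rather than silently extending a neighbour.
  The documented unripe band tops out at 400 kPa; higher readings remain
  "unripe" with an out-of-range flag rather than erroring, since sensor
  excursions above the band carry the same decision. Classification
  thresholds are variety-specific in practice (a 200 kPa line separates
  ripe from unripe tomatoes, for example) and live in configuration.
* **Quality score.** Each available feature (pressure, area, volume) is
  normalized to `[0, 1]` by a triangular membership — 1 at the centre of a
  user-supplied ideal range, 0 at its limits — and combined as a weighted
  mean. The membership shape is a package choice: the simplest
  unimodal normalizer with an interpretable "ideal band". The score is
  invariant to uniform weight rescaling, and an alert (the glove's
  vibration motor, here a boolean) fires when it drops below a
  configurable threshold.

## The simulator

`render_scene()` rasterizes the spherical fruit as a filled disk of pixel
radius `f R / Z` (the spherical-projection model the geometry assumes),
paints the laser dot as a saturated red blob at its exact triangulated
offset on the centre row, optionally renders the NIR partner frame under
the planar shift, and adds Gaussian noise. `simulate_trace()` builds
per-finger pressure pulse trains (raised-cosine ramps, amplitude
`turgor × contact quality`, additive noise, truncation at zero), and
`simulate_calibration()` samples a known transfer function on an even grid
with multiplicative noise — multiplicative because bench sensor error
scales with the reading, while image and trace noise are additive. All
generators are pure functions of their spec: the same seed gives identical
bytes.

**Simulator camera.** The default simulator camera is 320×240 with
`f = 100` px and a 1.0 cm laser baseline. This departs from the physical
glove's VGA/48° cameras deliberately: a 4 cm-radius fruit at 4 cm distance
cannot fit a 48° frame at all, and the study conditions (radius 2–4 cm,
distance 4–7 cm) must render whole fruit with the laser dot on them. The
chosen focal length and baseline keep the fruit inside the frame and the
dot offset (14–25 px) within even the smallest fruit's pixel radius, while
staying in the laser's 3–7.3 cm trusted range.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: real fruit are textured, specular, shaded and
only approximately spherical; scenes contain clutter, occlusion and other
red objects that could defeat the brightest-red dot rule; lenses distort
(the package keeps a no-op hook where undistortion would run); and real
turgor readings drift with contact area and operator force. The simulator
establishes that the *computation* is correct under its own geometric
model, not that the physical system achieves the same accuracy.

## Problem sizes and numerical choices

The test suite and the accuracy study run at 320×240 resolution with 20
scenes (disk radius 2–4 cm, Z 4–7 cm, noise sd 10 grey levels) and fit the
area conversion from 10 rendered calibration circles — sizes chosen so the
whole study re-runs in seconds while leaving each estimate's error well
inside the bands being checked. Other numerical choices: natural boundary
conditions for the bend spline; log–log OLS for power fits with r² on the
original scale; dot-detection ties broken by raster order; clamped (never
extrapolated) spline evaluation; negative areas clamped to zero with a
flag; integer block-matching disparity with ties to the smaller disparity;
JSON reports serialized at fixed precision so identical runs are
byte-identical.

## Worked example

```{r example}
cfg <- default_pipeline_config()
cfg$area_model$coefficients <- simulator_area_calibration()

scene <- render_scene(scene_spec(radius_cm = 3, Z_cm = 6, noise_sd = 10,
                                 seed = 17))
grasp <- simulate_trace(trace_spec(turgor_kPa = 250, seed = 17))

report <- run_measure(image = scene$rgb, trace = grasp$trace, config = cfg)
report
```

A 3 cm fruit at 250 kPa turgor: the report recovers the pressure within a
few kPa, classifies it unripe, and the volume lands within a few percent of
the true `(4/3)π·3³ ≈ 113.1` cm³.

## Known limitations

The laser working range (3–7.3 cm) is kept as a configuration constant
rather than derived from `f`, `H` and the image width, since it does not
follow from simple triangulation with the stated parameters. The grading
score's membership shape and the per-fruit grasp aggregation (mean of
valid-finger plateau medians across events) are package conventions.
Segmentation assumes a single connected object under the laser dot;
multi-object scenes and learning-based segmentation are out of scope.
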