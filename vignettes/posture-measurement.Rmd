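---
title: "Measuring sitting posture from fiducial markers and wearable accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sitting posture from fiducial markers and wearable accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturekit)
```

## The measurement model

`posturekit` quantifies seated posture with three angles, all in degrees.

**Craniovertebral angle (CA).** Three square fiducial markers are taped
over the ear tragus, the C7 spinous process and the acromion, and a single
camera views the subject's left sagittal plane in portrait orientation.
Each marker is detected per frame and reduced to the centroid of its four
corners. With $(x_{C7}, y_{C7})$ and $(x_{tr}, y_{tr})$ the C7 and tragus
centroids, the CA is the unsigned angle between the C7-to-tragus vector
and the horizontal unit vector $(1, 0)$:

$$\mathrm{CA} = \arccos\!\left(\frac{\Delta \cdot (1,0)}{\lVert\Delta\rVert}\right),
\qquad \Delta = (x_{tr} - x_{C7},\; y_{C7} - y_{tr}).$$

Image rows grow downward, so the vertical component is flipped to an
up-positive frame before the angle is taken: a tragus *above* C7 gives a
positive elevation and a tragus directly above C7 gives exactly 90. The
implementation uses `abs(atan2(dy, dx))`, which is algebraically identical
to the arccos form on $[0, 180]$ but has no cancellation near the
horizontal; the test suite holds the two routes together to $10^{-9}$
degrees.

**Shoulder angle (SA).** Measured the same way at the acromion, toward the
upper-body landmark. The field is not unanimous on that second landmark:
the visualisation convention this system follows draws the horizontal
through the lower neck and shoulder markers, which fixes the ray as
acromion-to-C7, but acromion-to-tragus also appears in the forward-head
literature. We adopt **acromion-to-C7 as the default** and expose
`sa_convention = "acromion_to_tragus"` throughout (`process_stream()`,
`render_posture_frame()`), so the choice is explicit and testable rather
than baked in.

**Kyphosis angle (KA).** Two accelerometers are worn on the back, over
T1/T2 (alpha) and T12/L1 (beta). Each 1 Hz sample's tilt is derived from
the gravity vector as

$$\theta = \operatorname{atan2}\!\left(a_x, \sqrt{a_y^2 + a_z^2}\right),$$

the inclination of the sensor's X-axis from the horizontal plane, and
$\mathrm{KA} = \alpha + \beta$. We use this form rather than
$\arcsin(a_x / g)$ because it is invariant to the vector's magnitude, so a
few percent of calibration error in $\lVert a \rVert$ perturbs the angle
only mildly and can never throw the function out of its domain. Forward
flexion of a sensor's X-axis is positive, so a kyphotic back gives
positive alpha and beta. No filtering, drift correction or static-offset
calibration is applied: the wearable this models specifies a 0.2-degree
inclination accuracy, and the composition of two such errors is already
well inside the clinical decision margins below.

## Classification

A sample is labelled **forward head posture (FHP)** when CA < 48, and
**hyperkyphotic** when KA > 40; SA > 54 is the compensatory-shoulder
criterion. All inequalities are strict, so boundary values classify as
non-pathological. The sources state the CA and SA criteria independently
and never say how they jointly decide a single sample, so `posturekit`
makes CA the deciding head criterion — it is the definitional measure of
FHP, while the SA reflects a secondary muscular adaptation — and reports
the SA exceedance as a corroborating flag. A strict-conjunction mode
(`posture_criteria(fhp_mode = "ca_and_sa")`) is available, and the mode in
force is recorded in every exported report.

## The fiducial system

No fiducial detector exists in this package's R dependency stack, so
`posturekit` ships its own complete square-binary-marker system, patterned
after the 4x4, 50-marker dictionaries common in marker-based tracking: a
one-cell black border around a 4x4 payload. The 50 codes are fixed
constants chosen (once, by a deterministic greedy search) so that the four
rotations of every marker are distinct and any two markers differ by at
least 4 bits in every relative rotation; decoding therefore requires an
exact match and cannot confuse two IDs. Detection binarises the frame at
gray level 0.5, labels connected dark components (`EBImage::bwlabel`),
fits a quadrilateral to each candidate's convex hull, samples the 6x6
cell grid, verifies the all-black border and decodes the payload in all
four rotations. Detection is stateless: every frame is processed
independently, with no temporal smoothing or tracking, so a lost marker
never contaminates neighbouring samples — the property that motivates
fiducial tracking over point-tracking software that drifts and needs
manual re-seeding.

The centroid of the four corners, not the corners themselves, carries all
downstream geometry, and the centroid is invariant to corner order and
unbiased under symmetric pixel quantisation. On the reference geometry
(300 px landmark baselines) a half-pixel centroid error bounds the angle
error near 0.14 degrees, comfortably inside the 1-degree recovery
tolerance the tests enforce.

## Pairing the two sensor streams

The two wearables are wireless and carry independent clocks, and no
synchronisation behaviour is specified for them, so `pair_streams()` uses
nearest-neighbour pairing: for each upper-back timestamp the nearest
mid-back sample within 0.5 s (half the nominal sample period) is taken.
Unmatched seconds become `partial` samples that keep alpha but have no
KA; nothing is interpolated. Sensors that expose a pre-computed tilt
instead of raw acceleration are accepted through an alternative CSV
dialect (`t_s, tilt_deg`).

## The synthetic generator

`generate_protocol()` produces every input the pipeline consumes, from
known ground truth: frames rendered so the marker centroids realise a
requested CA/SA exactly (the inverse of the measurement geometry), and
unit-norm acceleration streams whose tilt equals the requested alpha/beta
plus seeded Gaussian noise. Its defaults reproduce the reference
validation protocol: forward head posture with kyphosis (CA 40, SA 55,
KA 45 split as alpha 25 + beta 20) held for 120 s, a 5 s linear
transition, then neutral posture (CA 55, SA 50, KA 20 split as alpha 12.5
+ beta 7.5) to 240 s, at 1 Hz, with 0.2-degree sensor noise — the
wearable's specified accuracy. The 45/20 KA set-points are published;
their alpha/beta split is not, so the generator uses the 25 + 20 and
12.5 + 7.5 splits fixed by the validation targets. Linear interpolation
across the transition is a modelling choice: the reference protocol
repositions the subject by hand over about five seconds without
specifying a trajectory.

Pixel geometry is likewise unpublished (the physical setup states a 1 m
camera distance and 1 cm^2 markers): the generator defaults to a
1080 x 2048 portrait canvas with 300 px landmark baselines and 40 px
markers — proportions that put the markers at roughly the scale a webcam
at that distance would see, and comfortably above the detector's minimum
size. All of these are parameters, not claims about anthropometry.

What the generator does **not** emulate: lighting variation, occlusion,
marker rotation out of plane, perspective distortion, skin and clothing
motion, marker detachment, or sensor drift. Passing the synthetic
recovery tests therefore demonstrates that the geometry, decoding and
statistics chain is correct, not that the system is robust to real-world
capture conditions; the published agreement of the physical prototype
with an established 2D motion-analysis tool (Pearson r from 0.607 to
0.992 across angles and postures) rests on physical recordings that are
not reproducible on a desk.

## Reporting and agreement statistics

Sessions aggregate per started minute into the five box-plot numbers, with
quartiles by linear interpolation between order statistics (R's quantile
type 7, recorded in the report metadata); histograms use 1-degree bins.
Method agreement between a candidate and a reference series uses Pearson
r with a two-tailed t-test and the qualitative cutpoints conventional in
rehabilitation measurement (|r| at least 0.90 very high, 0.70 high, 0.50
moderate, below that low), plus MAPE reported as a fraction — 0.05 is the
"excellent agreement" boundary — and $R^2$ as $100\,r^2$ of the paired
series. Note that published validation tables in this area sometimes print
$R^2$ values inconsistent with their own printed $r$; `posturekit` always
reports the squared Pearson coefficient of the pair it actually computed.

## Numerical and testing choices

* Degrees at every API boundary; radians only inside trigonometric calls.
* Strict inequalities at all thresholds; ties classify non-pathological.
* Duplicate marker IDs in one frame drop that landmark as ambiguous (with
  a warning) instead of guessing between candidates.
* Empty frame sequences produce empty series, not errors; empty sessions
  refuse to summarise.
* The test suite exercises full-size frames where the claim is about the
  reference geometry (the set-point recovery and the default 240 s
  protocol, generated once and shared across checks) and a 520 x 760
  canvas with 150 px baselines elsewhere, where the geometry is
  scale-invariant and full frames would only add time.
* One integer seed governs each stochastic element, and the generator
  restores the global RNG state, so fixture creation never perturbs a
  caller's randomness; fixed-seed bundles are byte-identical across runs.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile("session-")
bundle <- generate_protocol(protocol_spec(seed = 1L), outdir = dir)

camera <- process_stream(file.path(dir, "frames"))
kyph <- pair_streams(
  read_sensor_csv(file.path(dir, "upper_back.csv"), "upper_back"),
  read_sensor_csv(file.path(dir, "mid_back.csv"), "mid_back"))

summarize_session(camera)$fhp_fraction      # ~0.5: half the session is FHP
validate_series(bundle$truth |>
                  transform(ka_deg = true_alpha + true_beta),
                kyph, "ka_deg")             # r, band, p, R^2, MAPE
export_report(kyph, file.path(dir, "report"))
```

## Known limitations

Single-camera 2D geometry only: no pose estimation, camera calibration or
distortion correction, and angles are meaningful only for a true sagittal
view. One subject per frame. The detector assumes reasonably axis-aligned,
unoccluded markers on a light background, which the renderer guarantees
but real scenes do not. Only the accelerometer channel of a 9-axis IMU is
used; gyroscope/magnetometer fusion is out of scope, as are scoliosis and
pelvic-tilt assessment.
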