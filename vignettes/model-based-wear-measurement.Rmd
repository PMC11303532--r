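---
title: "Model-based wear measurement of knee inlays from single radiographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based wear measurement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mbwm)
```

## The measurement problem

The polyethylene inlay of a total knee arthroplasty wears by a tenth of a
millimetre or two per year, and it is radiolucent: its thinning cannot be
read off a radiograph directly. What *is* visible are the metallic femoral
component and the tibial baseplate. Model-based wear measurement (MBWM)
estimates the **minimum joint space width (mJSW)** — the smallest separation
between the femoral component and the tibial baseplate reference plane —
by registering 3D surface models of both components to their silhouettes in
a single calibrated anteroposterior radiograph. Because the inlay fills the
joint space, the mJSW is a proxy for the inlay's minimum thickness, and its
change between two time points is the **linear wear**,

> linear wear = mJSW(new) − mJSW(worn).

No stereo image pair or physical calibration box is required: a *virtual*
flat-panel calibration — just the source-to-detector distance (SDD) and the
detector resolution (DPI) — fixes the projective geometry, provided the
source-knee-detector distances are known and the image plane is normal to
the beam.

This package implements the full chain and, because the physical experiment
(milled inlays, wear testbed, X-ray machine, tactile coordinate measurement
machine) is not reproducible at a desk, it also implements a **synthetic
phantom study** that stands in for it, with known ground truth at every
stage.

## Coordinate conventions

Stated once, because every exported pose depends on them:

* World frame: X-ray source at the origin; detector plane at `z = +SDD`;
  `u` right (+x) and `v` up (+y) from the principal point. A point
  `(x, y, z)` projects to `u = x·SDD/z`, `v = y·SDD/z` (detector mm).
* Rigid transforms: translations in mm; rotations in degrees about the
  *fixed world axes*, applied X, then Y, then Z (`R = Rz Ry Rx`). The
  commercial tool's convention is unpublished, so this one is ours and is
  documented prominently.
* Tibial frame: medio-lateral axis = tray model x (medial is negative x),
  baseplate reference plane normal = tray model y. The knee's
  antero-posterior axis is the beam axis in an AP view.

## Pipeline

1. **Silhouette rendering** (`render_silhouette`): projected triangles are
   rasterized with supersampling; this is robust to self-occlusion of the
   femoral component, unlike analytic silhouette-edge extraction. Synthetic
   radiographs (`render_synthetic_radiograph`) put dark implants on a bright
   background, multiply by a smooth low-frequency field that stands in for
   soft-tissue/PMMA attenuation (physical spectra are out of scope), then
   blur (default sigma 1 px) and add Gaussian noise (default SD 0.02),
   seeded.
2. **Contour extraction** (`canny_edge_map`, `link_edges_to_contours`):
   classical Canny (defaults: sigma 1 px, hysteresis at 0.1/0.2 of the
   maximum gradient magnitude), 8-connected chain linking, and sub-pixel
   refinement by a parabolic fit of the gradient magnitude across the edge
   normal. The sub-pixel step matters: one pixel at 96 DPI is 0.26 mm on the
   detector, while the method's useful accuracy is an order of magnitude
   below that. Selection of a component's contour, interactive in clinical
   software, is hint-driven here (`select_component_contour`); hints are
   stored in the scene metadata for reproducibility.
3. **2D-to-3D registration** (`register_pose`): a downhill simplex with
   simulated-annealing acceptance minimizes the difference between the
   image contour and the model's projected silhouette contour. Simplex
   moves that worsen the cost are accepted with probability `exp(-dE/T)`
   (implemented as Press-style thermal fluctuations on the stored vertex
   costs, so temperature zero is exactly deterministic Nelder-Mead);
   cooling is geometric (`T <- 0.9 T`, 50 steps, a handful of simplex
   iterations per step), and everything is seeded.
4. **Measurement** (`measure_mjsw`, `linear_wear`): the mJSW is the minimum
   distance from the registered femoral surface to the baseplate reference
   plane, per condyle, minus the height of the peripheral rim the phantom
   inlay rests on (the distance to a plane is attained at a mesh vertex, so
   the closest-point query reduces to a vertex minimum). Condyles are split
   by the sign of the medio-lateral coordinate *in the tibial frame*, so a
   worn pool's laterality is stable across flexion.
5. **Reference** (`cmm_probe_thickness`): the accuracy reference simulates a
   tactile CMM ball probe (default diameter 3 mm) lowered onto a 2 × 10 mm
   patch centred at the condyle's lowest articular point. The probe model is
   a morphological dilation: it can never read below the true minimum
   thickness, and it cannot reach the bottom of pools narrower than the
   ball — deliberately a *different* contact model from the mesh-minimum
   used by the measurement, reproducing the probe/femur contact-area
   mismatch a tactile reference has in reality.
6. **Statistics** (`accuracy_report`, `bland_altman`, `paired_t_test`,
   `anova_oneway`, `roughness_metrics`): measurement error (bias) and MAE
   per flexion angle and condyle, pooled columns recomputed from the raw
   per-measurement errors, Bland-Altman limits of agreement (fixed 1.96
   multiplier) for the double experiments, paired t-tests for pose effects,
   one-way ANOVA for wear across angles, and Ra/Rp profile roughness. SD is
   the sample SD (n − 1) throughout; no multiple-testing correction is
   applied and all raw p-values are exposed.

## Details of the registration cost

The *reported* contour difference (`contour_cost`, and the
`final_residual` of every registration) is the symmetric mean
nearest-neighbour point-to-polyline distance in detector mm divided by the
magnification `SDD / z`, so it is stated at the scale of the implant.

The *optimized* objective is the root-mean-square version of the same
distance. This is a deliberate asymmetry: silhouette features that carry
most of the pose information — fixation pegs, the short side walls of the
baseplate — occupy very little arc length. Under a plain mean, a tilt of
the whole component about the medio-lateral axis can trade against a
vertical shift so that the long horizontal edges still match while only the
short arcs misfit; this creates a false cost basin a few degrees away from
the true pose whose mean residual is deceptively small. Squaring restores
the leverage of the misfitting arcs (the false basin's RMS is roughly an
order of magnitude above the true one) and reshapes the descent path so the
trade-off no longer pays.

Two further safeguards address the same single-view ambiguity:

* **Structured restarts.** After the run from the supplied initial pose,
  the search restarts from that pose offset by ±2.5° on each free
  out-of-plane rotation, with the full annealing schedule. Restarts stop as
  soon as a converged fit reaches the raster-noise floor
  (`good_enough`, default 0.05 mm RMS at object scale), so clean
  registrations pay for a single run. We originally restarted from randomly
  perturbed incumbents; that demonstrably failed to escape the false basin,
  because every small perturbation stays inside it.
* **Frozen beam-axis translation.** Out-of-plane translation is weakly
  observable from one view (it only changes magnification); the protocol
  assumes the source-knee-detector distances are known, so `tz` is frozen
  at the configured object distance by default (`fixed = "tz"`). The
  property suite never asserts `tz` recovery below 2 mm.

The capture range with these defaults is comfortably ±2 mm / ±2° (the
initial-pose error budget of an operator's rough alignment, and what the
validation suite exercises); the structured restarts extend the rotational
range to roughly ±5°.

Numerical floor: the model silhouette is rasterized on a local grid at the
detector pitch with 3× supersampling and traced by marching squares at the
0.5 coverage level, giving a boundary that moves continuously with pose;
contours are chord-subsampled to ~350 points per side for the cost (chord
error on these smooth silhouettes is far below the raster resolution).
Ties in contour selection break deterministically (largest arc length in
the hint region, then centroid distance, then lowest index).

## The synthetic phantom

The proprietary implant geometry is replaced by a documented parametric
analogue; the method depends only on *matched* surface models, not on the
brand shape.

* **Inlay**: 76 × 50 mm footprint, flat bottom, nominal thicknesses
  10/14/16 mm, with two spherical condylar dishes (default depth 2 mm) of
  the femoral radius. The dish depth and femoral radius are not published
  for the physical study; 2 mm and 20 mm are plausible values recorded in
  the configuration, not asserted as the study's.
* **Femoral component**: two convex spherical condyle segments (radius
  20 mm, centres 46 mm apart) joined by an intercondylar bar. The condylar
  axis is the flexion axis, so the articulating spheres are *invariant
  under flexion* — the congruent-contact property that makes the true mJSW
  flexion-independent and isolates registration as the sole error source.
  The 5° tessellation grid contains the study's flexion angles, so the
  seated contact point is an exact mesh vertex at 0/30/60°.
* **Tibial tray**: plate with a peripheral rim (default 2 mm, subtracted
  from the raw plane distance as the phantom inlay rests on it), a central
  keel and two anteriorly offset pegs. The fixation features are not
  cosmetic: without them the plate's silhouette is genuinely ambiguous
  under tilt (see the registration section).
* **Wear** is imposed as geometric material removal: a uniform patch
  covering the dish (so the probe-model minimum thickness drops by
  *exactly* the imposed depth) or a Gaussian pool (where ball averaging
  reads slightly less than the peak depth). Default imposed depths span
  0.05-0.5 mm across inlays and condyles.
* **Seating** is a contact solve: the femur, rotated to the flexion angle,
  translates down until the vertical clearance against the inlay's
  articular height field reaches 3 µm; the clearance is linear in the
  drop, so the contact height has a closed form. Differential
  medial/lateral wear is accommodated by the small varus/valgus tilt the
  physical phantom's silicone bands would produce — without it a rigid
  femur would lift one condyle off. An optional `liftoff` offset lets the
  condyle-lift-off hypothesis be injected deliberately.
* **Scenes**: 3 inlays × {new, worn} × flexion 0/30/60° = 18 radiographs
  at SDD 1150 mm, 96 DPI, object plane at SDD/2 (the knee-to-detector
  distance of the physical phantom is unpublished; this is a configuration
  default). Every per-scene seed derives from the master seed; the dataset
  is a pure function of configuration and seed.

What the generator does *not* emulate: scatter, beam hardening, detector
MTF, bone/tissue texture, overlapping anatomy, metal artefacts, and the
actual tribology of wear (pools are imposed, not worn). Passing the
synthetic validation therefore demonstrates the correctness of the
geometry, registration and statistics chain under controlled image
formation — not clinical robustness.

## Initial poses

Clinically, the operator supplies a rough initial alignment. The study
runner emulates this by perturbing the ground-truth pose by up to ±2 mm
in-plane and ±2° per rotation axis, seeded per scene and replicate. The
"double experiments" for precision re-register the *same* radiographs with
an independent seed and initial perturbation, mirroring a second reading
session.

## Error budget (what the validation shows)

With the default noisy imaging (blur 1 px, noise SD 0.02) the chain's
residual errors stack roughly as: sub-pixel contour localization
(~0.01-0.03 mm at object scale), model-contour rasterization
(~0.01 mm), registration (~0.01-0.05 mm in-plane), and the
seating/tessellation floor of the ground truth itself (~0.01 mm, visible
as a constant +0.01 mm bias of mJSW against the probe reference caused by
the faceted dish seating the femur fractionally high). Linear wear, a
difference of two mJSW values, cancels most systematic terms. The
acceptance suite pins: noiseless in-plane recovery and mJSW within
0.05 mm; noisy mJSW MAE within 0.25 mm; imposed wear of 0.15/0.30 mm
recovered within 0.15 mm by the full pipeline and to 1e-6 mm when
ground-truth poses bypass registration.

Problem sizes used by the test-suite and the acceptance script — a full
18-scene study with doubles (72 registrations), 20 noiseless recovery
scenes, 50 random mesh pairs against the brute-force distance oracle, and
10,000 null simulations per statistical test — were chosen so the whole
validation runs in well under an hour on a single core while keeping every
assertion statistically meaningful.

## Known limitations

* Single-view registration leaves the beam-axis translation essentially
  unobservable; the method inherits the protocol's assumption that the
  distances are known.
* The mJSW underestimates wear whenever the contact point migrates off the
  probed patch; the phantom's congruent geometry suppresses this by
  construction, which flatters the method relative to cam-post or
  low-conformity designs.
* The commercial residual's convention (one-sided vs symmetric, detector vs
  object scale) is unpublished; ours (symmetric mean, object scale) is
  documented, not asserted equivalent.
* Mean-line Ra/Rp are implemented as profile metrics; areal parameters and
  filtering cascades of surface-metrology standards are out of scope.
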