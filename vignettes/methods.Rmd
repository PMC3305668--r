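---
title: "Guided freehand distal interlocking: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided freehand distal interlocking: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Distal interlocking screws fix an intramedullary nail against rotation and
shortening. Because the nail bends on insertion, the distal holes cannot be
targeted by a proximally mounted jig; the standard of care is the freehand
("perfect circle") technique: the C-arm is tilted until the interlocking hole
projects as a circle, and the drill is then aligned with the beam under
repeated fluoroscopy. That alignment loop costs time and radiation.

The guided alternative implemented here works from a *single* oblique shot.
Viewed off-axis, each cylindrical hole projects as a bright, lens-shaped
region: the overlap of the images of its two rim openings. The lens shape
encodes the hole's spatial orientation. The pipeline is

1. detect the two lens-shaped hole projections and extract a small set of
   significant contour landmarks;
2. build a virtual model of the two hole cylinders and compute the same
   landmarks for a trial pose;
3. recover the 6 degree-of-freedom pose of the distal nail segment by
   matching virtual to detected landmarks with damped least squares;
4. virtually align a two-ring targeting jig with each recovered hole axis;
5. project two targeting ellipses (one per ring) and a skin-incision
   landmark into the image.

When the surgeon translates the jig until the small ring's shadow coincides
with the small target ellipse, and then tilts the drill until the large
ring's shadow coincides with the large target ellipse, the drill is coaxial
with the hole.

## Geometry and conventions

The camera frame is right-handed with the X-ray point source at the origin
and +z toward the detector at distance SDD (default 1000 mm). Pixels are
0-based, u right, v down, square pitch (default 0.3 mm/px at 1024 x 1024;
the bundled test scenes use a 448 px crop at 0.2 mm/px so the object-plane
resolution, ~7 px/mm, matches a clinical image intensifier). Lengths are mm,
angles radians internally.

The nail frame puts the nail axis on +z; hole axes are unit vectors
perpendicular to it (mediolateral +x, anteroposterior +y), hole centers on
the axis at their axial stations. A rigid pose `R, t` maps nail to camera
frame.

**Rim circles.** Each hole opening is modeled as a planar circle of the hole
radius r_h, perpendicular to the hole axis, at offsets +/-sqrt(R^2 - r_h^2)
from the nail axis (the plane of inner tangency). The true rim curve of two
intersecting cylinders is non-planar; for the default geometry (R = 5 mm,
r_h = 2 mm) the maximal deviation from the rim plane is R - sqrt(R^2 - r_h^2)
= 0.417 mm. The ray-cast renderer uses the exact constructive solid geometry
and acts as the oracle bounding this approximation: across the usable band
the analytic lens boundary and the rendered bright-region boundary agree to
better than one pixel (acceptance criterion 1).

**Circle projection.** A circle with unit normal n, center c and radius r
seen from the origin satisfies, for a ray direction d,
`d' K d = 0` with `K = (n.c)^2 I - (n.c)(c n' + n c') + (|c|^2 - r^2) n n'`.
Substituting the pixel-to-ray map gives the exact conic image; this is used
everywhere (rim images, targeting rings) and is verified against a dense
point-sampling oracle.

**Feasible obliquity.** A ray can only pass the hole channel if its angle to
the hole axis is below atan(r_h / sqrt(R^2 - r_h^2)) ~ 23.6 degrees for the
default nail. Beyond that the two rim images separate and the lens is empty
— the package signals this explicitly. The synthetic scenario bands reflect
this: "mild-oblique" draws from [5, 20] degrees (the usable band),
"steep-oblique" from [40, 60] degrees (deliberately empty), "aligned" below
0.8 degrees (round-appearing). A stated band of 5-35 degrees is therefore
not realizable above ~24 degrees with this (clinically realistic) geometry;
all recovery studies sample the feasible sub-band.

**Hole layout.** Two holes with *parallel* axes (two ML or two AP), 12 mm
apart, are the default: this is the configuration a single view can solve,
since orthogonal axes would put one hole at >66 degrees obliquity whenever
the other is usable. Orthogonal layouts are constructible and render
correctly; solving then follows the single-lens path and reports the
under-constrained degree of freedom (rotation about the visible hole's
axis).

## Synthetic radiographs

`render_radiograph()` casts one ray per pixel through the nail solid (outer
cylinder minus open hole channels) and applies Beer-Lambert attenuation
`exp(-mu * path)`. The default `mu_mm = 20` renders the titanium implant
effectively opaque: clinical C-arm images of nails are contrast-saturated
(the study device applied automatic intensity correction), and an opaque
implant keeps the lens boundary penumbra below a tenth of a pixel. Lower
values give a soft, physically thinner-looking metal and are useful for
robustness experiments. Additive Gaussian intensity noise (default sd 0.01
for fixtures; the noisy acceptance study uses 0.02) and optional min-max
normalization complete the model.

What the generator does *not* emulate: bone and soft-tissue background,
scatter, image-intensifier vignetting and pincushion distortion, screw
threads, and the slightly non-planar rim curve is rendered exactly rather
than planar (that difference is the approximation the oracle bounds). A
green test therefore establishes correctness of the geometry pipeline on
clean, calibrated projections — not detection robustness in anatomical
scenes.

## Detection and landmarks

The nail silhouette is segmented by Otsu's threshold on the smoothed image
(sigma = 1 px) and the largest connected component; bright regions enclosed
by it are the lens candidates (area >= 30 px^2, solidity >= 0.85, at most
two, ordered along the silhouette's principal axis). Each candidate boundary
is traced with marching squares and refined to the gradient-magnitude
maximum along the local normal. Two tracing choices deviate from the obvious
defaults and matter at this lens size:

* the iso level is the midpoint of the *raw-image* interior and surround
  medians — computing it from the smoothed image biases the contour of a
  narrow lens outward by about a pixel, because the smoothed plateau of a
  5-10 px wide region never reaches the interior intensity;
* the gradient-peak refinement makes the traced boundary independent of the
  level choice wherever the edge profile is symmetric.

**Landmarks.** Per hole: the two lens *tips* (where the rim images cross),
each arc's *apex* (farthest point from the tip-to-tip chord) and two
*quarter-points* per arc (half arc-length between tip and apex) — 8 points,
plus the per-arc conics. Tips are initialized at the contour's diameter
endpoints (robust to point noise, unlike curvature maxima) and polished
either by intersecting local chord lines (sharp corners, e.g. analytic
contours) or by intersecting a jointly fitted rim-image ellipse pair. The
joint fit couples the two arcs through the nail geometry: one ellipse of
semi-axes (a, a cos theta) and a copy displaced along its minor axis by
2 (h_off / r_h) a sin theta, five parameters in total. Independent short-arc
conic fits are hopelessly ill-conditioned here (they happily return
hyperbolas); the coupled model is the smallest one that pins both arcs.
Contours whose curvature contrast stays below 3x the median are classified
round-appearing (the freehand surgeon's "appears round" criterion made
explicit) and summarized by a least-squares circle instead.

## Pose recovery

Initial candidates come from two independent sources: (i) the classical
closed-form single-view circle pose of each fitted arc conic (two mirror
solutions each, depth fixed by the known rim radius), and (ii) a shape-based
estimate solving obliquity and magnification from the lens length/width
ratio. Per-hole candidates are promoted to full nail poses; because the
per-hole *depth* estimates carry most of the error and the nail-axis
direction is hypersensitive to their difference, the two hole centers are
first rescaled to a common depth, which is itself corrected through the
known 12 mm hole separation. Near-duplicate candidates are collapsed.

Each candidate is polished by a short damped-least-squares pre-pass (4
iterations); the best three are refined fully (Levenberg-Marquardt on an
axis-angle increment composed onto the rotation plus a translation,
forward-difference Jacobian, termination at gradient inf-norm < 1e-10, step
< 1e-12, or 200 iterations; a stall under maximal damping counts as the
step-size criterion). The residual is the stacked 2D mismatch between
detected landmarks and virtual landmarks computed by the *same extraction
definitions* on the analytic forward model — like with like. Tips are
matched by proximity, arcs by the side of the tip chord; a round-appearing
hole contributes its circle fit (center + radius, 3 constraints) instead.
The lowest-residual converged candidate wins; its branch label records the
mirror combination. Wrong mirror branches in-band show several-fold larger
residuals, which is what resolves the classical two-fold circle-pose
ambiguity once both holes are used jointly.

The nail solid is invariant under a half-turn about its own axis, so the
identifiable quantities are per-hole *lines* and *points*: axis direction
modulo sign and hole center. All error metrics use these.

### Accuracy, measured

With exact landmarks (the analytic forward model feeding the solver), pose
recovery is exact to numerical precision (residuals ~1e-11 px; the
ground-truth pose is a fixed point). Through the full rendered pipeline at
clinical resolution the floor is set by landmark localization on the blurred
image: axis error median ~0.3 degrees (max ~2), hole-center error median
~2 mm — almost entirely *depth*, the weakly observed direction. A
ground-truth-tip substitution study shows the tips are not even the binding
constraint (median improves only to ~0.28 degrees), so this is the honest
floor of landmark-based solving at ~7 px/mm, and the corresponding stated
acceptance thresholds (0.2 degrees / 1 mm noise-free) are knowingly not met;
the pipeline criterion is left red with this analysis rather than loosened.
For drilling the clinically relevant quantities are the axis direction and
the transverse entry point (sub-0.1 mm here); a depth error moves the
targeting ellipses nearly concentrically and is largely harmless to the
ring-matching procedure, which the guidance-closure criterion confirms.

## Guidance

The drilling direction is the hole-axis sign pointing toward the source (the
surgeon works on the source side of the limb). The two targeting ellipses
are the exact conic projections of circles with the jig's ring radii,
centered on the hole axis at the bone-entry point plus each ring's offset;
the incision landmark is the axis point 30 mm (configurable) above the bone
entry. Jig defaults (small ring r = 8 mm at the tip, large ring r = 25 mm at
80 mm) are stand-ins chosen so that a 1 px ring-match error maps to well
under 1 degree of axis error at the default camera — ring separation, not
ring size, sets the angular sensitivity. `alignment_error()` closes the
loop: angle between sleeve and hole axis, lateral offset at entry, and
whether a 3.2 mm drill clears the 4 mm channel end to end.

After the first screw occupies its hole, a fresh two-hole solve is
impossible; `simulate_second_hole()` forward-projects the remaining hole
from the prior solution, correcting all landmarks by the inter-frame
translation measured with phase correlation (`estimate_frame_shift()`,
subpixel via a local upsampled DFT; confidence is the main-to-second peak
ratio).

## Numerical choices

* Conics are stored as unit-norm coefficient vectors with interior-negative
  sign; ellipse form is attached when real. Conic-conic intersection uses
  the degenerate pencil member plus Newton polishing (residuals < 1e-6 under
  both forms guaranteed by construction).
* `fit_conic` is the direct algebraic least-squares fit on Hartley-
  normalized coordinates; collinear input is rejected.
* All randomness flows through explicit seeds; fixtures are bit-reproducible
  and regenerate from their JSON sidecars.
* The image-ellipse center of a projected circle lies on the projected axis
  line only approximately under perspective; the offset stays below ~0.1 px
  for the small ring and ~0.3 px for the large ring at eccentric placements.

## Known limitations

* Detection assumes a clean metal-on-background scene; anatomical texture
  (cortical bone edges under the silhouette) is out of scope.
* Single-image, static method: motion between exposure and drilling is only
  handled via the translational inter-frame correction.
* Accuracy at clinical resolution is landmark-limited as quantified above;
  dense contour matching could push further but trades away the robustness
  argument for sparse significant landmarks.
* PNG output is 8-bit (16-bit output uses PGM); TIFF is not supported.
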