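---
title: "Template construction and smile metrics: models, parameters, design choices"
author: "smilecurves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template construction and smile metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smilecurves)
```

## The model

Aesthetic evaluation of an anterior smile is usually subjective; this package
operationalizes a set of widely used objective references into a parametric
template plus a landmark-based metric suite. The template represents the six
maxillary anterior teeth (FDI 13–23) as abutting boxes whose proportions are
fully determined by a single scalar, the central-incisor width $W_1$, plus a
small set of proportion constants:

* **Dominance and the regressive proportion.** Apparent mesiodistal widths
  decrease from the central incisor outward by the diagonal-of-a-square
  ratio: $W_2 = rW_1$, $W_3 = rW_2$ with $r = 1/\sqrt{2} \approx 0.7071$.
  We treat $1/\sqrt 2$ as the exact normative constant; the familiar "71%"
  is its rounding to integer percent and "1:1.414" its inverse to three
  decimals. With the default $W_1 = 8$ mm the widths are 8, 5.657 and 4 mm.
* **Crown proportion.** The central crown's width/height ratio defaults to
  0.80, so the default crown height is $H_1 = W_1/0.8 = 10$ mm.
* **Gingival (cervical) line.** Central and canine zeniths sit level; the
  lateral zenith sits `lateral_zenith_drop` = 0.6 mm more incisally, giving
  the convex cervical line of the ideal smile.
* **Incisal line.** The lateral incisal edges sit `incisal_step` = 0.8 mm
  gingival to the central edges while canine tips stay level with the
  centrals — the "soup plate" outline.
* **Connector spaces (50-40-30).** The connector zone between two adjacent
  teeth spans from papilla tip to contact point. Its height is 50% of the
  central crown height at the midline, 40% between central and lateral, and
  30% between lateral and canine.

The template frame is millimetres, y increasing downward (raster
convention), origin on the dental midline at the central incisal-edge line;
the patient's right teeth occupy $x<0$. That choice minimizes sign errors
when the template is registered onto photographs.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `central_width` | 8.0 | mm | the single size scalar |
| `wh_ratio` | 0.80 | — | central crown width/height |
| `regressive_factor` | $1/\sqrt 2$ | — | adjacent-width ratio |
| `lateral_zenith_drop` | 0.6 | mm | lateral zenith below the zenith line |
| `incisal_step` | 0.8 | mm | lateral edge above the central edges |
| `connector_fractions` | 0.50/0.40/0.30 | — | connector heights / $H_1$ |
| `papilla_line_fraction` | 0.70 | — | papillary-line depth / $H_1$ |

Two constructive choices deserve comment because the underlying references
leave them open:

* **Papillary line depth.** No accepted standard exists for absolute papilla
  heights. We place all five papilla tips on one horizontal line at
  $0.70\,H_1$ below the central zeniths and derive each contact point from
  the connector fraction. This reproduces the expected ordering of contact
  points (canine–lateral highest, midline lowest) and makes the 50-40-30
  percentages exact. The cost is that a strictly parallel papillary line and
  contact line cannot coexist with unequal connector fractions; the ideal
  template keeps the papillary line horizontal and lets the per-side contact
  line slope. The report exposes the angle between the two fitted lines
  (`papillary_contact_parallelism`) so users can judge the discrepancy; on
  the ideal template the two full-arch least-squares lines are both
  horizontal by symmetry and the angle is 0.
* **Box heights.** Only the central crown height is stated anywhere; lateral
  and canine box heights follow from the zenith and incisal-edge rules
  (lateral: $H_1 - 0.6 - 0.8$; canine: $H_1$), the only construction
  consistent with all stated offsets. Tooth long axes carry no numeric rule
  and are rendered as vertical box midlines, never scored. "Same
  perspective" for the canine tips is interpreted as "same $y$ as the
  central incisal edges".

Curved crown silhouettes in rendered overlays are cosmetic Bézier rounding
of the box corners and carry no metric meaning.

## Metric definitions and classification rules

All metrics run on a *canonicalized* copy of the landmark set: the set is
rotated so that the axis from the patient-right landmark centroid to its
patient-left mirror-partner centroid is horizontal, translated so the
midline contact point is the origin, and spun 180° if the zeniths end up
incisal to the edges. Canonicalization is a rigid motion, which is what
makes every metric invariant under global rotation and translation of the
annotation.

Class boundaries are qualitative in the source frameworks, so the package
fixes configurable defaults:

* cervical and incisal line classes use a 0.2 mm tolerance;
* the lip line is `low` when more than 25% of the central crown is covered,
  `high` when gingiva shows, boundary cases go to `medium`;
* the smile arc fits $y = ax^2+bx+c$ to the incisal midpoints of the four
  incisors and to the lower-lip polyline; it is `flat` when
  $|a_{inc}| < 0.002\ \mathrm{mm}^{-1}$, `reverse` when the incisal and lip
  curvatures have opposite signs, `consonant` when they share sign and
  $a_{inc}/a_{lip} \in [0.5, 2]$, otherwise `flat`.

Canine tips are excluded from the arc fit: in the soup-plate ideal they sit
level with the central edges, so a parabola through all six points is nearly
degenerate and its curvature sign is not noise-stable; through the four
incisors the ideal incisal curve has
$a = -\text{step}/\big((W_1+W_2/2)^2 - (W_1/2)^2\big) \approx -0.0079$
mm$^{-1}$, comfortably resolvable under realistic annotation noise.

Length tolerances are stated for a 10 mm central crown and rescaled by the
measured crown height (curvature tolerances inversely), so classifications
are invariant under uniform scaling — the same smile annotated at 20 px/mm
or 40 px/mm classifies identically without a calibration. Deviations from
the ideal reported by `full_report()` normalize measured mm offsets by the
ratio of the measured to the parameter-implied crown height for the same
reason.

Apparent widths are frontal-view projections between incisal corner
landmarks; the parallax of a frontal photograph is accepted, not corrected.

## Registration and rendering

Registration follows the rule that the central-incisor widths of template
and photograph should coincide: a similarity transform (scale, rotation,
translation — no reflection or shear) is fitted in closed form through two
anchor correspondences, by default the distal incisal corners of teeth 11
and 21 (i.e. the combined central width). Two points make the fit minimal
and well-posed while the rotation component absorbs tilted photographs. The
anchors are overridable when a user prefers other reference points.

Rendering is vector-first: the line work is produced as exact SVG polylines
in pixel coordinates (1 mm = 1 user unit in the pure-template export).
PNG output rasterizes those polylines directly on the photograph's own
pixel grid with alpha blending, so the photograph itself is never resampled.
Geometry mapped outside the canvas is clipped with a warning.

## The synthetic-smile generator

`make_smile()` derives every fixture from the ideal template's own
landmarks, applies one documented deterministic deformation, and adds
i.i.d. isotropic Gaussian noise with an explicit seed (global RNG state is
untouched). The presets emulate recognizable clinical presentations at
magnitudes a clinician would call typical: a 3 mm gummy display, 1.5 mm of
central over-eruption (deep bite), an inverted incisal curvature, a 0.5 mm
unilateral shift, and a levelled (flat-plate) incisal line. The ideal
preset carries consonant lips by construction — the lower lip follows the
incisal quadratic 2 mm below the edges; the upper lip rests 1 mm down the
central crowns (medium lip line).

What the generator does *not* emulate: perspective/parallax distortion, lens
distortion, lip asymmetry during smiling, gingival texture, or any pixel
appearance — fixtures are landmarks, with only schematic toy rasters for
pipeline tests. Green tests therefore demonstrate correctness of the
geometry and metric definitions, not robustness to the full variability of
clinical photography (annotation quality in particular remains the user's
responsibility).

## Numerical choices and degenerate inputs

* All template constants are closed-form; the construction is exactly
  mirror-symmetric (coordinates are computed once per side and negated) and
  exactly scale-equivariant when all mm-length parameters are scaled
  together. Doubling `central_width` alone doubles the boxes but leaves the
  0.6/0.8 mm offsets fixed, which is the intended clinical reading of those
  offsets as absolute lengths.
* Quadratic fits use QR decomposition; fewer than three distinct abscissae
  yield class `undetermined` rather than an arbitrary label.
* Connector heights that are zero or negative (papilla tip at or below the
  contact point) are reported and flagged as annotation errors.
* Validation errors are classed conditions naming the offending field; the
  CLI maps them to exit status 2.
* Landmark files store coordinates with 17 significant digits, so
  write/read round trips reproduce the doubles exactly.

## Problem sizes used in the test suite

Property suites run 200 seeded random similarity transforms and 200 seeded
noise replicates at 0.1 mm landmark noise (the noise level at which all
three headline class labels — soup plate, convex, consonant — are expected
to be recovered in at least 95% of replicates); round-trip properties use
10 random landmark sets per dialect. These sizes give stable pass/fail
behaviour at sub-minute runtimes on a single core.

## Known limitations

* 2D only; no STL/occlusal views, no 3D planning-software integration.
* No automatic landmark detection — annotations come from the user.
* No golden-proportion or alternative width systems beyond the diagonal
  proportion; no tooth-axis angulation scoring.
* The apparent-width parallax caveat above applies to every width-derived
  quantity.
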