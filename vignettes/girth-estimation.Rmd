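---
title: "Girth estimation from multi-angle silhouettes: model, assumptions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Girth estimation from multi-angle silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodygirth)
```

## The measurement model

A body cross-section at height *h* is observed only through its silhouette
widths: from view angle θ the camera sees a projected width *w(θ)*, and the
pipeline treats *r(θ) = w(θ)/2* as the section's radius at that angle. With
views at 0°, Δ, 2Δ, …, 180° (Δ dividing 180), the girth estimators are:

* **Cosine polygon.** Consecutive radii and the known angle Δ between them
  determine a triangle side by the law of cosines,
  c² = r₁² + r₂² − 2 r₁ r₂ cos Δ. The sides are summed over the half turn
  and doubled. Assumptions: the section is convex, has front/back mirror
  symmetry (so the 0–180° half determines the whole), and the body axis is
  vertical in every view.
* **Ellipse formula.** 2π √((a² + b²)/2) on the 0° and 90° half-widths, the
  classical two-view baseline the polygon method is compared against.

Pixels become centimetres through the subject's known stature:
AWW = AHV · CWW / CHV, where AHV is the true stature (cm), CHV the
silhouette pixel height of *that view*, and CWW any pixel width measured on
it. Normalising each view by its own bounding box absorbs small per-view
differences in apparent height; how rows correspond across views is not
observable from silhouettes alone, so this linear normalisation is a
declared modelling choice.

## Known bias structure

Two systematic effects, both quantified by the test suite, bound what a
green test can claim:

1. **Inscribed-polygon shortfall.** On a circle of radius *r* the polygon
   returns 2πr·(1 − (n/π)·sin(π/n)) with n = 360/Δ: −1.138 % at Δ = 30°,
   vanishing as Δ → 0 (`inscribed_polygon_error()`). A widely quoted figure
   of 1.02 % for the dodecagon does not follow from the geometry; the
   closed form is what the package implements and tests.

2. **Support-width bias.** The projected half-width is the *support
   function* of the section, which is ≥ the radial distance everywhere and
   equal only where the boundary is perpendicular to the view. The polygon
   built on support half-widths therefore converges (as Δ → 0) to the arc
   length of the support curve, not of the section itself. On a circular
   section the two coincide and refinement converges to the truth; on an
   elliptic section (p = 2) the residual bias grows quickly with the axis
   ratio: ~0.03 % at ratio 1.05, ~0.2 % at 1.1, ~1.8 % at 1.32 (at Δ = 5°).

The combination decides the cosine-vs-ellipse contest on exact phantoms.
At Δ = 30° and p = 2 the two biases partially cancel and the cosine polygon
beats the ellipse formula up to an axis ratio of about 1.33; beyond that
(including ratio 1.5) the ellipse formula — which is tailored to ellipses —
is closer. On flatter, "boxy" sections (superellipse exponent p ≳ 2.5),
which is what real hip sections resemble, the ellipse formula collapses
(it badly underestimates non-elliptic perimeters) while the polygon stays
within a few percent, and the cosine method wins at every tested aspect.
The property suite pins all three regimes; the acceptance test asserts the
ordering inside the regime where it genuinely holds (axis ratio 1.3,
exactly sampled). Empirically measured hip sections in the bundled
validation tables show exactly this pattern: the ellipse estimate
undershoots the hip actuals by ~7 % while the cosine estimate is within a
fraction of a percent.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| angular step Δ | 30° (7 views) | the original acquisition protocol; girth estimates decrease monotonically as Δ grows (verified property), so fewer views = shorter polygon |
| `n_rows` | 500 | normalised height grid; finer than any tested render (≤ 600 body rows) |
| `waist_band` | 0.55–0.70 | standard anthropometric region of the natural waist (girth minimum above the iliac crest), as height-from-ground fraction |
| `hip_band` | 0.42–0.55 | widest gluteal level; must sit strictly below the waist band |
| `smooth_rows` | ~2 % of `n_rows`, odd | running mean before the band extremum search, so a single pixel-quantisation glitch cannot capture the landmark |
| segmentation threshold | Otsu | dark subject on light background; fixed thresholds accepted |
| Canny σ, low, high | 2.0, 0.1, 0.3 | conventional defaults (no values were published); thresholds are fractions of the max gradient magnitude |

Landmark values are reported from the smoothed profile at the selected row;
ties in a flat profile resolve to the band centre (so a cylinder reports
its girth at the centre row — exercised by the tie-break test). Reports
round to 2 decimals; JSON/CSV keep full precision.

## The phantom generator: what it does and does not emulate

`phantom_spec()` stacks superellipse sections |x/a|ᵖ + |y/b|ᵖ = 1 with
(a, b, p) linearly interpolated between height levels. The family was
chosen because it is convex (p ≥ 1), spans circle → ellipse → rectangle,
has a closed-form support width (the dual-norm expression
(|a cos θ|^q + |b sin θ|^q)^{1/q}, 1/p + 1/q = 1), and a perimeter
computable to high accuracy. Presets: `cylinder` (r = 1 cm), `elliptic`
(1.2 × 0.8 cm), `hourglass` (hip bulge designed at h = 0.50, waist minimum
at h = 0.60), and the matched `thin`/`overweight` pair — the hourglass with
all torso levels (h 0.40–0.88) rescaled so the designed waist girths are
4.7 cm and 6.0 cm, the actual waistlines of the matched model pair in the
bundled validation tables (designed difference 1.3 cm). Default stature is
15 cm, a 1/16-scale desk model; the pipeline is scale-anchored, so only
ratios matter.

Rendering is orthographic by default: per image row the foreground run is
round(2 · support half-width · px/cm), centred. A pinhole mode scales each
row by the tangent-ray magnification d/√(d² − w²) to *study* the
camera-distance effect; the measurement path applies no perspective
correction, mirroring the original protocol. Optional seeded
salt-and-pepper pixel flips emulate mask defects; segmentation's
largest-component + hole-fill cleaning keeps girth shifts below 2 % at a
1 % flip rate (verified). The phantoms do **not** emulate pose articulation,
arms, clothing, hair, lighting, or camera tilt — a green phantom test
validates the geometry and the raster pipeline, not human-subject
performance.

## Numerical choices

* **Arc-length oracle.** The superellipse parametrisation has integrable
  endpoint singularities (|sin t|^{2/p−1}) for p > 2. The quadrature
  substitutes t = s^{p/2} at both ends (evaluated in log space to survive
  p in the hundreds) before handing the integrand to adaptive quadrature at
  rel. tol 1e−8 (1e−9 internally). Spot checks: circle exact to 1e−8,
  ellipse (1.2, 0.8) = 6.346176 (independently confirmed by plain
  quadrature on the standard parametrisation and by a 5·10⁶-point chord
  sum), p = 200 unit "square" = 7.9779 — note the true perimeter at p = 200
  is 0.28 % *below* the limit 8, so tests assert the verified value, not
  the limit.
* **Cancellation guard.** cosine_side clamps tiny negative values of
  r₁² + r₂² − 2 r₁ r₂ cos Δ (possible when r₁ = r₂ and Δ is small) to 0.
* **Otsu plateau.** With a gapped histogram (e.g. a rendered two-level
  photo) the between-class variance is maximal on a plateau of thresholds;
  the implementation takes the plateau's middle bin and returns its upper
  edge, so the dark mode itself always segments as foreground.
* **Canny.** Separable Gaussian smoothing with replicated edges, Sobel
  gradients, *interpolated* non-maximum suppression (the quantised-sector
  variant leaves double-width diagonal ridges), and hysteresis by
  8-connected labelling of weak edges anchored at strong ones. On a
  120×120 disk of radius 50 the result is bit-identical in pixel count to
  the reference scientific-Python implementation (352 edge pixels — a thin
  digital staircase counts ~12 % more pixels than the arc length 2π·50,
  which is worth knowing before using edge-pixel counts as perimeters).
  The measurement path deliberately uses the filled mask, not the edge
  map: identical information on solid silhouettes, but hole-robust and
  deterministic.
* **Degenerate inputs.** Empty silhouettes, empty landmark bands,
  sub-20-px renders, pinhole cameras inside the body, non-dividing angular
  steps, and missing 0°/90° views for the ellipse path all fail with
  stage-named errors rather than producing numbers.

## Design decisions that were genuinely open

* **Row selection for waist/hip.** The original study reports landmark
  girths but never defines the row; the band-extremum rule (minimum /
  maximum of the smoothed cosine profile within configurable bands) is this
  package's choice, with defaults from standard anthropometric practice.
* **RMS as "average error rate".** The bundled per-model errors reproduce
  the published aggregate error rates under √(mean e²) — 5.16 % waist,
  4.58 % hip, 4.59 / 6.30 / 5.57 % in the distance experiments — and do not
  under a plain mean. Both statistics are reported (`error_summary()`), the
  RMS as the headline. Two published aggregates (the 30 cm-distance
  averages) do not reproduce from the printed per-model rows under either
  reading and are bundled but not asserted; one hip error cell (M14) is
  inconsistent with its own actual/measured pair and is consumed as
  printed.
* **Masks over edges.** Widths come from filled-mask extremes rather than
  the Canny map (kept as an inspectable stage), making the contract
  deterministic and hole-robust.
* **Formats.** Masks read/write as 8-bit PNG (0 background / 255
  foreground) or plain-text ASCII PGM; photographs as PNG/JPEG/PGM/PPM.
  TIFF is rejected — no reader exists in the dependency set.

## Limitations

* Front/back asymmetry (real abdomens) violates the doubled-half-perimeter
  rule; the support-width bias means even infinitely many views cannot
  recover a non-circular section's true girth exactly from silhouette
  widths alone.
* Landmark bands assume an upright, roughly standard-proportioned body;
  unusual proportions need re-banded configuration.
* The resolution floor (stature ≥ 20 px) and the 1 px rounding per row set
  the raster error scale; at 20 px/cm on a 15 cm phantom, girth errors stay
  within ~2 % (tested), but coarser scales degrade quickly.
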