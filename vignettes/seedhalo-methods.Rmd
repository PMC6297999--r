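---
title: "Quantifying seed mucilage halos: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seed mucilage halos: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedhalo)
```

## The measurement problem

Myxospermous seeds (flax, Arabidopsis, camelina, plantain, shepherd's
purse) release a hydrophilic mucilage capsule from the seed coat upon
imbibition. When seeds are laid on an agarose gel containing toluidine blue
O, the soluble fraction of this mucilage diffuses outward and the
metachromatic dye stains it purple-pink against the light-blue gel, leaving
a roughly concentric halo around each dark seed. A single scanned plate
thus carries two phenotypes per seed: the area of the released mucilage
halo (`AreaM`) and the morphometry of the seed itself (`AreaS` and its
shape descriptors). Because halo size scales with seed size, the trait of
interest is the **adjusted mucilage content**,

$$\mathrm{ratio} = \frac{\mathrm{AreaM}}{\mathrm{AreaS}},$$

where `AreaM` is the full disk bounded by the outer stained contour —
including the pixels under the seed — and `AreaS` the projected seed area.
A seed inside its own halo therefore always has ratio ≥ 1, and ratio = 1
means no detectable soluble mucilage beyond the seed outline.

`seedhalo` implements the complete supervised chain: calibration, HSV
thresholding, hole filling, top-to-bottom object numbering, size filtering,
an eleven-descriptor morphometric profile per object, and seed–halo
pairing. It is deliberately *not* a learning method: plates imaged under
controlled conditions are separable by fixed colour bands, and a supervised
threshold workflow stays interpretable and auditable.

## Segmentation model

Images are split into 8-bit H, S and V planes (all three scaled to 0–255,
hue mapped as `floor(h° / 360 · 255)`, achromatic pixels assigned hue 0). A
pixel belongs to a target iff all three of its channel values fall inside
the target's inclusive bands.

The shipped flax defaults anchor each band at one non-trivial bound, the
other end being the extreme of the scale:

| target   | H band      | S band      | V band    | rationale |
|----------|-------------|-------------|-----------|-----------|
| mucilage | [172, 255]  | [24, 255]   | [85, 255] | stained halo is purple-pink (high hue); S ≥ 24 rejects near-achromatic noise; V ≥ 85 excludes the dark seed body |
| seed     | [0, 255]    | [0, 255]    | [0, 70]   | only brightness separates the dark seed from gel and halo |

Both value thresholds (85 and 70) straddle the same gap between the dark
seed population and everything brighter. After banding, interior holes
(4-connected background regions not reachable from the border, the standard
dual of 8-connected foreground) are filled, which is what makes `AreaM`
include the seed pixels, and what removes specular highlights from seed
bodies.

### Automatic threshold suggestion

`suggest_seg_params()` is advisory, mirroring the supervised workflow: the
pipeline applies the species defaults unless automatic thresholding is
requested. The suggester runs the iterative-intermeans (IsoData) threshold
on each channel histogram: starting from the intensity bisecting the
histogram mass, iterate $T \leftarrow \lfloor (\mu_{\le T} + \mu_{>T})/2 +
0.5\rfloor$ (ties round half up) to its fixed point; a histogram with fewer
than two occupied bins is degenerate and triggers a fallback to the
defaults with a warning. The test suite checks the iterate against an
exhaustive 256-candidate fixed-point search.

One subtlety is documented here because it is a genuine design decision:
the value plane of a stained plate has *three* populations (dark seeds,
stained halo, bright gel), and the first intermeans split lands between
halo and gel — the wrong gap for both value thresholds. The suggester
therefore re-splits the dark class while that class is still spread over a
wide intensity range (weighted SD > 24 levels), which isolates the darkest
population. On a plainly bimodal histogram the first split is final, so the
simple case is unaffected.

## Object numbering and size filtering

Connected components (8-connected) are numbered *line by line from the top
of the image*: label k is the component whose anchor — topmost pixel, ties
broken by smallest column — comes k-th in raster order. This convention
exists to support rank pairing of seeds with halos (below) and matches how
a scanline labeller naturally numbers compact objects.

Mucilage components with calibrated area outside **18–315 mm²** are
deleted: the lower bound drops staining specks, the upper bound
automatically removes two or more halos that have merged on the gel, which
cannot be attributed to single seeds. Seed masks get a separate
configurable filter (default 0.5–50 mm² for flax) to drop dust. Removed
objects are logged with label, area and reason. Objects touching the image
border are *flagged*, not deleted — cropping to the plate interior is the
primary defence against edge artefacts, and deletion is an explicit option
(`delete_border`).

## Shape descriptors

Eleven descriptors per object, in calibrated units: area, perimeter,
circularity, max/min Feret diameter, Feret angle, solidity, convex area,
aspect ratio, centroid x and y.

* **Area** is pixel counting divided by the squared scale. Analytic
  formulas such as $\pi r^2$ are circular idealisations; the measurement is
  the count.
* **Perimeter** is estimated from the Moore-traced outer boundary chain
  code with the Vossepoel–Smeulders corner-corrected weights
  $L = 0.980\,N_{\mathrm{even}} + 1.406\,N_{\mathrm{odd}} -
  0.091\,N_{\mathrm{corner}}$. The choice matters: the naive $1/\sqrt2$
  chain weights overestimate a digitised circle's perimeter by ≈5%, which
  would depress the circularity of a genuinely round object to ≈0.90 and
  destroy the round-seed anchor. The corrected estimator is biased below
  1.5% on disks of radius ≥ 20 px; its residual bias on axis-aligned
  rectangles (where it under-measures by up to 5%) is the accepted
  trade-off, since seeds and halos are round-ish blobs. Single-pixel
  objects have a degenerate boundary and perimeter 0.
* **Circularity** is $4\pi A/P^2$, clipped at 1.0: digitisation can push
  the raw value slightly above 1 for round objects, and the descriptor is
  defined on (0, 1]. It is undefined (error) for zero perimeter.
* **Feret diameters** are computed on the convex hull of pixel centres:
  the maximum over hull-vertex pairs (verified against the exhaustive
  $O(n^2)$ pairwise oracle in the tests) and the minimum caliper width
  over hull edge orientations; the angle is the orientation of the maximal
  chord in degrees from the image x-axis.
* **Solidity** divides the pixel-count area by the shoelace area of the
  convex hull of the pixel *corners* (equivalently, the hull of pixel
  centres dilated by the half-pixel square). This guarantees
  convex area ≥ area, scores axis-aligned convex shapes exactly 1.0, and
  gives the classic 5/7 for the plus-sign pentomino. For small digitised
  disks the corner hull exceeds the pixel count by roughly
  $\tfrac{1}{2}P/A$, so disk solidity approaches 1 from below
  (≈ 0.957 at r = 20 px, ≥ 0.98 from r ≈ 50 px); this digitisation bound
  is intrinsic to any hull convention that never under-covers the region.
* Collinear (degenerate-hull) components are defined to have solidity 1
  and min Feret 0; the aspect ratio is `NA` when min Feret is 0.

## Seed–halo pairing

Two modes:

* **Rank matching** (default, faithful to the supervised protocol): seeds
  are sown along diagonal lines so that every successive seed sits strictly
  lower on the plate; top-to-bottom numbering then pairs seed k with halo
  k. Its known failure mode is a rank shift: if one halo's topmost point
  overtakes its predecessor's (e.g. an unusually large halo), every later
  pair is off by one. Unequal seed/halo counts therefore truncate with a
  warning instead of aborting.
* **Containment matching** (opt-in, recommended): a seed pairs with the
  halo whose region contains the seed's centroid pixel. Halos containing
  two or more centroids are merged halos and yield no pairs (warning);
  seeds with no containing halo are reported unmatched (e.g. mucilage-free
  mutants). This mode is independent of sowing geometry, and the original
  protocol's manual table join is automated here — a deliberate behavioural
  extension, since the rank hazard is well documented.

On clean diagonal plates the two modes provably agree, and the tests assert
exactly that.

## The synthetic plate generator

`generate_plate()` renders plates with analytic ground truth so that every
stage is testable without any external data. What it emulates: the
light-blue gel (RGB 190, 215, 235), dark elliptical seeds (60, 40, 30),
concentric halos with a radial dye gradient from (200, 120, 180) at the
seed to (215, 150, 200) at the rim — all palette constants chosen so the
flax default bands segment them — plus additive Gaussian sensor noise and
hard pixel-centre rasterisation. Defaults describe a flax plate: ~30 seeds
(the practical capacity of one plate for flax), seeds ~4.8 × 2.4 mm, halo
radii ~4.8 mm (areas ≈ 48–105 mm², inside the 18–315 mm² filter), 8 px/mm.
Ground truth uses closed forms: ellipse area $\pi ab$, Ramanujan's second
perimeter approximation (relative error < 10⁻⁴ at seed aspect ratios),
halo area $\pi R^2$.

Sowing modes: `"diagonal"` places seeds on a sheared grid — several
diagonal lines, with every seed strictly lower than its predecessor — which
is how plates are actually sown at 30 seeds, and which guarantees exact
rank pairing by construction (halo radius variation is truncated so
consecutive halo tops cannot reorder). `"jittered"` perturbs positions to
exercise containment matching; `"overlap_pair"` renders two ~170 mm² halos
whose merged component (~330 mm²) exceeds the 315 mm² bound, exercising the
deletion filter. A `border_touch` flag pushes the first halo across the top
image border.

What the generator does *not* emulate — and hence what passing tests do not
show about real plates: uneven illumination and staining gradients across
the gel, dye diffusion kinetics (halos are hard-edged disks with a clean
radial gradient), partially adherent mucilage, touching seeds, out-of-focus
blur, JPEG artefacts, and anisotropic pixels. Accuracy statements from the
synthetic validation (areas within 3%, ratio within 4%) are statements
about segmentation-to-measurement fidelity under separable colours, not
about biological measurement error on real images.

## Validation set-up and problem sizes

The test suite validates end-to-end recovery on 20 plates of 5–30 seeds
(half clean, half with σ = 5 noise on 8-bit channels) at 8 px/mm — roughly
450–900 px square images — asserting seed and halo areas within 3% of the
analytic truth, adjusted ratio within 4%, and 100% rank-pairing accuracy in
diagonal mode; descriptor anchors use digitised disks of radius 20–100 px,
100 random blobs against the Feret oracle and 100 random histograms against
the intermeans oracle. These sizes were chosen as the smallest that
exercise every code path at realistic resolution.

## Degenerate inputs and numerical conventions

* Coincident calibration points, non-positive distances: calibration error.
* All-zero or single-bin histograms: degenerate-histogram error (suggester
  falls back to defaults with a warning).
* Empty masks label to zero objects; empty labelings measure to an empty
  table; matching empty tables yields an empty pair table.
* Hue of achromatic pixels is 0; black has saturation 0. The 8-bit hue
  quantisation step is 360/255 ≈ 1.41°, so an RGB→HSV→RGB round trip moves
  the intermediate channel by up to `delta · 1.41/60 + 1` levels (≈ 7 at
  full chroma); max/min channels survive within one level. Threshold tests
  therefore carry a ±1-level tolerance on hue-derived values.
* Intermeans ties round half up; the iteration is clamped to the occupied
  intensity range and capped at 256 steps (it converges far earlier in
  practice).
* CSV outputs round numeric columns to 4 decimals so repeated runs are
  byte-identical across platforms.

## Known limitations

* Touching seeds are not split (no watershed); merged halos are deleted,
  not divided — both by design, matching the deletion filter's purpose.
* The species presets other than flax reuse the flax threshold bands;
  their area filters are scaled defaults. Recalibrate per imaging set-up:
  generate the overlay for one representative plate, run
  `suggest_seg_params()`, and adjust the non-trivial bounds.
* A single isotropic scale is assumed (square pixels).
* The corner-corrected perimeter slightly under-measures elongated
  axis-aligned shapes; circularity of such shapes is accordingly
  optimistic.
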