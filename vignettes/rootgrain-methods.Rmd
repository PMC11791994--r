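---
title: "Methods: fine-grained root phenotyping from instance masks"
author: "rootgrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-grained root phenotyping from instance masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootgrain)
```

# Scope and model of the data

`rootgrain` covers the mask-centric stages of a fine-grained root phenotyping
pipeline for in situ scans of roots growing against a transparent panel in
soil. The data model is: a scan (grayscale or RGB raster, nominally 1200 dpi,
up to ~10 200 × 14 039 px), a polygon annotation document per scan (Labelme
dialect: `shapes` with `label` and `points`, `imagePath`, optional base64
`imageData`, `imageHeight`, `imageWidth`), and — downstream of an instance
segmenter — one binary mask per detected root segment. The package does not
train or run the segmentation network; it prepares its training data
(tiling), repairs its outputs (largest connected domain), measures per-root
traits from single-object masks, and accounts for the network architectures
analytically.

All pixel coordinates are 0-based with `x` = column and `y` = row, the
annotation format's convention; mask matrices are indexed `[y + 1, x + 1]`.
Physical scale is `mm_per_px = 25.4 / dpi` (`scaleModel()`).

# Annotation tiling

Scans are far larger than what GPU memory admits for training, so scans and
annotation documents are split into `s × s` tiles (default 2048 px, grid of
`ceiling(H/s) × ceiling(W/s)` per-tile origins `(col·s, row·s)`).
Two restriction modes exist because the verbatim splitting procedure and
sound geometry disagree:

* **faithful** — subtract the tile origin from every vertex, delete vertices
  with `x > s`, `x < 0`, `y > s` or `y < 0` (strict tests: `x = 0` and
  `x = s` survive), then delete shapes left with two or fewer vertices.
  Boundary-crossing polygons are distorted (their outside vertices simply
  vanish), which is the historical behaviour and is kept for reproducing
  datasets built that way.
* **clip** (default) — Sutherland–Hodgman intersection of the polygon with
  the tile window. The window is convex, so the result is a single polygon;
  a subject polygon whose true intersection is disconnected comes back with
  degenerate bridges along the window edge, an accepted limitation (the
  environment provides no general polygon-clipping library, and annotation
  consumers are tolerant of such bridges).

Edge tiles are padded with background to a full `s × s` (a flag of
`tileGrid()`; discarding partial tiles is the alternative convention).
`imageData` in tile documents is `null` unless re-encoding is requested, in
which case the tile PNG is embedded as single-line base64 and the document
opens self-contained in the annotation tool. Unknown JSON fields pass
through untouched, and field order is preserved so a read → write round trip
is byte-identical up to float formatting.

# Largest connected domain

Predicted masks of long roots often swallow fragments of neighbouring roots
lying inside the same detection box. `largestComponent()` keeps exactly one
connected component per mask. Decisions taken where the procedure is
underspecified:

* **criterion** — default `area` (foreground pixel count), matching the
  stated goal of keeping the largest connected domain. `contour_length`
  (boundary point count per component) is retained because published
  pseudocode of this step ranks contours by their point count, which can
  misrank a compact blob against a long thin fragment; the test suite pins
  down exactly that divergence.
* **connectivity** — default 8, so thin diagonal root runs stay connected;
  4 available.
* **ties** — the component whose first pixel comes earliest in row-major
  order wins; results are bit-stable across runs.
* **empty masks** — an error from `largestComponent()` (the caller decides),
  but `postprocessDetections()` — which also applies the prediction-time
  confidence threshold, default 0.4 — drops them silently so batch runs never
  crash.

# Skeletonisation

`thinMask()` reduces a single-object mask to a one-pixel-wide, 8-connected,
topology-preserving medial curve. The default method is the K3M phased
border-marking scheme: neighbours are weighted 1…128 clockwise from north;
phase 0 marks border pixels by a weight lookup; phases 1–5 sequentially
delete marked pixels with 3…7 "sticking" neighbours per rotation-closed
lookup sets; the cycle repeats to a fixpoint and a final one-pixel-width
pass follows. Deletion is sequential in row-major order with weights
recomputed on the fly — this is what preserves connectivity, and it makes
results deterministic. A classical Zhang–Suen two-subiteration thinning
(followed by the same width-1 pass) is available as `method = "zhangsuen"`;
the contract both must meet is the postcondition set: width 1 (no 2 × 2
foreground square), one connected component, holes preserved, skeleton ⊆
mask. The tests assert the postconditions rather than a particular pixel
set, so either method may be used interchangeably.

**Spur pruning.** Mask-boundary roughness thins into short side branches.
`pruneSpurs()` removes every branch running from a branchpoint to an endpoint
in fewer than `minBranchPx` pixels (default 10 px ≈ 0.21 mm at 1200 dpi),
repeating until stable. Two refinements proved necessary in practice:
the two endpoints realising the skeleton's longest geodesic are never pruned
(a rounded root tip can thin into a short fork; pruning both prongs blunts
the main curve and can leave a skeleton without endpoints), and a final
width-1 pass clears one-pixel junction remnants. Pruning happens before
polyline ordering; the reverse order is defensible but was not chosen.

**Polyline.** `toPolyline()` returns the longest geodesic between endpoints
on the skeleton's pixel graph (8-adjacency, steps weighted 1/√2). Diagonal
edges that merely short-cut an axial corner are dropped from the graph so the
path traverses the curve instead of cutting corners. Residual side branches
are ignored: each root is analysed as a single curve. A closed loop (no
endpoints) raises `"cyclic skeleton"` rather than guessing.

# Trait measurement

* **Length.** `rootLength()` is the Euclidean chain sum (1 per axial step,
  √2 per diagonal step, scaled to mm). Raw pixel chains overestimate smooth
  curves by up to ~8 % at intermediate orientations (the classical staircase
  bias of the (1, √2) estimator), so the pipeline measures length on a
  polyline resampled every 5 px (`resamplePolyline()`), which tracks true
  arc length to well under 1 %. Thinning also stops at the centre of each
  rounded root tip; `phenotypeInstance()` adds the local cap radius
  (distance-transform value − 1) at both tips. Both corrections are flags
  (`resamplePx`, `tipCorrection`).
* **Diameter.** Local diameter at a skeleton pixel is `2·EDT − 1` px
  (pixel-centre convention: a width-1 line has EDT 1, diameter 1; a 5-wide
  strip has interior EDT 3, diameter 5). Evaluated literally on the integer
  grid this convention loses up to ~1.6 px on oblique roots — the skeleton
  sits up to half a pixel off the true centre line and the nearest
  background pixel centre quantises the boundary distance — which is material
  at fine lateral-root widths (a 0.4 mm root at 1200 dpi is only 19 px wide).
  `rootDiameters()` therefore evaluates the *same* convention at half-pixel
  resolution: the EDT of the 2× pixel-replicated mask, reduced per original
  pixel, for which `2·EDT_half` equals `2·EDT − 1` exactly on axial
  cross-sections and is far less orientation-biased on oblique ones. Skeleton
  pixels inside the rounded tip caps (closer to a tip, along the curve, than
  the local radius) are excluded from the statistics, because cap
  cross-sections are geometrically narrower than the trunk. Statistics
  reported: mean, max, min over the retained skeleton pixels.
* **Areas.** Projected area = foreground pixel count × `mm_per_px²`;
  cylindrical surface = `π · d_avg · L`. Both are reported since "surface
  area" is ambiguous between projection and cylinder models.
* **Curvature.** The ordered polyline is rotated so its principal axis
  (leading eigenvector of the coordinate covariance, oriented along the
  traversal direction) lies along x — near-vertical roots would otherwise
  make y(x) multivalued — and `y = a·x² + b·x + c` is fitted by least
  squares (`fitQuadratic()`; rotation, centroid, domain and residual RMS are
  recorded). Curvature uses the standard plane-curve formula
  `K = |y''|/(1 + y'²)^{3/2}` with `y' = 2ax + b`, `y'' = 2a`, and
  `ρ = 1/K`; a printed form of this formula elsewhere is typographically
  garbled, and only the standard form is consistent with `ρ = 1/K`. The
  single-number summary is `K` at the domain midpoint by default; the vertex
  value `|2a|` and the closed-form mean of `|K|` over the domain are
  selectable, since no evaluation point is canonical. Straight roots
  (`a ≈ 0`) report `K = 0`, `ρ = ∞`, flag `straight`, never an error. The
  negative-log transform `−log K` (natural log by default; the base is a
  flag) maps small curvatures to a scale on which growth trends are visible.
  Curvature is invariant under rigid motions of the input (tested to 1e-6
  relative) and `ρ·K = 1` exactly whenever `K > 0`.

`phenotypeInstance()` chains largest-component → thinning → pruning →
polyline → traits; `phenotypeBatch()` maps it over a mask list or directory,
catching per-instance failures into a `status` column so one bad detection
cannot kill a batch, and stamping an acquisition day for time-series tables.

# Architecture accounting

`buildSpec()` resolves the YoloV8seg family layouts (variants n/s/m/l/x with
their depth/width multipliers and channel caps) and the elongated-target
variant into explicit layer graphs; `countParams()`/`countLayers()`/
`countFlops()` sum closed-form per-layer formulas (conv `k²·c_in·c_out` plus
2·c_out affine normalisation terms; C2f/SPPF/head blocks decomposed into
their convs). Conventions, chosen to match the family's published summaries
and validated against all five published variant rows:

* **layers** counts unique modules of the flattened module tree (a conv block
  is container + convolution + normalisation, with the single shared
  activation object counted once per model);
* **parameters** count weight tensors and affine normalisation terms
  (including the fixed distribution-focal conv);
* **FLOPs** are twice the convolution multiply-accumulates plus
  normalisation element operations, evaluated at an explicit input size
  (default 640 × 640, the family's reporting convention, recorded in every
  `CountReport`). Heads predict 2 classes (primary root, lateral root).

The elongated-target variant keeps the n backbone verbatim as a prefix and
appends two stride-2 downsampling stages at 256 channels (P6/64, P7/128,
fusion blocks of 2 repeats), a full top-down/bottom-up neck across P3…P7,
and detect/segment heads at all five strides. The added stages' exact widths
are not published as text; the frozen choice — top-down fusion widths
256/256/192/64, bottom-up 128/256/256/256 — is the configuration whose
layer, parameter and FLOP counts reconcile with the published accounting of
this design (431 layers; a uniform cap-width extension misses the published
parameter and FLOP totals by 2–4 %). `exportModelConfig()` /
`importModelConfig()` round-trip the layouts through the family's YAML
dialect. `selectTrainingTargets()` implements the training-target filter:
degenerate boxes are always dropped; the aspect-ratio < 100 restriction is
optional and off by default, admitting elongated root boxes.

# Synthetic root scenes

The generator provides geometric ground truth, not photorealism: soil is
speckle noise, roots are uniform-intensity bands. A root is a parametric
medial curve — straight segment, circular arc, or quadratic — rasterised at
0.25 px arc-length steps and widened by thresholding a 2×-supersampled
distance field at the cap radius (+0.75 px, which keeps axial cross-sections
at the exact odd nominal width; a binary disc-brush dilation draws diagonal
bands visibly too thin). The stated length is tip-to-tip: the medial curve is
trimmed by one cap radius per end so the rounded tips land on the stated
length. Ground truth per instance: analytic arc length, the nominal
rasterised diameter, and the analytic curvature (exactly `1/R` for arcs, 0
for straights, the mid-arc value for quadratics — note that a quadratic's
curvature varies along the curve, so closed-loop curvature validation uses
constant-curvature arcs).

Default study conditions (chosen once for realism at desk scale): scenes at
300 dpi on a 40 × 40 mm canvas — the same ~12–33 px-per-diameter regime as
1200 dpi scans of 0.35–0.7 mm lateral roots at a quarter of the pixel count —
with root lengths 4–14 mm, diameters 0.35–0.7 mm, mostly-downward growth
(±57° around vertical), arc radii 8–25 mm for the curved pattern, and
overlapping placements accepted with probability 0.2 (overlaps are resolved
in favour of the later-drawn root in the composite image only; instance
masks stay separate). Scene annotations carry one contour-traced polygon per
instance. Closed-loop recovery under these conditions (50 seeded roots at
1200 dpi) is within 2 % for length, 5 % for diameter and 10 % for curvature,
per instance.

The growth time series emulates scans collected every other day, with two
presets: **curved** roots elongate fast (2.5–3.5 mm/day) while their total
bend angle grows slowly, so `K = angle/length` falls and `−log K` rises day
by day — the signature of roots that keep growing downward as they bend;
**straight** roots elongate slowly (0.3–0.7 mm/day, stagnating growth) at a
fixed large bend radius (80–200 mm), so their small curvature barely
changes. Under these presets per-day length increments are strictly larger
for every curved root than any straight one, curved length distributions
disperse faster, and the measured `−log K` trend is positive and steeper for
the curved series — ordering statements only; no magnitudes are claimed for
real roots.

What passing tests on synthetic scenes do **not** show: robustness to real
soil texture, root hairs, moisture films, scanner optics, touching roots of
similar intensity, or segmentation errors other than the disconnected-
fragment kind the post-processing stage addresses.

# Numerical choices and limitations

* Deterministic row-major scan order everywhere (thinning passes, component
  tie-breaks), so identical inputs and seeds give byte-identical outputs.
* Thinning cost is proportional to root width; masks are cropped to their
  foreground bounding box (plus a 2 px guard) before thinning.
* Problem sizes in the test suite — scenes of ≤ 12 roots at 300 dpi, 50
  single roots at 1200 dpi, 100-seed oracle sweeps on 40 × 40 px masks —
  were chosen so the whole suite completes in well under a minute per file
  on one CPU while still exercising every tolerance stated above.
* The quadratic curve model is deliberate (one curvature summary per root);
  strongly S-shaped roots are outside its validity, and their residual RMS
  (recorded in `QuadraticFit`) is the diagnostic.
* `faithful` tiling distorts boundary-crossing polygons by construction;
  use `clip` for new datasets.
* Architecture accounting counts; it never trains, runs inference, or
  exports weights. Published FLOP figures obtained with runtime profilers
  can include small profiler-version-dependent terms; the analytical
  convention here stays within ~1 % of them.
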