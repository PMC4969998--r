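---
title: "Measuring plant morphology on triangle meshes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring plant morphology on triangle meshes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(phenomesh)
```

## The measurement problem

Optical scanners (structured light, laser triangulation) deliver plant
surfaces as triangle meshes: vertex positions in millimetres plus triangular
connectivity. Morphological parameters that are difficult or destructive to
measure by hand — the length of a twisted strap leaf, the area and enclosed
volume of a succulent organ, the surface-to-volume (S/V) ratio that
characterises water economy in xerophytes — become geometric computations on
that mesh. phenomesh implements those computations together with the
supporting analyses a practitioner needs before trusting them: how the
measurements degrade with mesh resolution, and how to patch the small holes
that thorns and prickles leave in structured-light scans.

All coordinates are taken to be millimetres; there is no unit option, and
every derived quantity is reported in mm, mm², mm³ or mm⁻¹ accordingly.

## Mesh model and morphometrics

A `trimesh` stores an *n* × 3 vertex matrix and an *m* × 3 face matrix.
Faces use 1-based vertex indices, the natural convention in R; the 0-based
conventions of PLY and STL are translated at the file boundary only, and
OBJ's 1-based indices pass through unchanged. STL files carry no
connectivity, so their per-facet corners are welded by exact coordinate
equality on load; PLY and OBJ are never welded implicitly, since an
unreferenced duplicate vertex in those formats is an authorial decision, not
a format artefact.

Surface area is the sum over faces of half the cross-product magnitude.
Enclosed volume is the absolute sum of signed tetrahedron volumes spanned by
each face; the apex is the vertex centroid rather than the origin, which is
mathematically equivalent on a closed surface but avoids catastrophic
cancellation for meshes far from the origin. Volume requires a closed,
manifold surface: `enclosed_volume()` refuses open meshes (naming the number
of boundary loops) and first makes the face windings consistent by
breadth-first flood fill across shared edges, flipping globally if the
signed total is negative. Scanned meshes arrive with arbitrary winding, so
orientation is treated as something to repair, not to trust.

Degenerate (zero-area) faces are kept in the topology — scanners produce
slivers, and silently deleting them would change vertex/face counts — but
they contribute nothing to area or volume; `validate_mesh()` counts them.

Mesh *resolution* is summarised as the mean length of the unique undirected
edges (`mean_edge_length()`). Unique edges rather than per-face half-edges:
interior edges would otherwise be counted twice, biasing the mean toward
dense interior regions.

## Geodesic distances

Two surface-distance notions are provided, and they bracket the truth from
opposite sides:

* **Edge-graph Dijkstra** (`dijkstra_path()`): the mesh is converted to a
  weighted graph (vertices; edges weighted by Euclidean length) and the
  shortest edge-restricted route is found. This always *over*estimates the
  true geodesic, because paths may only travel along edges. Determinism is
  pinned down explicitly: among equal-cost frontier vertices the lowest
  index is settled first, and a vertex keeps its first minimal predecessor,
  so reported paths are reproducible. The search stops as soon as the
  destination is settled.
* **Fast marching** (`fmm_distance()`): a first-order eikonal solver whose
  front crosses triangle interiors. Each triangle contributes a two-point
  update — the arrival time of a planar unit-speed wave fixed by the two
  already-accepted vertices — with a causality check that the characteristic
  enters through the triangle; when the angle at the update vertex is obtuse
  or no causal planar wave exists, the update falls back to the one-point
  edge value. The fallback equals Dijkstra's relaxation, which guarantees
  the fast-marching field never exceeds the edge-graph distance. The
  alternative (virtual unfolding of obtuse triangles) buys accuracy in
  pathological meshes at substantial complexity; the UV-sphere pole caps are
  the worst case here and the test suite shows sub-0.1% error without it.

On the 50 mm validation sphere the test suite verifies the full ordering
chain at every vertex — analytic arc ≤ fast-marching × (1 + 2%) ≤ Dijkstra —
and that the maximum fast-marching error shrinks monotonically over a
6° → 4° → 2° refinement ladder. Eight degrees, the natural next-coarser
rung, does not divide 180° and therefore cannot be built as a uniform
latitude–longitude sphere; the ladder starts at 6° instead.

## Centerline length of a twisted leaf

The botanical length of a strap leaf runs along its midline. On a twisted
leaf the shortest surface path cuts corners and underestimates it, so the
midline is reconstructed in five steps:

1. collect the leaf's outer edge (all boundary-loop vertices), optionally
   excluding a radius around the endpoints;
2. map each vertex's distance **to that edge** by fast marching;
3. map the distance **from the start point** by fast marching and slice the
   mesh into *k* bands of equal distance width, using the end point's
   distance as the total;
4. in every band except those containing the start and end, take the vertex
   farthest from the edge (ties to the lowest index) — a midline waypoint;
5. chain shortest edge paths start → waypoints (in band order) → end and sum
   their lengths.

Design choices the procedure leaves open, and how they are fixed here:

* **k defaults to 10** (CLI flag `--bands`). Bands must stay several edge
  lengths wide so every band is populated; at 1 mm resolution on
  decimetre-scale leaves, 10 bands keep band width ≥ 15 edge lengths.
  `band_partition()` fails loudly ("k too large for mesh resolution") if an
  intermediate band comes out empty. The straight-strip test shows the
  result is insensitive to k (k = 3 vs k = 10 differ < 1%).
* **Inter-waypoint routes use edge-graph Dijkstra**, not gradient descent on
  the fast-marching field: the deterministic edge paths compose exactly
  (segment lengths sum to the total) and the waypoint spacing — several
  band widths — makes the lattice overestimate negligible next to the
  quantities measured.
* **Waypoint order follows band index**, not field value, so a noisy
  distance field cannot reorder the chain.
* **The exclusion radius defaults to 0**: the entire margin is "the edge".
  A nonzero radius is useful when the mesh ends in an artificial cut (a
  detached leaf, a pot boundary) whose vertices should not attract the
  midline.
* **No smoothing** is applied to the waypoint chain; the reported length is
  exactly the sum of the Dijkstra segments.

The twisted-ribbon generator makes this algorithm's hardest case exactly
checkable: the ribbon twists about its own midline axis, so the true
centerline is the straight axis with length known analytically (the margins
are helices, strictly longer). The tests run the recovery on a 180 × 30 mm
ribbon with two full turns at ~1 mm resolution and require the estimate
within 3% of the axis length and strictly above the direct shortest path.
In those tests the transverse sample count is even, so the axis is *not* a
lattice line — on real scans the midline never coincides with a mesh path,
and an odd count would make the degenerate case (centerline = shortest
path = axis) possible.

## Resolution-versus-error analysis

`resolution_study()` reproduces the standard accuracy experiment: remesh a
model to a ladder of coarser resolutions, recompute every measurement per
rung, and express each as a relative error

> error = |reference − model| / reference × 100%

against the densest model — always the input mesh itself; the study never
upsamples. The absolute value is deliberate: a coarse model can slightly
*exceed* the reference (volume does, on near-flat regions), and error tables
conventionally print such cells as positive percentages.

Coarsening uses isotropic remeshing — iterated long-edge split (> 4/3 of
target), short-edge collapse (< 4/5 of target, link-condition guarded),
valence-equalising edge flips, and tangential relaxation with relaxed
vertices projected back onto the input surface via a uniform-grid
closest-point query — because the experiment's independent variable is the
mean vertex spacing, which isotropic remeshing controls directly (quadric
decimation controls triangle count and error, not spacing). Boundary
vertices move only along boundary collapses, so boundary-loop count,
closedness and genus are preserved; the iteration stops when the mean edge
length is within ±10% of the target and errors out, reporting the achieved
mean, if the mesh is too small to coarsen further. Only coarsening is
supported: a scan should be re-exported, not invented, when finer data are
needed.

`resolution_threshold()` then answers the practical question — the coarsest
mean edge length whose errors all stay within a tolerance. On the
synthetic sphere the suite verifies the headline expectation that a ~1 mm
mesh keeps area and volume errors below 1% of the analytic values.

### What S/V invariance does and does not mean

Because vertices are projected onto the input surface, a coarsened mesh is
locally *inscribed* in the reference surface. For a curved closed shape this
couples the errors: chords shorten both area and (more strongly) the
supporting height of the volume tetrahedra, making the volume deficit
roughly twice the area deficit, so the S/V error tracks the area error
rather than vanishing. The test ladders on the sphere and on a wrinkled
"scan-like" blob (1 mm ripple, 12 lobes — emulating the fine relief of
structured-light scans) show S/V drifting below its ingredient errors at
moderate coarsening, but a ladder whose coarsest rung loses more than 2% of
area cannot keep full-precision S/V drift under 1% on such
curvature-dominated shapes. S/V stability across an aggressive ladder is a
property of surfaces whose coarse-resolution error is proportional shape
simplification (thin scanned leaves behave this way, and S/V tables are
conventionally printed at two decimals, which hides sub-percent drift); it
is not a universal mesh property, and the acceptance suite records this
distinction rather than papering over it.

## Hole repair

`detect_holes()` classifies boundary loops by perimeter: loops at or below
the threshold (default 50 mm, CLI `--max-perimeter`) are punctures; larger
loops are the leaf margin or the cut where a pot was removed. Perimeter is
the discriminator because it is scale-appropriate and directly testable; no
shape heuristic is attempted. `fill_holes()` closes each loop with a
triangle fan from the loop centroid (added as a new vertex, wound opposite
to the adjacent faces so orientation stays consistent). The repair is purely
additive — no existing vertex moves, no existing face changes — so area can
only grow, and `area_report()` accounts for exactly the added patch. A
centroid fan is the right tool for small, nearly planar thorn punctures; it
makes no attempt at curvature-aware filling, and a wildly non-planar loop
can self-intersect undetected. Large-defect reconstruction is out of scope.

## Synthetic meshes and their ground truth

Every fixture the tests use is generated in code, deterministically:

* `uv_sphere(radius, resolution_deg)` — latitude rings at multiples of the
  step (poles excluded), longitude circles at the same step, each quad split
  along the (ring *i*, lon *j*)–(ring *i*+1, lon *j*+1) diagonal, pole fans.
  The step must divide 180°. Vertices lie exactly on the sphere, so area and
  volume are strictly below 4πr² and (4/3)πr³ and converge monotonically
  under refinement; at 2° and r = 50 mm the construction gives 16,022
  vertices, 32,040 faces and 2·r·sin(1°) ≈ 1.7 mm equatorial spacing. The
  fixed diagonal makes the construction reproducible; alternative diagonal
  conventions change area and volume by far less than the 0.05% tolerance
  used in validation.
* `twisted_ribbon(length, width, twist, ...)` — a segment swept along a
  straight axis while rotating about it; per-vertex (length-fraction,
  width-fraction) parameters ride along as ground truth. Twisting about the
  midline is what makes the centerline analytically known.
* `perforated_ribbon(...)` — the ribbon with faces removed wherever all
  three vertices fall inside a punched disc in the flattened parameter
  plane; each hole adds one boundary loop. Because removal is
  vertex-containment-based, the realised hole under-covers the disc by
  about one grid spacing of radius: hole-area assertions use either the
  exact removed area (flat ribbons, where the fan fill is exact) or discs
  several grid spacings wide.
* `primitive_mesh()` — exact cube and regular tetrahedron for closed-form
  oracles; `wrinkled_blob()` — a ripple-modulated sphere for scan-like
  resolution ladders.

What the generators deliberately do not emulate: scanner noise and
registration artefacts, non-manifold junk, texture, and globose spiny
plants that structured light cannot capture at all. Tests passing on these
fixtures validate the geometry pipeline, not scanner physics.

## Numerical choices, sizes, limitations

* Distances, areas and volumes are 64-bit doubles in mm; no grid snapping.
  Report printing rounds measurements to integers and errors to two
  decimals, but all arithmetic keeps full precision.
* Ties (Dijkstra frontier, waypoint argmax) break toward the lowest vertex
  index, so identical inputs give identical outputs on any platform.
* The test suite works at desk scale deliberately: spheres at 90°–1°
  (up to ~64k vertices), ribbons at 0.5–2 mm sampling (~5k–22k vertices),
  remeshing ladders of four rungs on ~16k-vertex inputs. These sizes
  exercise every code path while keeping the whole suite in the
  single-digit minutes.
* Known limitations: fast marching is first-order (errors grow on extremely
  anisotropic triangles beyond the obtuse fallback's reach); the remesher
  targets mean edge length, not element quality bounds; hole filling does
  not check fan self-intersection; non-manifold meshes are diagnosed but
  not repaired.
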