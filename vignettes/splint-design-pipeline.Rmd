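---
title: "How splintforge designs a printable splint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How splintforge designs a printable splint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splintforge)
```

## The design problem

A custom wrist/forearm splint is a rigid shell that covers the immobilization
region of a limb with a small clearance, split into parts that print quickly
and screw together, perforated for ventilation, and edged with tubes so it
does not abrade skin. The clinical inputs are deliberately minimal: a scanned
limb surface placed along +X on the XY plane (palm up), and two curves drawn
in the XY plane — line A bounding the splint on the distal (palm) side, line
B on the proximal (body) side. Everything else is computed.

Handheld-scanner meshes are imperfect: backlit patches drop out, leaving
holes of a few square centimetres, and the thumb web-space produces geometry
that a single surface cannot cover. The pipeline is therefore *flaw
tolerant*: holes are reported at intake but never "fixed" on the mesh;
instead they are repaired where they actually cause trouble — on the
cross-section curves — which is both local and robust.

## Stage by stage

### 1. Intake

`read_mesh()` consumes STL/PLY/OBJ in millimetres, merges duplicate vertices
(1e-6 mm) and drops degenerate faces, keeping boundary loops.
`validate_placement()` reports — never enforces — the placement convention:
the angle between the limb's long axis and +X, plane contact, and the hole
census. The long axis is estimated robustly (a consensus line through
cross-slab medians) so a thumb branch or a flaw rim does not skew it;
`align_to_convention()` is available when a mesh arrives in the wrong pose.
Units from the scanner are undocumented in practice; millimetres are assumed
and documented here.

### 2. Covering surface

The limb is offset 2 mm along area-weighted vertex normals to leave swelling
room (2–3 mm is routine practice; the offset is a config knob and can be
raised for fracture patients). Between the resampled curves A and B,
interior guide polylines are *pointwise linear blends* after arc-length
resampling — the simplest monotone morph between the two drawn shapes — at a
default spacing of 15 mm (`n_inner = round(L/spacing) − 1`, half-up). Each
guide extrudes vertically into a cutting surface; its intersection with the
mesh is chained into maximal polylines with a 0.5 mm closure tolerance.

Two flaw classes are handled per station:

* **Open sections** (scan holes). The surviving path is resampled to 16
  points by arc length and a periodic cubic spline is interpolated through
  them, bridging the gap smoothly. Gaps of ≥ 50 % of the path length are
  refused with advice to move the input curves — interpolation cannot
  recreate shape that was never scanned.
* **Dual sections** (line A crossing the thumb web-space). Exactly two
  closed loops are bridged by a rectangle of ±5 mm about the
  centroid-to-centroid line; the outline of the union (computed in the
  developed, isometric coordinates of the cutting surface) is smoothed by
  periodic interpolation. The 10 mm corridor later becomes the slim gap that
  fixes the thumb.

Every accepted loop is resampled to `n_u = 96` arc-length-uniform points,
oriented counter-clockwise viewed from +X, seam-anchored at its topmost
point — that fixed correspondence is what makes skinning twist-free — and
passed through a curvature limiter that relaxes concave corners to a minimum
6 mm radius. The limiter exists because a tangential cut through the thumb
root, or a sharp union corner, can carry corners tighter than the shell
thickness; offsetting such a corner by 3–4 mm would fold the outer surface.
Six millimetres is 1.5× the maximum shell thickness, with margin.

The covering surface itself is a skinned grid: each u column is interpolated
longitudinally with a natural cubic spline (C1; the continuity order of a
CAD network surface is not observable from its output, so visual smoothness
is the requirement) and sampled at `n_v = 8 ×` sections rows. The four guide
curves through per-section extremes (max/min z, max/min y) are reproduced by
construction and act as a QC constraint rather than a second interpolation
family — this reproduces the network-surface construction without a NURBS
solver, and keeps every later query (area, division, engraving) a structured
grid operation.

### 3. Division and thickness

Two sizing rules, both clinician-adjustable:

* **Part count**: 3 equal circumferential parts if the covering area
  strictly exceeds 260 cm² (about an adult palm's covering surface), else 2.
  Ties go to 2 parts. A `wrist_2part` splint type forces 2 regardless —
  part count and thickness are deliberately independent computations,
  because a mid-sized wrist splint can exceed the reference area while still
  printing comfortably in two parts.
* **Thickness**: linear remap of [150, 600] cm² (child's palm to adult
  forearm) onto [2.8, 4.0] mm, clamped outside. Thickness is computed once
  from the total area, not re-evaluated per part, so mating parts always
  agree. The mapping is a printable-strength heuristic; true structural
  sizing would need mechanical validation and is out of scope.

The u domain is cut at equal arc-length seams anchored at the lateral
(y-max) seam so a two-part split separates dorsal/volar halves. Sections are
arc-length-uniform, so equal column counts give equal extents, and adjacent
parts share their seam column exactly — that shared column is also what
guarantees mating screw holes align. Each sub-surface grows into a solid
shell: outer grid = inner + thickness × per-point normals, four stitched
boundary bands, every edge on exactly two faces. A fold-over check compares
the offset surface's intrinsic normals against the base surface's and errors
with the offending (u, v) cell rather than emitting a self-intersecting
solid.

### 4. Diamond lattice

The 2D panel takes its width from the mean rim (U) edge length `Ua` and its
length from the mean seam (V) edge length `Va` of the divided surface.
Division counts are `round(Ua/20) × round(Va/28)` (half-up, floored at 1) —
20 and 28 mm per division are the standard coefficients, overridable because
they are a support-material heuristic, not physics. Inside a frame of margin
M = 8 mm (sized to host the rim tubes and screw seats), the inner rectangle
is tiled by oblique lines into (W/nu) × (H/nv) diamonds; the nu × nv whole
diamonds of one checkerboard family become ventilation cells, each inset by
the truss margin N = 1.6 mm (about three extrusion widths). Insetting a
rhombus is an exact similarity, so a cell collapses — and is dropped with a
warning — only when N exceeds half the cell's smaller half-diagonal. The
complementary family plus the insets is the printed X-truss; making both
families holes would leave no material, which is why the cell count equals
nu × nv exactly and the engraved genus is countable.

Engraving happens in parameter space, not by 3D booleans: the panel is
triangulated analytically around the holes (every vertex on the half-cell
lattice or an inset corner, so the triangulation is conforming by
construction), mapped through the shell's (u, v) parameterization onto the
inner and outer surfaces, and the matched hole rims are stitched with wall
bands. This gives an exact hole count, preserved watertightness, and no
dependence on boolean robustness. If a cell spans fewer than two grid cells
of the shell parameterization, divisions are reduced by one and the pattern
regenerated once — the same remedy a clinician would apply by hand — then it
errors.

### 5. Rounded edges and screw seats

Each rim (U) isocurve of the shell mid-surface, trimmed to the 0.01–0.99
curve domain so tube caps never poke past the seams, is swept with a circle
of diameter thickness + 1.5 mm using parallel-transport frames and capped.

Screw seats land at parametric positions 0.1 and 0.9 of each longitudinal
(V) edge, plus a midpoint seat when the edge is strictly longer than 180 mm
— so a part carries 4 or 6 seats. The M3 geometry (3.4 mm clearance hole,
5.6 mm across-flats hex pocket 2.6 mm deep, Ø 9 mm boss, height thickness
+ 2 mm) suits plastic M3 L10 screws with prefabricated caps; the screw works
by constraining the nut, since printable threads at this scale do not exist.
All dimensions are config keys.

Two departures from a naive boolean pipeline are deliberate:

* The screw axis is stood off outward from the seam mid-surface by
  thickness/2 + hole radius + 0.5 mm. With the axis in the seam plane the
  corridor would pass through the shell wall and require subtracting the
  hole from the shell itself; the standoff keeps the corridor clear while
  the boss still overlaps the shell for attachment, and mating bosses still
  meet at the seam plane because both parts derive the frame from their
  shared seam column (with ghost-column stencils so even the normal is
  computed identically on both sides).
* `partO − partI` (boss minus pocket and hole) is built directly as a closed
  ring-stitched solid — both operands are package primitives, so their
  difference has a closed form — and the final part is a component-wise
  union of closed manifolds (shell ∪ tubes ∪ seats). Every edge still bounds
  exactly two faces, which is the watertightness contract slicers need;
  overlapping closed shells are unioned by the slicer.

### Checkpoints and orchestration

`run_pipeline()` executes the stages with per-stage timing. The three
checkpoints (after sectioning, after division/thickness, after the lattice)
dump the section polylines as JSON, the covering surface as OBJ with a
sizing report, and per-part SVG pattern previews; in interactive mode a gate
function (terminal prompt by default) must approve each before the run
continues, mirroring how a clinician inspects intermediate geometry in a CAD
viewport. Batch mode auto-approves and is deterministic: identical inputs,
config and seed give byte-identical STL output. Configuration is a TOML file
mirroring `pipeline_config()`; every constant above is a key and is logged
into `assembly_metadata.json` for provenance.

## The synthetic limb

`generate_limb()` emulates what a handheld scan of a resting forearm+hand
looks like to this pipeline: an elliptic cross-section lofted along +X with
a smoothstep taper (defaults 45×34 mm proximal to 40×23 mm distal over
250 mm — adult forearm to flattened palm), resting on the XY plane with a
horizontal centreline. Surface noise is a smooth, seeded, low-frequency
radial field (a few modes in x and θ) rather than per-vertex jitter —
skin/scan undulation without self-intersections; 0.5 mm is a realistic
handheld-scanner amplitude. A thumb is a capsule blended into the body by a
smooth-min signed distance field and polygonized by marching tetrahedra
(Freudenthal decomposition, canonical edge interpolation so the mesh is
watertight by construction); this is the cheapest construction that gives
the *genuine* two-component section topology near the thumb, with no
anatomical fidelity intended — fingers are absent, and the default clinical
curves avoid the regions where a real scan is unusable anyway.
`inject_scan_flaws()` removes the faces inside an (x, azimuth) footprint —
2×4 cm and 1.5×2 cm elliptical holes reproduce the flaw sizes handheld
scanners typically leave — adding exactly one boundary loop per flaw and
refusing flaws wider than half the local circumference, which section repair
could not recover by design.

What passing tests on these fixtures shows: the geometric contracts (closed
analytic sections to <0.5 %, repair to <1 mm on a gapped circle, area
conservation, watertight/genus-correct engraving, deterministic reruns).
What they cannot show: behaviour on real scans with motion distortion
(explicitly not repairable here), anatomical pressure distribution, or
mechanical strength — the thickness rule remains a calibrated heuristic.

## Numerical choices

* Duplicate-vertex merge 1e-6 mm; STL round-trip tolerance 1e-4 mm (float32).
* Section closure tolerance 0.5 mm; segment chaining tolerance 0.05 mm;
  chains shorter than 3 mm are treated as numerical debris.
* Seam anchor = topmost point; orientation CCW viewed from +X; ties in
  extreme-point extraction break to the smaller u index.
* Periodic cubic interpolation (`stats::spline`, method "periodic")
  wherever a closed curve is regenerated; chord-length parameterization.
* Concave-corner limit 6 mm (1.5× maximum shell thickness).
* Division counts and station counts round half-up (floor at the rule's
  minimum); the 260 cm² part-count boundary is strict.
* Default problem sizes — `n_u = 96` (divisible by 2 and 3 so parts share
  seam columns), `n_v = 8` rows per section, 64-sample tube paths, 24-gon
  tube/boss sections, 2.5 mm marching-tetrahedra pitch — were chosen so a
  full design completes in a couple of seconds on one CPU, comfortably
  inside the interactive budget clinicians expect, with discretization
  errors an order of magnitude below the stated tolerances.

## Known limitations

* Repair is section-local: deformation/distortion from patient motion is
  out of scope, as is any flaw the clinician's curves cannot route around.
* Only the two-component merge is defined; three or more section components
  at one station error with advice to move the curves.
* The engraver assumes the shell grid resolves each diamond (≥ 2 grid cells
  per cell); it reduces divisions once, then errors.
* Unions are component-wise: exported parts are watertight edge-manifold
  assemblies of closed shells, not a single re-meshed boundary — exactly
  what slicers consume, but mesh-repair tools that demand one connected
  2-manifold per file will report multiple components.
* Velcro strap rings, FEA export and slicer integration are out of scope.
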