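---
title: "molray: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molray: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical decisions
behind `molray`, in the spirit of a methods section: what is computed, under
which assumptions, and where the discretizations can bite.

## 1. The molecular model

A structure is a table of atoms — name, element, chain, residue, occupancy,
B-factor — plus a list of coordinate frames (n × 3 matrices, Ångström) with
one *active frame* that every downstream stage reads. Radii come from
shipped tables: Bondi-style van der Waals values and Cordero-style covalent
values, with carbon-like fallbacks (1.50 / 0.76 Å) and one warning per
unknown element. Alternate locations other than blank/`A` are dropped: this
is a single-conformer viewer convention, and it makes atom counts and
geometry deterministic. Hydrogens are kept.

Bond perception, used when a file carries no connectivity, creates bond
(i, j) iff `min_dist < |p_i − p_j| < cov_i + cov_j + tol` with
`tol = 0.4 Å` and a `min_dist = 0.4 Å` clash cutoff, on a uniform spatial
grid so the cost is near-linear. The output ordering (i < j, lexicographic)
is part of the contract: every builder downstream is deterministic and
permutation-stable with respect to file order.

## 2. Discrete Solvent Excluded Surface

The SES is computed on a regular grid in three stages.

**Signed accessible field.** `f(p) = min_i(|p − c_i| − r_i) − r_probe` is
negative strictly inside the probe-inflated atom union. Outside that union,
`f` is the *exact* Euclidean distance to its boundary (a property of sphere
unions that stage 2 exploits). Each atom stamps only a local box
(`r_i + probe + stamp_margin`), so cost is O(atoms · local nodes); nodes no
atom reaches get a positive sentinel, which preserves the field's sign —
the only thing later stages need far from the molecule.

**Level field.** With the exterior node set `E = {p : f(p) ≥ 0}`, an exact
separable squared Euclidean distance transform (Felzenszwalb's
lower-envelope-of-parabolas, implemented in C++ and O(n) per axis) yields
`EDT(p)`, and `h(p) = r_probe − EDT(p)` vanishes on the SES: points exactly
one probe radius inside the accessible boundary.

Two refinements matter numerically:

* *Sub-voxel correction.* `EDT` measures distance to exterior **nodes**,
  which sit up to one spacing beyond the continuous accessible surface;
  this inflates the SES radius by O(spacing) (≈ 6% area error for a single
  atom at 0.3 Å spacing). The distance transform also returns the *feature
  node* (nearest exterior node), and `f` at that node is precisely how far
  it lies beyond the continuous surface — subtracting it (clamped to
  [0, √3·spacing]) removes the bias to second order. The raw, uncorrected
  EDT remains available as `distance_transform()` and is what the
  brute-force oracle tests check exactly.
* *Exterior continuation.* Exterior nodes take `h = r_probe + f` rather
  than the constant `r_probe`. For probes well above the spacing this
  changes nothing (the zero crossing is deep inside the accessible volume);
  in the probe → 0 limit it lets the isosurface interpolate to the true van
  der Waals surface instead of snapping to the first exterior node.

**Marching cubes.** The standard 256-case extraction with edge-interpolated
vertices and gradient normals. The case table is not copied from the
literature: it is derived once at load time. On each cube face, the
isosurface cuts the boundary in crossings that are paired
(leaving-positive → next entering-positive along the face walk, viewed from
outside) and directed so the positive region lies to the left; ambiguous
faces thus always connect the positive corners, and because the rule
depends only on the shared face's signs, adjacent cubes agree — meshes are
watertight (every interior edge is used by exactly two triangles, verified
in the tests) and consistently oriented toward increasing field, i.e.
outward. Shared edge vertices are merged globally. Normals are the
linearly-interpolated central-difference gradient, unit-normalized;
triangle winding is flipped where it disagrees with the gradient.

Defaults: probe 1.4 Å (water), spacing 0.4 Å (CLI-overridable), grid
padding `max(r_i) + probe + 2·spacing`. The acceptance suite pins the
accuracy contract: single-atom SES area within 3% of 4π·1.7² at 0.3 Å
spacing, additivity for well-separated atoms, and monotone improvement with
refinement.

## 3. Rendering

GPU viewers rasterize a screen-aligned quad per primitive and ray-cast the
implicit equation in the fragment shader. Headless, the quad is a detour:
`molray` evaluates the same implicit equations directly for every pixel's
ray. The semantics (and the tests) are identical — the sphere depth buffer
must match the closed-form quadratic to 10⁻⁶ Å on every pixel.

Conventions, fixed once: right-handed world; camera looks along −z with +y
up; vertical field of view; pixel (0, 0) top-left with pixel-center
sampling; depth is the *eye-space Euclidean distance* (not z/w), because
that is what the analytic test contracts want. Trackball cameras orbit a
target (yaw about world up, pitch about camera right clamped to ±89°,
log-scale zoom); free-fly rotates then translates in its own basis.

The G-buffer stores depth, view-space normal, RGBA albedo and an object id
per pixel. Sticks use finite *open* cylinders (caps come from sphere
primitives, so the union is seamless); bond colors split at the midpoint.
Solvent-accessible sphere sets share a *union group*: a candidate hit
strictly inside any other group sphere is rejected and the ray re-enters
from that point, so only the union boundary is ever shaded. Triangle meshes
(SES, cartoon) are intersected through a median-split AABB BVH (leaf ≤ 8)
with Möller–Trumbore tests; an independent brute-force scan is the test
oracle.

Screen-space stages, each gated by an `enabled` flag whose `FALSE` setting
reproduces the previous stage bit-exactly:

* **Shading** — one directional headlight `L` (default view direction).
  flat: albedo; matte: `albedo · (0.15 + 0.85·max(N·L,0))`; glossy: matte
  plus white Blinn specular `0.4·max(N·H,0)³²`; toon: albedo scaled by
  `max(N·L,0)` quantized into four equal bands {0.25, 0.5, 0.75, 1}. The
  coefficients are normative for the tests, chosen as unremarkable
  viewer-like defaults.
* **SSAO** — per pixel, a cosine-weighted hemisphere kernel (fixed by an
  integer seed, generated once per render from an internal Park–Miller
  stream) is oriented along the normal; a sample is occluded when the depth
  stored at its projected pixel is nearer than the sample's own eye
  distance minus a 0.025 Å bias, within a 1.5 Å range check. The output is
  the unoccluded fraction, multiplied into the shaded color. Because the
  reference technique's exact kernel is unpublished, the *contract* is
  bounds and monotonicity: values in [0, 1], ≥ 0.95 on an open plane,
  strictly lower in a concave corner, and never increased by adding an
  occluder.
* **Fog** — linear: `w = density·clamp((d − near)/(far − near), 0, 1)`,
  miss pixels untouched. (Exponential fog was the other candidate; linear
  is chosen and normative because it is exactly testable at the midpoint.)
* **Outline** — Sobel gradient of inverse depth `1/(1 + d)` (0 at misses)
  plus the largest neighbor normal discontinuity `1 − N·N'`; either above
  the threshold marks the pixel, and the mask dilates to the requested
  thickness. On a sphere against empty background the mask necessarily
  closes around the silhouette (the depth jump to +∞ dominates any
  threshold below the inverse-depth step).
* **Anti-aliasing** — supersampling with a box filter (deterministic and
  filter-free to specify, unlike FXAA-style heuristics). Factor 1 is the
  identity.
* **Compositing** — premultiplied source-over onto an RGBA background
  color or image. Geometry pixels carry alpha 255, misses alpha 0, so a
  fully transparent background yields transparent misses — the
  poster-export path. Snapshots are capped at 7680 × 4320 (8K); renders are
  processed in pixel blocks so the cap fits in a few GB of RAM.

Determinism is a hard contract: same scene, settings and seed give
bit-identical PNG bytes (asserted in the acceptance suite).

## 4. Cartoon ribbons

Per chain, a centripetal Catmull–Rom spline interpolates the CA trace
(centripetal parameterization avoids cusps and self-intersections near
kinks); frames along the spline come from the double-reflection
rotation-minimizing-frame method, which avoids the twisting of naive
Frenet frames. Cross-sections are swept and stitched into a closed mesh
(end caps included): coil = 0.3 Å tube, helix = 1.1 × 0.25 Å ellipse,
sheet = 1.1 × 0.25 Å rectangle flaring to a 1.6 Å arrowhead over the last
residue of each sheet run. The dimensions are this package's normative
choices — published viewers do not document theirs. Adaptive tessellation
is replaced by a fixed `subdivisions_per_residue` (default 8): a headless
renderer has no screen-space error metric to adapt to.

Secondary structure comes from file HELIX/SHEET records when present, else
a P-SEA-like CA-distance rule (d13/d14/d15 windows for helix, d13 ≥ 6.4 and
d14 ≥ 9.0 for sheet, runs < 3 revert to coil, chains with < 5 CA all coil).
The thresholds are validated against closed-form fixtures: an ideal helix
(rise 1.5 Å, twist 100°, radius 2.3 Å) classifies helix; a 3.8 Å extended
chain must not.

## 5. Alignment

Kabsch superposition is the standard SVD solution with reflection
correction (det = +1). CE alignment builds aligned fragment pairs (AFPs) of
length m = 8 wherever the intra-fragment CA–CA distance matrices differ by
at most d0 = 3.0 Å on average, then searches for the path of AFPs —
increasing in both sequences, gaps ≤ 30, cross-consistency against every
path member ≤ d1 = 4.0 Å — that aligns the most residues; ties prefer
smaller RMSD, then the lexicographically first start. The parameters follow
the method's original publication; no Z-score stage and no final path
refinement are included (out of scope), so `aligned_length` + RMSD is the
whole output contract.

Two search decisions are worth recording. Same-diagonal AFPs may overlap
(any step ≥ 1): without overlap, non-overlapping length-8 fragments could
never align 30 of 30 residues, which the self-alignment contract requires.
And the search is an exact depth-first enumeration with optimistic-bound
pruning plus a 2×10⁵-node budget: exactness is what the brute-force oracle
checks on small instances; the budget bounds pathological inputs (highly
self-similar structures), where the result degrades gracefully to the best
path found. Periodic chains (ideal helices) have many optima of equal
length and zero RMSD under a screw symmetry; the lexicographic tie-break
picks one deterministically, which is why oracle fixtures use non-periodic
random-walk chains.

## 6. Synthetic data: what it does and does not establish

The generators emulate the *geometric regimes* of the pipeline: ideal
helices (closed-form coordinates, so spline/SS tests have analytic
expectations), extended chains (negative controls), random sphere clusters
with a minimum separation (surface/render stress), toy PDB/mmCIF/DCD texts
(parser contracts), and random-walk CA chains (unique-optimum alignments).
They are pure functions of their arguments and seed, using an internal RNG
that never touches R's global `.Random.seed`.

They are not proteins: no side chains, no physical torsions, no B-factor
structure, no crystallographic quirks (insertion codes, negative residue
numbers, microheterogeneity beyond altloc A). A green suite therefore
establishes that the *algorithms* meet their analytic and oracle contracts,
not that every deposited PDB file parses — the deposited-entry checks
(criterion 8 of the acceptance suite) exist for that and require the
one-time download cache.

## 7. Known limitations

* Pure-R ray casting is minutes-per-frame at 8K; this is an export tool,
  not an interactive viewer. Meshes in very large frames are the slowest
  path (per-pixel BVH walks in R).
* The discrete SES has no interior-cavity suppression and no
  contact/toroidal/reentrant patch classification; analytic SES is out of
  scope.
* Marching-cubes ambiguous cases use the fixed face rule; rare thin-handle
  artifacts are accepted in exchange for determinism and watertightness.
* CE has no statistical significance stage; on highly repetitive structures
  the node budget may truncate the exact search.
* Nucleic-acid cartoons are not drawn (chains without CA atoms are
  skipped); coarse-grained bead systems render as spheres.
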