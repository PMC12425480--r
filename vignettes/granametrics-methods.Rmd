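---
title: "Methods: quantifying thylakoid membrane architecture with granametrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying thylakoid membrane architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`granametrics` quantifies the membrane architecture of chloroplast
thylakoid networks from cryo-electron tomography data: voxel
segmentations, single-membrane triangle meshes, and particle position
tables. This vignette documents the models and procedures behind each
module, the tunable parameters with their defaults and rationale, the
numerical choices, what the synthetic phantoms do and do not emulate, and
the known limitations.

## Coordinate and unit conventions

All world coordinates are nanometers, everywhere downstream of I/O.
Tomographic data mix angstrom pixel sizes (3.52 Å acquisition pixels,
14.08 Å at bin4), voxel indices, and nanometer measurements; converting
once at the I/O boundary (MRC/STAR readers, `voxels_to_nm()`) prevents
silent unit errors. Volumes are stored as R arrays indexed `[x, y, z]`
(x fastest, matching MRC disk order); the world position of 1-based voxel
`(i, j, k)` is `origin + (i-1, j-1, k-1) * voxel_size` at the voxel
center.

## The synthetic phantom: what it emulates

Real validation data for these analyses are tomograms of whole
chloroplasts; at package-development scale we instead validate against
phantoms with exact ground truth. `make_granum_phantom()` builds a stack
of `n_thylakoids` discs along z. Each thylakoid is a pair of bilayer
membranes enclosing the lumen; adjacent thylakoids are separated by the
stromal gap. The defaults are the measured mean geometry of spinach
thylakoids — membrane 5.1 nm, stromal gap 3.2 nm, lumen 10.8 nm, hence a
21.0 nm thylakoid — at the bin4 analysis voxel of 1.408 nm.

Each bilayer is rendered as two leaflet bumps. The bump is asymmetric by
design: the outer flank is a raised cosine of half-width t/4 whose
half-maximum falls exactly at the nominal membrane boundary (±t/2 from
the midplane), while the inner flank has half-width t/8. The asymmetry is
deliberate: with symmetric bumps whose half-maxima sit at the boundary,
the two flanks sum to an exactly flat top between the leaflet centers
(the cos² flanks are complementary), and no inter-leaflet dip exists at
any resolution. The narrower inner flank produces two resolvable leaflet
peaks with a central dip while keeping the outer half-maximum crossings
exactly t apart — which is what makes the morphometry module's
half-maximum edge correction exactly recoverable on the phantom.

A lamellar tongue of length `lamella_length` extends from the outer
membranes to stand in for non-appressed stromal lamellae. Two
mirror-image tongues are attached (top and bottom), so the phantom is
symmetric under reflection through the stack mid-plane for every
parameter choice — a property the test suite asserts on the rendered
density.

Ground truth consists of one midplane mesh per membrane with per-face
labels: the two outermost membranes and their tongues are non-appressed,
all interior membranes appressed, so the appressed area of an
n-thylakoid granum is exactly 2(n−1) disc areas.

Hard-core particle patterns are sampled by dart throwing with rejection
below `min_separation`, using the 3D chord distance. On the near-planar
phantom membranes chord and geodesic separation coincide, and since the
geodesic can never be shorter than the chord, a chord-rejection pattern
satisfies the geodesic constraint as well. Default densities are the
measured appressed-membrane concentrations (2160 all, 1415 PSII, 446
cytochrome b6f per µm²); the 13 nm default exclusion distance is the
scale of the PSII core dimer. Edge-clipped particles (within the
protrusion radius of an open boundary) are kept and flagged, matching the
convention that reported totals include clipped particles; they are
excluded as nearest-neighbor *sources* to avoid censored-distance bias.

The phantom deliberately omits the missing wedge, CTF, tilt-series
geometry, plastoglobules, and envelope membranes. Passing tests on
phantoms therefore demonstrate correctness of the geometry and
statistics, not robustness to reconstruction artifacts of real
tomograms.

## Mesh geometry

Voxel masks are converted to surfaces with a marching-tetrahedra variant
of marching cubes: each grid cube is split into six tetrahedra sharing
the main diagonal (so neighboring cubes agree on face diagonals and the
surface is watertight), vertices are interpolated onto the 0.5 iso-level,
and triangles are oriented out of the mask. Laplacian smoothing (default
30 iterations, relaxation 0.6, open boundaries pinned) relaxes the
voxel-scale zigzag; these defaults were calibrated so a 30-voxel digital
sphere recovers its analytic area within 3%. The area change from
smoothing is reported in the log.

Per-face curvature is the maximum absolute principal curvature from a
quadric fit over the 2-ring vertex neighborhood, corrected for the local
first fundamental form. The 2-ring is large enough to be stable at
phantom mesh densities and small enough to localize the highly curved
thylakoid tips.

Geodesic distances use two backends. The `graph` backend is Dijkstra on
the vertex-edge graph — fast, and always an upper bound on the true
polyhedral geodesic. The `exact` backend refines it: a corridor of
near-shortest vertices (all v with d(s,v) + d(v,t) within 5% plus two
edge lengths of the graph distance — a two-sided criterion that survives
the strong anisotropy of grid meshes) is densified with Steiner points on
its edges (4 per edge), Dijkstra is re-run so paths can cross face
interiors, and the crossing points are then relaxed along their
supporting edges by coordinate descent (golden-section per node, C++).
Interior nodes that sit on mesh vertices are released by replacing them
with movable crossings on the cheaper fan arc around the vertex, and
nodes whose neighbors share a face are dropped (the in-face segment is
never longer); the sleeve conversion and relaxation alternate until the
length stops improving. When the corridor is exactly coplanar and the
straight segment lies inside it, the chord is returned directly — on
planar meshes the result is exact to machine precision; on curved meshes
it is a tight upper bound (0.03% above the great-circle length on a
subdivided icosphere). Because every refinement starts from the graph
solution and only shortens it, graph ≥ exact holds by construction.
Endpoints snap to the nearest face; sub-face precision is below the
1.4 nm voxel scale of the data.

## Domain classification

For every face, rays are cast from the centroid along ±normal against
all membranes in the scene; the facing distance is the nearest
intersection in either direction. The face's own 2-ring is excluded from
intersection rather than its whole connected component, so a membrane
folding back onto itself is still detected. Faces with no intersection
report infinity.

Thresholding at 12 nm center-to-center separates appressed faces
(stromal-side spacing 3.2 + 5.1 ≈ 8.3 nm) from faces whose nearest
neighbor is their own partner membrane across the lumen
(10.8 + 5.1 ≈ 15.9 nm). No canonical threshold value exists for this
step; 12 nm is the midpoint of the two spacings implied by the measured
geometry, and the choice of center-to-center distances follows from
single-membrane meshes tracing the bilayer midplane. A majority vote over geodesic face neighborhoods
(default radius 30 nm, one iteration, area-weighted, ties keep the
incumbent) removes speckle, and faces on open boundaries or with
curvature above 0.1 nm⁻¹ (radii below 10 nm — thylakoid tips,
segmentation rims) are excluded from area sums. All four parameters are
config-exposed. On phantoms across 2–6 thylakoids the classification
recovers ground truth on >99% of the non-excluded area, and the three
label classes always sum exactly to the total mesh area.

## Spacing morphometrics

Membranes are flattened by laying a 2 nm grid over the best-fit plane,
snapping grid points to the mesh, and sampling the volume by trilinear
interpolation at offsets within ±40 nm along the local normals, grouped
into 50 nm patches. The profile step defaults to a quarter voxel; the
sample spacing and range were chosen to resolve the 3.2 nm stromal gap at
bin4. Per patch, the masked mean over grid points gives a 1D profile;
membranes are bright by convention and an `invert_contrast` flag accepts
conventional dark-density data.

Keypoints are local maxima with prominence above 10% of the profile
dynamic range (found on a 3-sample box-smoothed profile), grouped into
bilayers when closer than 4 nm — between the intra-bilayer peak spacing
(t/2 ≈ 2.6 nm) and the closest inter-bilayer leaflet distance across the
stromal gap (gap + t/2 ≈ 5.8 nm). Peaks within one merge distance of the
profile ends are discarded: a bilayer truncated by the sampling window
would otherwise fake a spuriously thin membrane. Profiles with no
acceptable peak are flagged and excluded — the automated counterpart of
manually discarding outlier plots; a per-patch table of QC flags supports
human review.

The half-maximum edge correction resolves a genuine ambiguity in how the
membrane "edge" is defined ("halfway between the leaflet maximum and the
membrane center" can be read as a literal midpoint or as the half-maximum
crossing). The half-maximum reading on the *outer* leaflet flank is the
default: the boundary on each side is the crossing of half the amplitude
from the outer leaflet peak down to the per-side local baseline (the
minimum between this bilayer and its neighbor), located by linear
interpolation and applied symmetrically. Crossings are measured on the
raw masked-mean profile, not the smoothed one, because box smoothing
biases crossings inward on concave flanks; peak amplitudes are refined by
a parabola through samples one voxel apart (the profile is
piecewise-linear between voxel-scale knots, so closer samples carry no
curvature information and the sampled peak underestimates the true one).

Per patch: membrane thickness is the corrected bilayer width;
boundary-to-boundary gaps between consecutive bilayers are classified
stromal below 7 nm (midway between the 3.2 nm gap and the 10.8 nm lumen)
and luminal above; thylakoid thickness spans outer boundary to outer
boundary across each luminal gap, measured from the same detected edges
but not forced to equal 2·membrane + lumen. Aggregates are mean ± SEM
over patches; absent patterns (an isolated membrane has no gaps) report
NA, never zero.

On the default phantom all four quantities recover the generator truth
within a quarter voxel. Across a grid of geometries (membrane 4–6 nm,
gap 3.2–4 nm, lumen 8–14 nm at 1.408 nm voxels) membrane, gap, and lumen
recover within half a voxel (±0.7 nm). Two limits are documented rather
than hidden: (i) stromal gaps below two voxels (2.5 nm at bin4) push the
inner leaflet maxima out of the band-limited signal entirely, and the
extrema-based pattern cannot be recovered at that sampling — such
geometries need finer voxels; (ii) the thylakoid span compounds three
sub-voxel edge biases and can reach one voxel of error at low-lumen
corners of the grid, while remaining within ±0.7 nm at the measured
spinach geometry.

## Point-pattern statistics

Nearest-neighbor distances are geodesic, center-to-center, within one
membrane, per source/target class pair. Candidates are pre-ranked by
chord distance (a lower bound on the geodesic), and geodesics are
evaluated only while a candidate's chord could still beat the best
geodesic found; on perfectly planar meshes the chord fast path is exact.
Both pooled and per-membrane summaries can be formed; pooled is the
default reported by the pipeline.

Distances to the appressed-region edge are Euclidean (3D chord) to the
nearest point of the boundary polyline, following the stated convention;
the boundary defaults to the appressed/other label boundary from the
domains module when no manual annotation is supplied. Bins are half-open
`[k·w, (k+1)·w)` with w = 10 nm; triangles are assigned by centroid
distance. Per-bin concentration is count over summed triangle area, and
bin counts and areas sum exactly to the analyzed totals.

## Footprint occupancy

Footprints are closed 2D outlines in a local frame centered on the
particle with +x as the orientation reference. The built-in C2 (20.5 ×
11 nm ellipse), C2S2 (24 × 13 nm), C2S2M2 (30.5 × 13.5 nm rounded
rectangle), S2-trimer pair, and cytochrome b6f (9 × 6.2 nm) outlines are
documented geometric approximations with realistic overall dimensions —
they are deliberately not presented as measured outlines, and every
dimension is configurable. When an atomic structure aligned with the
membrane plane is supplied, the authoritative outline is derived from it:
atoms within a ±2.5 nm slab are projected, blurred to 14 Å, contoured at
half maximum, and the largest closed contour is taken (the extraction
threshold is config-exposed since no canonical value exists).

Placement, clash, coverage, and overlap use tangent-plane geometry in the
membrane's best-fit plane — valid because appressed grana membranes are
near-planar at footprint scale; curvature-induced distortion grows with
deviation from planarity and a warning is raised for stacks inclined
beyond 30°. In-plane clash is exact: footprint polygons are triangulated
by ear clipping and pairwise intersections computed with
Sutherland–Hodgman clipping; the clash fraction is summed pairwise
intersection area over total footprint area. Union-based quantities
(coverage, cumulative coverage, pair overlap) use a raster engine whose
grid is anchored to the particle pattern's own principal axis and
centroid: a rigid rotation of mesh and particles together rotates the
grid with them, so every statistic is invariant to floating-point
precision. The default 0.5 nm pixel keeps discretization error well
below 1% at footprint scale.

Stacks are projected along a single axis — the area-weighted average
normal of the starting membrane — rather than per-particle normals, as
the per-membrane positions are translated along this axis onto the
starting mesh. The analysis is restricted to the raster intersection of
all projected membrane outlines, which removes the non-overlapping
margin of inclined stacks. Pair overlap normalizes by the first set's
area by default ("percent of their surface area overlapping"); a union
normalization is available. Membranograms sample the volume at a signed
offset along each face normal (2 nm by default, the offset at which
oxygen-evolving complexes read out clearly) and are binarized by a
two-class histogram split (1D k-means midpoint), config-exposed because
no canonical threshold exists.

## Pipeline and reproducibility

`run_pipeline()` executes synthetic generation (optional), meshing,
domains, morphometry, particle statistics, and occupancy from one YAML
configuration; any stage failure aborts with the stage name. Every unset
parameter is filled with the module default and recorded in
`manifest.toml`, which also records package and R versions but no
timestamps — identical configuration and seed reproduce every CSV
bit-for-bit, which the test suite asserts. The run seed fans out to fixed
per-stage offsets (noise field, per-membrane particle seeds) so stages
are independently reproducible.

Problem sizes in the bundled demo and the test suite (60 nm phantom
discs, 1 µm² point patterns, 600 nm occupancy membranes, icospheres of a
few thousand faces) were chosen so the complete validation runs on a
single CPU in minutes while keeping every statistical tolerance
meaningful; all are parameters, not limits.

## Known limitations

- The exact geodesic backend is a refinement of the graph solution; in
  adversarial mesh geometry it can return a slightly longer locally
  shortest path (it is always an upper bound and never below the chord).
- Tangent-plane occupancy geometry degrades on strongly curved
  membranes; the package targets appressed grana discs, which are
  near-planar.
- Spacing morphometrics require characteristic separations of at least
  about two voxels; sub-two-voxel gaps are flagged, not silently
  mis-measured.
- The phantom validates geometry and statistics, not robustness to
  missing-wedge or CTF artifacts; on real tomograms the upstream
  denoising and segmentation quality dominate.
- Non-appressed membranes are treated as one class; no sub-classification
  into margins or end membranes is attempted.
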