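# granametrics

Quantitative membrane-architecture analysis for thylakoid cryo-electron
tomography.

In vascular plant chloroplasts, the thylakoid network is divided into
stacks of tightly apposed discs (grana) and non-stacked stromal lamellae.
Cryo-ET of intact chloroplasts resolves this architecture at the
single-membrane level: binary segmentations of the membrane network,
triangle meshes of single membranes, and tables of photosynthetic-complex
positions (photosystem II, cytochrome b6f) on those membranes.
`granametrics` turns these inputs into the standard quantitative readouts
of grana organization:

- **Domain classification** — every mesh triangle is labeled *appressed*
  (facing a stacked neighbor across the narrow stromal gap) or
  *non-appressed* by tracing the distance to the next membrane along the
  triangle normal and thresholding it (default 12 nm center-to-center,
  midway between the stromal-side spacing 3.2 + 5.1 ≈ 8.3 nm and the
  luminal spacing 10.8 + 5.1 ≈ 15.9 nm), followed by a geodesic
  majority vote and curvature-based exclusion of segmentation edges.
  Outputs: per-face labels, domain areas, appressed:non-appressed ratio.
- **Spacing morphometrics** — membranes are flattened by sampling the
  density along local normals; 1D intensity profiles per 50 nm patch give
  leaflet keypoints, and a half-maximum edge correction on the outer
  leaflet flanks yields membrane thickness, stromal gap, lumen width, and
  thylakoid thickness with sub-voxel precision.
- **Point-pattern statistics** — exact-surface geodesic nearest-neighbor
  distances between particle classes, Euclidean distance-to-edge binning
  (10 nm bins), and per-bin concentrations.
- **Footprint occupancy** — in-plane outlines of the PSII core dimer (C2)
  and its supercomplexes (C2S2, C2S2M2) are placed at the measured
  positions/orientations to quantify membrane coverage, in-plane steric
  clash (exact polygon clipping), cumulative coverage across the granum,
  and the overlap of footprints or membranogram densities across stromal
  and luminal gaps.
- **Synthetic phantoms** — a generator for multilamellar granum stacks
  with known ground truth (bilayer density profiles at the measured
  geometry: membrane 5.1 nm, stromal gap 3.2 nm, lumen 10.8 nm) and
  hard-core surface point processes at the measured concentrations
  (2160/1415/446 particles per µm² for all/PSII/cytb6f), used to validate
  every stage.

I/O covers MRC2014 volumes, RELION-dialect STAR particle tables, and
Wavefront OBJ meshes; all world coordinates are nanometers internally.

## Worked example

```r
library(granametrics)

# a three-thylakoid granum phantom at the measured spinach geometry
ph <- make_granum_phantom(geometry_params())

# classify appressed vs non-appressed membrane domains
cd <- classify_domains(ph$truth$meshes)
cd$areas
#> <domain_areas> appressed 0.0384 um^2 | non-appressed 0.02597 um^2 | excluded 0.005136 um^2
#>   appressed:non-appressed ratio = 1.479

# recover the spacing morphometrics from the rendered density
measure_membrane_morphometry(ph$density, ph$truth$meshes[[3]])
#> <spacing_measurement> (nm)
#>   membrane_thickness     5.23 +/- 0.068  (n=9)
#>   stromal_gap            3.29 +/- 0.040  (n=9)
#>   lumen_width           10.70 +/- 0.011  (n=9)
#>   thylakoid_thickness   21.14 +/- 0.033  (n=9)

# a hard-core PSII pattern at 1415 particles/um^2 and its NN statistics
mesh <- flat_square_mesh(1000, 1000, spacing = 10)
ps <- sample_particles_hardcore(mesh, particle_model("PSII",
                                                     min_separation = 13))
nn_distances(ps, mesh, include_clipped_sources = TRUE)
#> <nn_result> n=1415, mean 18.05 +/- 4.21 nm (SD), SEM 0.112
```

The domain ratio recovers the phantom's ground-truth value (1.479 vs
1.4795 on the ground-truth meshes), the morphometrics recover the
generator geometry
(5.1/3.2/10.8/21.0 nm) within a quarter voxel, and the nearest-neighbor
mean reflects the hard-core null model at the measured concentration (for
a 13 nm exclusion distance; observed patterns in real grana are more
dispersed).

The full pipeline runs from one configuration file:

```r
run_pipeline(run_config(system.file("extdata", "demo_config.yaml",
                                    package = "granametrics")))
```

which writes `labels.csv`, `areas.csv`, `spacings.csv`, `nn.csv`,
`bins.csv`, `coverage.csv`, `overlap.csv`, `cumulative_coverage.csv`, QC
plots, and a deterministic `manifest.toml`. A thin command-line wrapper is
installed at `inst/cli/granametrics.R`
(`Rscript granametrics.R run --config run.yaml`).

## Scope

The package consumes segmentations, meshes, and particle positions; it
does not reconstruct tomograms, denoise, or detect particles (those stages
belong to dedicated upstream tools), and it performs no biological
interpretation.
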