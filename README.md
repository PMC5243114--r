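# oticmap

Lineage, spatial and level-set analytics for 3D+time imaging of the
developing inner ear.

During zebrafish otic-vesicle development, neuronal progenitors
(neuroblasts) exit the ventral epithelium basally — delamination — and
assemble into the statoacoustic ganglion (SAG), while hair cells
differentiate in two sensory patches (anterior and posterior maculae) and
become postmitotic. Modern light-sheet recordings track every cell over many
hours; turning those tracks into biology requires a stack of computational
analyses. `oticmap` implements that stack as a tested R package:

* **Synthetic otic vesicle** (`simulate_epithelium`): a two-shelled
  ellipsoidal epithelium with domain-dependent division rates, an
  anterolateral-to-posteromedial delamination front, lateral-accretion
  ganglion settlement and hair-cell differentiation — with full ground
  truth, so every downstream stage is testable without any imaging data.
* **Track I/O and pre-processing** (`read_tracks`, `register_fixpoint`,
  `map_dynamic_range`): a documented CSV track dialect, fixpoint rigid
  registration, 16-to-8-bit dynamic-range mapping; TIFF and legacy-VTK
  image stacks.
* **Lineage analytics** (`build_forest`, `backtrack`, `flat_layout`):
  validated lineage forests, ancestor backtracking, flat tree layouts.
* **Fate analytics** (`detect_delamination`, `classify_division_behavior`,
  `sister_delay`, `positional_correspondence`, `detect_differentiation`,
  `growth_curve`, `progenitor_map`): delamination/differentiation event
  detection with hysteresis, timing-interval colour classes, division
  behaviour before/after exit, sister delays, Spearman-rank order
  preservation with permutation tests, delaminated fractions, macula growth
  curves and progenitor maps.
* **Spatial statistics** (`local_density`, `nn_distance`): local cell
  density within 20 um (count / sphere volume) and within-selection
  nearest-neighbour distances, on a grid spatial index with an all-pairs
  oracle path.
* **GSUBSURF segmentation** (`edge_detector`, `evolve_levelset`,
  `segment_cell`): the generalized subjective-surface level-set PDE
  `du/dt = wa grad(g).grad(u) + wc g |grad u| div(grad u/|grad u|)`,
  solved by a semi-implicit finite-volume scheme with seed-based
  initialization, steady-state stopping, and marching-tetrahedra cell
  extraction with dual (voxel + mesh) volume estimates.
* **Surface reconstruction** (`distance_field`, `evolve_mesh`,
  `vesicle_volumes`): Lagrangian evolution of a triangulated surface,
  `dF/dt = wa (-grad d . N) N + wc d (Laplace-Beltrami F) + vT`, onto
  point clouds marked on the vesicle walls, with tangential mesh
  redistribution and divergence-theorem volumes (outer, inner, shell).
* **Pipeline** (`run_pipeline`): one YAML configuration drives
  simulate → register → analyse → segment → reconstruct into a
  deterministic report; `inst/scripts/oticmap` is a thin command-line
  front end.

## A worked example

```r
library(oticmap)

geom <- vesicle_geometry(outer_semiaxes = c(50, 40, 40), shell_thickness = 12)
sim  <- simulate_epithelium(geom, sim_params(n0 = 250, seed = 42, noise_xyz = 0))
forest <- build_forest(sim$tracks)
forest
#> lineage_forest: 810 tracks, 250 founders, 280 divisions, dt = 0.08333 h

events <- detect_delamination(forest, geom)
table(events$interval_class)
#> orange    red  white yellow
#>      9      4      4      3

cb <- classify_division_behavior(forest, events)
cb$counts
#> before  after   none
#>      3      3      6
```

Twenty delaminations: four in 18-20 hpf (white), three in 20-22 (yellow),
nine in 22-24 (orange), four after 24 hpf (red) — the colour code of the
flat lineage tree. Of the twelve delaminating lineages, three divided in the
epithelium before exit, three divided after reaching the ganglion, six did
not divide. Because this run is noiseless, the same numbers are recoverable
exactly from the generator's ground truth (`sim$truth`), which is how the
test suite validates each detector.

Rank-order preservation into the ganglion:

```r
p100 <- sim_params(n0 = 100, seed = 9, noise_xyz = 0, delam_prob = 1,
                   delam_domain = "all", division_rate_nonsensory = 0,
                   division_rate_sensory = 0, diff_onset_rate = 0)
s100 <- simulate_epithelium(geom, p100)
f100 <- build_forest(s100$tracks)
ev  <- detect_delamination(f100, geom)
sag <- do.call(rbind, lapply(ev$cell_id, function(id) {
  d <- f100$tracks[[as.character(id)]]
  d[nrow(d), c("cell_id", "x_um", "y_um", "z_um")]
}))
positional_correspondence(ev, sag, "AP", seed = 1)
#> axis AP: Spearman rho = 0.999 (n = 100, permutation p = 0.0010)
positional_correspondence(ev, sag, "ML", seed = 1)
#> axis ML: Spearman rho = -0.027 (n = 100, permutation p = 0.7930)
```

Anteroposterior order is maintained from epithelium to ganglion;
mediolateral order is not — the ML position in the ganglion is set by
arrival order (lateral accretion) instead.

Vesicle volume from two 300-point wall clouds:

```r
outer <- sample_surface_points(geom, "outer", 300, noise = 0.5, seed = 1)
inner <- sample_surface_points(geom, "inner", 300, noise = 0.5, seed = 2)
vv <- vesicle_volumes(inner, outer)
str(vv[c("outer_enclosed", "inner_enclosed", "shell")])
```

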