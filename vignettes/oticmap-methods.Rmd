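---
title: "Models and numerical methods in oticmap"
author: "oticmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in oticmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

oticmap re-implements, as a tested and reusable pipeline, the computational
analyses used to reconstruct inner-ear neurosensory lineages from 3D+time
light-sheet recordings of the zebrafish otic vesicle: lineage-forest
analytics (delamination, division behaviour, hair-cell differentiation,
progenitor maps), spatial statistics (fixed-radius local density,
nearest-neighbour distances), a generalized subjective-surface level-set
solver for single-cell segmentation, and a Lagrangian triangulated-surface
method that reconstructs the vesicle walls from marked point clouds and
measures their volumes. Because the original multi-gigabyte recordings are
not needed to validate the machinery, the package ships a synthetic
otic-vesicle generator whose ground truth drives every downstream test.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do and do not
demonstrate about real data.

## The synthetic otic vesicle

### Geometry

The vesicle is modelled as the shell between two concentric, axis-aligned
ellipsoids (`vesicle_geometry()`): the basal (outer) surface and the apical
(inner) surface bounding the lumen. Axes follow the anatomical convention
x = anteroposterior (anterior low), y = mediolateral (medial low),
z = dorsoventral (ventral low); all lengths are in micrometres and times in
hours post-fertilization (hpf). The default outer semiaxes (50, 40, 40) um
with a 12 um epithelial thickness give a vesicle of realistic mid-segmentation
size. A point classifier (`classify_points()`) labels positions lumen /
epithelium / outside from the two implicit functions; it is the single
geometric primitive used by the generator, the delamination detector and the
renderer, so the three can never disagree about what "epithelial" means.

### Cell dynamics

`simulate_epithelium()` is an event-schedule simulation on the acquisition
grid (default 5-min frames over 18-30 hpf, the neurogenic phase):

* **Domains.** Founders placed uniformly in the shell are labelled by
  position: ventral-lateral cells are neurogenic (delamination-competent),
  ventral-medial cells sensory (prospective maculae), the dorsolateral rest
  non-sensory. The fractions are geometric consequences of the cuts, not
  separate dials.
* **Delamination.** Each eligible cell independently delaminates with
  probability `delam_prob` (default 0.25, echoing the observed scale of
  epithelial cell loss). The eligible region's posterior edge advances at
  `delam_front_speed` (fraction of AP length per hour, default 0.125 so the
  domain is fully established within about six hours); a cell's exit time is
  drawn a short exponential lag (mean about 1.4 h) after the front passes
  it, reproducing the "massive" exit that follows domain establishment. The
  Bernoulli draw happens before any time is assigned, so the event count is
  exactly binomial — this is what the parameter-recovery tests exploit.
  With the default spatially restricted eligibility the fraction of *all*
  epithelial cells lost in a four-hour window is correspondingly smaller
  than `delam_prob`; setting `delam_domain = "all"` makes the two coincide.
* **Ganglion settlement.** Delaminated cells jump beneath the ventral floor.
  Their anteroposterior order is preserved (positions compressed toward the
  centre with sub-micron jitter), while their mediolateral position is set
  by arrival order — later cells settle more laterally, emulating lateral
  accretion onto the existing ganglion. Because exit times depend on AP
  position and chance but not on the epithelial ML coordinate, ML order is
  scrambled. This provides a true signal for the rank-correspondence tests.
* **Divisions.** Each track draws its next division from an exponential
  clock (per-domain rates; neurogenic cells use the non-sensory rate, the
  sensory rate is lower because committed hair-cell progenitors divide
  less). A division ends the mother track at the division frame and starts
  two daughters one frame later at +/-2 um offsets. A delamination fate is
  inherited by *both* daughters of an epithelial division; the sisters exit
  with an exponential delay between them (mean 1 h, so roughly one pair in
  eight exceeds the two-hour flag).
* **Differentiation.** Two macula anchors sit on the ventromedial floor.
  Hair-cell onsets arrive as a Poisson stream per patch (tether cell first);
  onsets are assigned to sensory cells by distance to the anchor, and a
  differentiated cell's division clock is cancelled from its onset —
  differentiated hair cells are postmitotic by construction, which the
  `postmitotic_check()` invariant verifies downstream.
* **Noise.** Positions perform a per-frame Gaussian random walk
  (`noise_xyz`, default 0.15 um) about their base trajectory; epithelial
  positions are projected back into the shell frame-by-frame. With
  `noise_xyz = 0` trajectories are exactly reproducible, which is the regime
  in which the detectors are required to agree with the ground truth
  *exactly* (precision = recall = 1).

What the generator does **not** model: tissue mechanics and cell-cell
exclusion, vesicle growth and morphogenetic deformation over time, apical
constriction during exit (cells jump rather than translocate), imaging
artefacts beyond Gaussian blur, and tracking errors. Tests passing on this
generator therefore validate the *analytics* (event detection, statistics,
solvers) under known truth; they do not validate robustness to tracking
noise beyond the jitter model.

## Track I/O, registration, dynamic range

Track tables use a documented CSV dialect
(`cell_id,mother_id,t_hpf,x_um,y_um,z_um,labels`; founders have an empty
`mother_id`, labels are semicolon-joined). Reading validates uniqueness of
`(cell_id, t)` and mother-link integrity, listing offenders.

Registration (`register_fixpoint()`) implements the fixpoint strategy of
semi-automated rigid registration: the user clicks one landmark per frame;
every frame is translated so the landmark returns to its first-frame
position. Tracks are shifted by the exact vectors; images by nearest-integer
voxel offsets with replicated edge padding (no interpolation — the
registration is a pure translation, and sub-voxel resampling would alter
intensities). Recovery of a synthetically drifted table is exact provided
the drift is expressed relative to the first frame, which is how any
fixpoint trajectory is anchored.

`map_dynamic_range()` maps per-frame intensity percentiles linearly onto
0-255 with clipping, the standard compensation for changing transgene
expression when converting 16-bit acquisitions to 8-bit working stacks. A
constant frame maps to zero by convention; the mapping is monotone and
invariant to per-frame gain (a bleaching factor drops out).

## Lineage forest and fate analytics

`build_forest()` enforces the forest invariants (at most two daughters, a
daughter's first frame exactly one timestep after the mother's last, per-track
time contiguity, acyclicity) and keeps interrupted tracks with a `censored`
flag rather than dropping them. The binary-branching identity (terminal
tracks = founders + divisions) is asserted on every synthetic forest.

**Delamination detection** declares an event at the first frame a cell
centre leaves the shell through the basal surface and stays outside for at
least `k_hysteresis` frames (default 3, suppressing tracking jitter; the
threshold is exposed in the configuration). Two deliberate choices: (i) runs
are evaluated along whole founder-to-terminal paths so an exit immediately
before a division is credited to the mother and each cell delaminates at
most once; (ii) a track that *ends* while outside counts as an event even if
fewer than `k_hysteresis` frames remain — otherwise exits near the end of
the recording would be silently lost and exact generator agreement would be
impossible. The operational criterion (basal crossing with hysteresis,
rather than apical detachment) is our documented choice; timing differences
against an apical criterion are bounded by the sub-hour transit time of the
cell body.

Delamination times are binned into the conventional display intervals
(18-20, 20-22, 22-24, 24-30 hpf) with half-open `[lo, hi)` boundaries, so
touching bin edges are deterministic.

**Division behaviour** classifies each delaminating lineage by whether its
first division precedes (class `before`) or follows (`after`) its first
delamination, or is absent (`none`); the classes partition the cohort by
construction. **Sister delays** report, per division, the absolute
difference of the daughters' first exit times, flagging delays above two
hours; pairs with a non-exiting sister are reported censored rather than
dropped.

**Positional correspondence** quantifies order preservation between the
epithelial exit coordinate and the ganglion coordinate as a Spearman rank
correlation with a two-sided permutation tail probability (999 label
permutations under a fixed seed). Ranks are the right scale for a claim
about *relative* position, and the permutation null avoids any
distributional assumption at these sample sizes (tens to ~150 cells).

**Differentiation** takes the first marker-positive frame as the onset
(flickering labels use the earliest onset with a warning) and assigns each
event to the anterior or posterior macula by the nearest tether-cell anchor
— the tether cells are the first hair cells and anchor the patch poles; no
quantitative assignment rule exists in the literature, so nearest-anchor is
our documented choice, and anchors can be supplied explicitly when patches
are close. Growth curves are cumulative step functions; progenitor maps
backtrack each event cell to a reference time and also report the overlap
count between two progenitor domains (cells of one set within radius r of
the other).

## Spatial statistics

Local density counts the other cell centres within r = 20 um of each centre
and divides by the volume of that sphere; the focal point is excluded and
neighbours at exactly r are included (closed ball — the boundary convention
is not standardized, so it is fixed and documented here). No edge correction
is applied; for comparisons between subsets the nearest-neighbour distance
within the selection is used instead, precisely to limit boundary effects.
Both estimators run on a uniform-grid (cell-list) spatial index written for
this package — the classical kd-tree route is functionally equivalent for
fixed-radius and NN queries at these sizes — and both retain an all-pairs
brute-force path (`method = "brute"`) used as the oracle in the tests, which
require *exact* agreement of counts.

## GSUBSURF level-set segmentation

The solver integrates

du/dt = w_a grad(g) . grad(u) + w_c g |grad u| div(grad u / |grad u|)

on the voxel grid. `g = 1 / (1 + K |grad(G_sigma * I)|^2)` is a
Perona-Malik-type edge indicator on the image rescaled to [0, 1] (the
functional form is configurable; only "an edge detector depending on the
intensity" is canonical). The initial condition is a union (voxelwise
maximum) of smooth cosine bumps at the seed points — in practice three seed
centres per cell.

**Discretization.** Semi-implicit finite volumes: at each time step the
curvature term is solved implicitly with coefficients frozen at the previous
step (Evans-Spruck regularized gradient `|grad u|_eps`, face-centred
gradients with exact normal and averaged tangential components, 7-point
stencil, zero-flux boundaries), and the resulting diagonally dominant system
is solved by SOR sweeps; the edge-advection term is applied explicitly with
upwind differences. The evolution stops when `max |u^{n+1} - u^n| < tol` or
at `max_iter`. The scheme satisfies a discrete maximum principle
(min u0 <= u <= max u0), which the tests assert at every step, and with
`w_a = 0, g = 1` it reproduces mean-curvature flow: a sphere's radius
follows r(t) = sqrt(r0^2 - 4t) within a few percent on a 64^3 grid.

**Two regimes of eps.** The regularization eps plays a modelling role, not
just a numerical one. With eps small (default 1e-4 in grid units) the
curvature term is genuine level-set mean-curvature motion — the regime for
the closed-form verification. For *segmentation*, `segment_cell()` runs the
solver with eps = 1: there the regularized term behaves as edge-gated graph
diffusion, so the seed bump spreads into a flat plateau that fills the cell
interior and is blocked at the membrane where g is small, while the
advection term sharpens the transition onto the edge. The steady state is a
nearly piecewise-constant u; the cell is the superlevel set at an iso-level
of 0.55 x max(u), the plateau-to-background transition midpoint, calibrated
once on synthetic membrane renders of 14-16 um cells and left fixed.
Segmentation runs on a cropped subvolume around the seeds (padding 2.5 x
seed radius plus two voxels, enough to contain the membrane wall and its
blur), as cells are segmented one at a time.

**Extraction.** `extract_cell()` reports the volume two ways — voxel count
of the thresholded mask, and the divergence-theorem volume of the
iso-surface triangulated by marching tetrahedra (each cube split into six
tetrahedra around its main diagonal, which makes opposite cube faces share
diagonals and the surface watertight; orientation is fixed per triangle so
normals point outward). The two estimates agreeing within a few percent is
itself a consistency check used in the tests.

Known limitations: the upwind advection is mildly grid-anisotropic (boundary
placement varies by roughly half a voxel between axis and diagonal
directions), which bounds the achievable Jaccard on small cells; cells are
segmented independently, with no contact handling between neighbours.

## Lagrangian surface reconstruction and vesicle volumes

The vesicle walls are reconstructed from manually (here: synthetically)
marked point clouds of 100-300 points per wall by evolving a triangulated
surface

dF/dt = w_a (-grad d . N) N + w_c d (Laplace-Beltrami F) + v_T

where d is the unsigned distance to the point cloud, evaluated exactly at
the nodes of a regular grid (default pitch = cloud bounding-box diagonal /
200) and interpolated trilinearly with central-difference gradients. The
initial surface is an icosphere mapped to the cloud's bounding ellipsoid
(inflated so that every point satisfies the implicit-function bound, then
scaled by `margin_factor` 1.3). Per step, the normal attraction is explicit;
the distance-weighted curvature term uses the cotangent Laplace-Beltrami
operator with barycentric dual areas and is solved semi-implicitly (one
sparse solve per coordinate); v_T is the tangential component of a
uniform-weight neighbourhood Laplacian — pure mesh-quality motion that the
tests verify changes enclosed volume by under 1% while preserving triangle
quality. With `w_a = 0` and constant d the scheme reproduces weighted
mean-curvature flow, r(t) = sqrt(r0^2 - 4 w_c d t), within a fraction of a
percent.

Default weights (w_a = 1.5, w_c = 0.05, dt = 0.5, 500 steps, subdivision 3)
were chosen on synthetic sphere clouds: stronger smoothing drags the surface
towards chords and inflates the (already negative) volume bias. The method
has an intrinsic inward bias of a few percent at 300 points per wall: a
vertex between cloud points equilibrates where the distance gradient is
orthogonal to the normal, a sheet that lies slightly inside the true surface
(for a sphere of radius R, at R cos(theta) with theta the angular offset to
the nearest point), and the polyhedral volume of the final mesh adds a
further ~0.5% deficit. On 300-point spheres of radius 40 um the recovered
enclosed volume is reproducibly about 4% low — within the 5% envelope used
in the acceptance checks and commensurate with the sampling density; denser
clouds reduce the bias as 1/n.

Vesicle volumes are reported three ways — outer-enclosed, inner-enclosed and
their difference (the epithelial shell) — because "vesicle volume" is
ambiguous between the enclosed and the tissue volume; consumers pick the
quantity they mean.

## Pipeline and reproducibility

`run_pipeline()` drives simulate -> lineage -> fate analytics -> spatial
statistics -> segmentation -> reconstruction from a single YAML
configuration (reviewable, diffable provenance); every stage derives its
seed from the master seed and records it in the report, failures are
recorded per stage without aborting the rest, and fixed-seed runs are
byte-identical (verified by checksums that exclude only the timestamped
log). The demo configuration uses a 250-cell cohort over 18-30 hpf at 5-min
frames, a 64^3 single-cell segmentation fixture and 300-point wall clouds —
sizes chosen so a complete run takes on the order of a minute while leaving
every stage's statistics well out of the small-sample regime.

## What the acceptance-style checks show

The package's end-to-end checks are property-based: solvers against
closed-form flows (level-set and mesh mean-curvature laws), segmentation
against rendered ground truth (Jaccard and volume), reconstruction against
analytic sphere/shell volumes, indexed spatial queries against brute force
(exact), and generator-parameter recovery (binomial delamination fraction,
exact division-class recovery on noiseless tracks, preserved-AP /
scrambled-ML rank structure with a permutation oracle). They validate the
machinery under known truth at desk scale; they deliberately do not claim to
reproduce the cohort-specific counts of any particular imaged embryo, which
depend on data that only the original recordings contain.
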