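#' Edge detector field for level-set segmentation
#'
#' Perona-Malik-type edge indicator `g = 1 / (1 + K |grad(G_sigma * I)|^2)`
#' on the image rescaled to [0, 1]: `g` equals 1 in flat regions and drops
#' towards 0 on strong intensity edges, where it stalls the evolving
#' surface.
#'
#' @param img a [voxel_image()].
#' @param sigma Gaussian pre-smoothing scale in um (>= 0).
#' @param K contrast constant (>= 0); `K = 0` gives `g == 1` everywhere.
#' @return list of class `edge_field`: `g` (3D array in (0, 1]), `sigma`, `K`,
#'   `voxel_size`.
#' @export
edge_detector <- function(img, sigma = 1, K = 100) {
  stopifnot(inherits(img, "voxel_image"), sigma >= 0, K >= 0)
  d <- dim(img$data)
  I <- img$data / max(img$range[2], max(img$data), 1)
  if (sigma > 0)
    I <- array(cpp_blur3(as.vector(I), d, sigma / img$voxel_size), d)
  gr <- grad3(I, img$voxel_size)
  g2 <- gr$x^2 + gr$y^2 + gr$z^2
  structure(list(g = 1 / (1 + K * g2), sigma = sigma, K = K,
                 voxel_size = img$voxel_size), class = "edge_field")
}

# central-difference gradient with replicated boundaries
grad3 <- function(a, h) {
  d <- dim(a)
  ip <- function(n) pmin(seq_len(n) + 1, n)
  im <- function(n) pmax(seq_len(n) - 1, 1)
  list(x = (a[ip(d[1]), , , drop = FALSE] - a[im(d[1]), , , drop = FALSE]) / (2 * h[1]),
       y = (a[, ip(d[2]), , drop = FALSE] - a[, im(d[2]), , drop = FALSE]) / (2 * h[2]),
       z = (a[, , ip(d[3]), drop = FALSE] - a[, , im(d[3]), drop = FALSE]) / (2 * h[3]))
}

#' Initial level-set field from segmentation seeds
#'
#' Builds `u0` as a union (voxelwise maximum) of smooth radial bumps, each
#' equal to 1 at a seed centre and decaying to 0 at its radius — a
#' reasonable initial approximation of the segmented cell from its
#' (typically three) seed points.
#'
#' @param seeds data frame or matrix with columns `x_um, y_um, z_um` and
#'   optionally `radius_um` (recycled from `radius` when absent).
#' @param dim grid size (voxels).
#' @param voxel_size um per voxel.
#' @param origin position of the first voxel centre (um).
#' @param radius default seed radius (um).
#' @return 3D array `u0` in [0, 1].
#' @export
initialize_levelset <- function(seeds, dim, voxel_size = 1,
                                origin = c(0, 0, 0), radius = 5) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  dim <- as.integer(rep_len(dim, 3))
  sm <- as_points_matrix(seeds)
  radii <- if (is.data.frame(seeds) && "radius_um" %in% names(seeds))
    seeds$radius_um else rep(radius, nrow(sm))
  hi <- origin + (dim - 1) * voxel_size
  inside <- sm[, 1] >= origin[1] & sm[, 1] <= hi[1] &
    sm[, 2] >= origin[2] & sm[, 2] <= hi[2] &
    sm[, 3] >= origin[3] & sm[, 3] <= hi[3]
  if (!all(inside))
    stop("seed(s) outside the grid: ",
         paste(which(!inside), collapse = ", "), call. = FALSE)
  ax <- origin[1] + (seq_len(dim[1]) - 1) * voxel_size[1]
  ay <- origin[2] + (seq_len(dim[2]) - 1) * voxel_size[2]
  az <- origin[3] + (seq_len(dim[3]) - 1) * voxel_size[3]
  u0 <- array(0, dim)
  for (s in seq_len(nrow(sm))) {
    dx2 <- (ax - sm[s, 1])^2
    dy2 <- (ay - sm[s, 2])^2
    dz2 <- (az - sm[s, 3])^2
    dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    # smooth cosine bump: 1 at the centre, 0 from the radius outward
    bump <- ifelse(dist >= radii[s], 0, 0.5 * (1 + cos(pi * dist / radii[s])))
    u0 <- pmax(u0, bump)
  }
  u0
}

#' Parameters of the subjective-surface evolution
#'
#' @param wa advection weight (edge attraction), >= 0.
#' @param wc curvature regularization weight, >= 0.
#' @param dt time step; default `0.5 * h^2` with `h` the smallest voxel
#'   pitch (stability-motivated; resolved at evolve time when `NULL`).
#' @param eps Evans-Spruck gradient regularization (grid units).
#' @param tol steady-state threshold on `max |u^{n+1} - u^n|`.
#' @param max_iter iteration cap.
#' @return `gsubsurf_params` list.
#' @export
gsubsurf_params <- function(wa = 1, wc = 1, dt = NULL, eps = 1e-4,
                            tol = 1e-5, max_iter = 500) {
  stopifnot(wa >= 0, wc >= 0, eps > 0, tol > 0, max_iter >= 1)
  if (!is.null(dt)) stopifnot(dt > 0)
  structure(list(wa = wa, wc = wc, dt = dt, eps = eps, tol = tol,
                 max_iter = max_iter), class = "gsubsurf_params")
}

#' Evolve the level-set field to its segmentation steady state
#'
#' Integrates `du/dt = wa grad(g).grad(u) + wc g |grad u| div(grad u/|grad u|)`
#' with a semi-implicit finite-volume scheme: the curvature motion is solved
#' implicitly each step (regularized gradients, 7-point finite-volume fluxes,
#' SOR iterations, zero-flux boundaries), the edge-advection term is applied
#' explicitly with upwind differences.  The evolution stops once
#' `max |u^{n+1} - u^n| < tol` (no significant change in `u`) or after
#' `max_iter` steps.
#'
#' @param u0 initial 3D array (e.g. [initialize_levelset()]).
#' @param g an `edge_field` from [edge_detector()], or a 3D array on the same
#'   grid (use an array of ones for pure mean-curvature motion).
#' @param params a [gsubsurf_params()].
#' @param voxel_size um per voxel (taken from `g` when it is an edge field).
#' @return list `u` (steady-state array), `iterations`, `converged`, and a
#'   `trace` data frame (`max_change, u_min, u_max` per step) for checking
#'   the discrete maximum principle.
#' @export
evolve_levelset <- function(u0, g, params = gsubsurf_params(),
                            voxel_size = NULL) {
  if (inherits(g, "edge_field")) {
    if (is.null(voxel_size)) voxel_size <- g$voxel_size
    g <- g$g
  }
  if (is.null(voxel_size)) voxel_size <- 1
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(is.array(u0), identical(dim(u0), dim(g)))
  dt <- params$dt
  if (is.null(dt)) dt <- 0.5 * min(voxel_size)^2
  res <- cpp_gsubsurf_evolve(as.vector(u0), as.vector(g), dim(u0),
                             voxel_size, params$wa, params$wc, dt,
                             params$eps, params$tol, params$max_iter)
  list(u = array(res$u, dim(u0)),
       iterations = res$iterations,
       converged = length(res$max_change) > 0 &&
         res$max_change[length(res$max_change)] < params$tol,
       dt = dt,
       trace = data.frame(max_change = res$max_change,
                          u_min = res$u_min, u_max = res$u_max))
}

#' Extract the segmented cell from a steady-state field
#'
#' Thresholds `u` at `iso` for the binary mask, extracts the iso-surface by
#' marching tetrahedra, and reports the volume both ways: voxel count times
#' voxel volume, and the divergence-theorem volume of the triangulated
#' surface.
#'
#' @param u steady-state 3D array.
#' @param iso iso-level, strictly inside `(min u, max u)`.
#' @param voxel_size um per voxel.
#' @param origin position of the first voxel centre (um).
#' @return list `mask` (logical array), `mesh` (list `vertices`, `faces`),
#'   `volume_voxel_um3`, `volume_mesh_um3`.
#' @export
extract_cell <- function(u, iso, voxel_size = 1, origin = c(0, 0, 0)) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (!(iso > min(u) && iso < max(u)))
    stop("empty segmentation: iso level ", iso,
         " is outside (min u, max u) = (", signif(min(u), 6), ", ",
         signif(max(u), 6), ")", call. = FALSE)
  mask <- u >= iso
  mt <- cpp_march_tets(as.vector(u), dim(u), origin, voxel_size, iso)
  mesh <- trimesh(mt$vertices, mt$faces)
  list(mask = mask,
       mesh = mesh,
       volume_voxel_um3 = sum(mask) * prod(voxel_size),
       volume_mesh_um3 = mesh_volume(mesh))
}

#' Segment one cell around its seed points
#'
#' Runs the subjective-surface pipeline on a cropped subvolume around the
#' seeds (padding twice the seed radius), as done when segmenting single
#' delaminating cells: edge field, seed initialization, evolution, cell
#' extraction.
#'
#' @param img a [voxel_image()] (membrane channel).
#' @param seeds seed centres as in [initialize_levelset()].
#' @param radius seed radius in um.
#' @param params a [gsubsurf_params()]; the defaults run the solver in its
#'   surface-completion mode (`eps = 1`, balanced advection and diffusion),
#'   which fills the cell interior with a flat plateau of `u` bounded by the
#'   membrane edge.
#' @param sigma,K edge-detector settings.
#' @param iso extraction level as a fraction of `max(u)` (default 0.55, the
#'   plateau-to-background transition midpoint, calibrated on synthetic
#'   membrane renders).
#' @param origin position of the first voxel centre of `img` (um).
#' @return [extract_cell()] result (mask in full-image coordinates) plus
#'   `evolution` diagnostics and the crop `window`.
#' @export
segment_cell <- function(img, seeds, radius = 5,
                         params = gsubsurf_params(wa = 1, wc = 1, eps = 1,
                                                  dt = 0.5, tol = 1e-6,
                                                  max_iter = 500),
                         sigma = 0.5, K = 300, iso = 0.55,
                         origin = c(0, 0, 0)) {
  stopifnot(inherits(img, "voxel_image"))
  sm <- as_points_matrix(seeds)
  # window must contain the whole cell plus its membrane wall and blur
  pad <- 2.5 * radius + 2 * max(img$voxel_size)
  lo_um <- apply(sm, 2, min) - pad
  hi_um <- apply(sm, 2, max) + pad
  d <- dim(img$data)
  lo <- pmax(floor((lo_um - origin) / img$voxel_size) + 1, 1)
  hi <- pmin(ceiling((hi_um - origin) / img$voxel_size) + 1, d)
  sub <- img$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_img <- voxel_image(sub, img$voxel_size, img$range)
  sub_origin <- origin + (lo - 1) * img$voxel_size
  ef <- edge_detector(sub_img, sigma = sigma, K = K)
  u0 <- initialize_levelset(sm, dim(sub), img$voxel_size,
                            origin = sub_origin, radius = radius)
  ev <- evolve_levelset(u0, ef, params)
  res <- extract_cell(ev$u, iso * max(ev$u), img$voxel_size,
                      origin = sub_origin)
  full_mask <- array(FALSE, d)
  full_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- res$mask
  res$mask <- full_mask
  res$evolution <- ev[c("iterations", "converged", "dt")]
  res$window <- list(lo = lo, hi = hi, origin = sub_origin)
  res
}
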