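#' Render synthetic nuclei and membrane channels
#'
#' Rasterizes a set of cell centres into two microscopy-like channels:
#' the nuclei channel holds Gaussian-blurred balls at the centres; the
#' membrane channel holds bright shells on the cell-boundary mask, where a
#' cell's region is the Voronoi-restricted ball of `cell_radius` around its
#' centre (clipped to the epithelium when a geometry is given) so that
#' touching cells share one membrane wall.  Intensities are additive and
#' clipped to [0, 255].
#'
#' @param cells data frame with `x_um`, `y_um`, `z_um` (cell centres of one
#'   frame) or an n x 3 matrix; may be empty (background-only image).
#' @param geom optional [vesicle_geometry()]; when given, cell regions are
#'   clipped to the epithelial shell.
#' @param voxel_size um per voxel (scalar or length-3).
#' @param psf_sigma Gaussian blur s.d. in um emulating the point-spread
#'   function; 0 disables blurring.
#' @param dim,origin optional grid size (voxels) and position of the first
#'   voxel centre (um); derived from `geom` (or the points) when missing.
#' @param nucleus_radius,cell_radius,membrane_halfwidth radii in um.
#' @return list with `nuclei` and `membranes` ([voxel_image()]s) and `masks`
#'   (integer array of ground-truth cell ids per voxel, 0 = background).
#' @export
render_images <- function(cells, geom = NULL, voxel_size = 1, psf_sigma = 0.5,
                          dim = NULL, origin = NULL,
                          nucleus_radius = 3, cell_radius = 6,
                          membrane_halfwidth = 1) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive", call. = FALSE)
  centers <- if (is.null(cells) || (is.data.frame(cells) && !nrow(cells)) ||
                 (is.matrix(cells) && !nrow(cells))) {
    matrix(numeric(0), 0, 3)
  } else as_points_matrix(cells)

  if (is.null(dim)) {
    if (!is.null(geom)) {
      lo <- geom$center - geom$outer_semiaxes - 4 * voxel_size
      hi <- geom$center + geom$outer_semiaxes + 4 * voxel_size
    } else if (nrow(centers)) {
      lo <- apply(centers, 2, min) - cell_radius - 4 * voxel_size
      hi <- apply(centers, 2, max) + cell_radius + 4 * voxel_size
    } else stop("need geom, cells or an explicit dim", call. = FALSE)
    dim <- pmax(ceiling((hi - lo) / voxel_size) + 1, 2)
    origin <- lo
  }
  dim <- as.integer(rep_len(dim, 3))
  if (is.null(origin)) origin <- c(0, 0, 0)

  nuc <- array(0, dim); mem <- array(0, dim)
  masks <- array(0L, dim)
  if (nrow(centers)) {
    nf <- cpp_nearest_two(centers, origin, voxel_size, dim)
    d1 <- array(nf$d1, dim); d2 <- array(nf$d2, dim)
    idx <- array(nf$idx, dim)
    inside <- d1 <= cell_radius
    if (!is.null(geom)) {
      # clip cell regions to the epithelial shell
      ax <- origin[1] + (seq_len(dim[1]) - 1) * voxel_size[1]
      ay <- origin[2] + (seq_len(dim[2]) - 1) * voxel_size[2]
      az <- origin[3] + (seq_len(dim[3]) - 1) * voxel_size[3]
      gx <- array(rep(ax, times = dim[2] * dim[3]), dim)
      gy <- array(rep(rep(ay, each = dim[1]), times = dim[3]), dim)
      gz <- array(rep(az, each = dim[1] * dim[2]), dim)
      cls <- classify_points(geom, cbind(as.vector(gx), as.vector(gy),
                                         as.vector(gz)))
      inside <- inside & array(cls == "epithelium", dim)
    }
    masks[inside] <- idx[inside]
    # membrane: outer wall of each cell region plus shared Voronoi walls
    wall <- (abs(d1 - cell_radius) <= membrane_halfwidth) |
      (inside & (d2 - d1) <= 2 * membrane_halfwidth)
    if (!is.null(geom)) wall <- wall & (d1 <= cell_radius + membrane_halfwidth)
    mem[wall] <- 255
    # nuclei: additive balls, clipped
    counts <- array(cpp_ball_counts(centers, origin, voxel_size, dim,
                                    nucleus_radius), dim)
    nuc <- pmin(200 * counts, 255)
  }
  if (psf_sigma > 0) {
    sig_vox <- psf_sigma / voxel_size
    nuc <- array(cpp_blur3(as.vector(nuc), dim, sig_vox), dim)
    mem <- array(cpp_blur3(as.vector(mem), dim, sig_vox), dim)
  }
  list(nuclei = voxel_image(pmin(pmax(nuc, 0), 255), voxel_size),
       membranes = voxel_image(pmin(pmax(mem, 0), 255), voxel_size),
       masks = masks)
}
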