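#' Sample points on a vesicle wall
#'
#' Draws `n` points area-uniformly on the chosen ellipsoid surface (inner =
#' apical, outer = basal) by rejection from the unit-sphere parametrization,
#' then adds isotropic Gaussian jitter emulating manual marking error.
#' Manual surface marking typically uses on the order of 100-300 points per
#' wall.
#'
#' @param geom a [vesicle_geometry()].
#' @param which `"outer"` or `"inner"` wall.
#' @param n number of points (>= 4; fewer is degenerate for reconstruction).
#' @param noise isotropic jitter s.d. in um.
#' @param seed optional integer seed for reproducible clouds.
#' @return n x 3 matrix of positions (um) with attribute `surface`.
#' @export
sample_surface_points <- function(geom, which = c("outer", "inner"),
                                  n = 200, noise = 0.5, seed = NULL) {
  stopifnot(inherits(geom, "vesicle_geometry"))
  which <- match.arg(which)
  if (n < 4) stop("n must be at least 4 (degenerate for reconstruction)",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ax <- if (which == "outer") geom$outer_semiaxes else geom$inner_semiaxes
  a <- ax[1]; b <- ax[2]; c <- ax[3]
  wmax <- max(a * b, b * c, a * c)
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    m <- max(2L * (n - nrow(pts)), 32L)
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    # area element of the ellipsoid pulled back to the sphere
    w <- sqrt((b * c * u[, 1])^2 + (a * c * u[, 2])^2 + (a * b * u[, 3])^2)
    keep <- runif(m) < w / wmax
    cand <- sweep(u[keep, , drop = FALSE], 2, ax, "*")
    pts <- rbind(pts, sweep(cand, 2, geom$center, "+"))
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  if (noise > 0) pts <- pts + matrix(rnorm(3 * n, 0, noise), n, 3)
  colnames(pts) <- c("x_um", "y_um", "z_um")
  attr(pts, "surface") <- which
  pts
}

#' Read/write point clouds as whitespace XYZ or ASCII PLY
#'
#' @param points n x 3 numeric matrix.
#' @param path file path; format chosen by extension (`.xyz`/`.txt` vs `.ply`).
#' @return write functions return `path` invisibly; read functions an
#'   n x 3 matrix.
#' @export
write_pointcloud <- function(points, path) {
  points <- as_points_matrix(points)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(points)),
                 "property float x", "property float y", "property float z",
                 "end_header"), con)
    writeLines(apply(points, 1, function(r)
      paste(format(r, trim = TRUE), collapse = " ")), con)
  } else {
    utils::write.table(points, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_pointcloud
#' @export
read_pointcloud <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    i0 <- grep("^end_header", lines)[1]
    vals <- do.call(rbind, lapply(lines[(i0 + 1):(i0 + nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  } else {
    vals <- as.matrix(utils::read.table(path))
  }
  pts <- matrix(as.numeric(vals), ncol = 3,
                dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  if (!all(is.finite(pts))) stop("non-finite coordinates in ", path, call. = FALSE)
  pts
}
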