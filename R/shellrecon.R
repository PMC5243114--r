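#' Triangulated surface container
#'
#' @param vertices n x 3 numeric matrix (um).
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals).
#' @return object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            all(faces >= 1), all(faces <= nrow(vertices)))
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @method print trimesh
#' @export
print.trimesh <- function(x, ...) {
  cat("trimesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Icosphere
#'
#' Subdivided icosahedron projected onto the unit sphere: `10 * 4^n + 2`
#' vertices and `20 * 4^n` faces at subdivision `n`, consistently outward
#' oriented.
#'
#' @param subdiv number of 1:4 subdivisions (>= 0).
#' @return a unit-radius [trimesh()] centred at the origin.
#' @export
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      nv <<- nv + 1L
      edge_mid[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  m <- trimesh(v, f)
  if (mesh_signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Initial bounding ellipsoid mesh for a point cloud
#'
#' An icosphere affinely mapped to the cloud's axis-aligned bounding
#' ellipsoid scaled by `margin_factor`, guaranteeing the cloud starts inside
#' the evolving surface.
#'
#' @param cloud n x 3 point matrix.
#' @param margin_factor scale (>= 1) applied to the half-extents.
#' @param subdiv icosphere subdivision level.
#' @return a [trimesh()] containing every cloud point.
#' @export
init_ellipsoid <- function(cloud, margin_factor = 1.3, subdiv = 3) {
  stopifnot(margin_factor >= 1)
  cloud <- as_points_matrix(cloud)
  lo <- apply(cloud, 2, min); hi <- apply(cloud, 2, max)
  center <- (lo + hi) / 2
  semi0 <- pmax((hi - lo) / 2, 1e-6)
  # inflate until every point satisfies the implicit-function bound; for an
  # ellipsoidal cloud this is a no-op and the half-extents are kept
  smax <- max(rowSums(sweep(sweep(cloud, 2, center), 2, semi0, "/")^2))
  semi <- semi0 * sqrt(max(smax, 1)) * margin_factor
  ico <- icosphere(subdiv)
  v <- sweep(sweep(ico$vertices, 2, semi, "*"), 2, center, "+")
  trimesh(v, ico$faces)
}

#' Unsigned distance field of a point cloud
#'
#' Exact nearest-point distance evaluated on a regular grid enclosing the
#' cloud with a margin; values and gradients off-grid come from trilinear
#' interpolation and central differences.  The distance function is the
#' driving force of the surface evolution.
#'
#' @param cloud n x 3 point matrix.
#' @param pitch grid spacing in um; default bounding-box diagonal / 200.
#' @param margin fractional margin added around the bounding box per side
#'   (default 0.45, enough to contain the initial ellipsoid).
#' @return object of class `distance_field`: `d` (3D array), `origin`,
#'   `spacing`, `dim`, plus precomputed gradient arrays.
#' @export
distance_field <- function(cloud, pitch = NULL, margin = 0.45) {
  cloud <- as_points_matrix(cloud)
  lo <- apply(cloud, 2, min); hi <- apply(cloud, 2, max)
  diam <- sqrt(sum((hi - lo)^2))
  if (is.null(pitch)) pitch <- diam / 200
  pad <- margin * max(hi - lo) + 5 * pitch
  origin <- lo - pad
  extent <- hi + pad - origin
  dims <- pmax(as.integer(ceiling(extent / pitch)) + 1L, 2L)
  d <- array(cpp_distance_field(cloud, origin, rep(pitch, 3), dims), dims)
  gr <- grad3(d, rep(pitch, 3))
  structure(list(d = d, origin = origin, spacing = rep(pitch, 3), dim = dims,
                 gx = gr$x, gy = gr$y, gz = gr$z),
            class = "distance_field")
}

# trilinear sample of one array of a distance_field at points (n x 3)
df_sample <- function(field, arr, pts) {
  rel <- sweep(pts, 2, field$origin)
  rel <- sweep(rel, 2, field$spacing, "/")
  d <- field$dim
  i0 <- pmin(pmax(floor(rel[, 1]), 0), d[1] - 2)
  j0 <- pmin(pmax(floor(rel[, 2]), 0), d[2] - 2)
  k0 <- pmin(pmax(floor(rel[, 3]), 0), d[3] - 2)
  fx <- pmin(pmax(rel[, 1] - i0, 0), 1)
  fy <- pmin(pmax(rel[, 2] - j0, 0), 1)
  fz <- pmin(pmax(rel[, 3] - k0, 0), 1)
  at <- function(di, dj, dk)
    arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - fx) * (1 - fy) * (1 - fz) * at(0, 0, 0) +
    fx * (1 - fy) * (1 - fz) * at(1, 0, 0) +
    (1 - fx) * fy * (1 - fz) * at(0, 1, 0) +
    fx * fy * (1 - fz) * at(1, 1, 0) +
    (1 - fx) * (1 - fy) * fz * at(0, 0, 1) +
    fx * (1 - fy) * fz * at(1, 0, 1) +
    (1 - fx) * fy * fz * at(0, 1, 1) +
    fx * fy * fz * at(1, 1, 1)
}

#' Evaluate a distance field and its gradient at arbitrary points
#'
#' @param field a [distance_field()].
#' @param pts n x 3 matrix (um).
#' @return `df_value`: numeric vector; `df_grad`: n x 3 matrix.
#' @export
df_value <- function(field, pts) df_sample(field, field$d, as_points_matrix(pts))

#' @rdname df_value
#' @export
df_grad <- function(field, pts) {
  pts <- as_points_matrix(pts)
  cbind(df_sample(field, field$gx, pts),
        df_sample(field, field$gy, pts),
        df_sample(field, field$gz, pts))
}

# area-weighted vertex normals (outward for an outward-oriented mesh)
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])   # 2*area * unit normal
  n <- rowsum(rbind(fn, fn, fn), group = c(f[, 1], f[, 2], f[, 3]),
              reorder = TRUE)
  full <- matrix(0, nrow(v), 3)
  full[as.integer(rownames(n)), ] <- n
  len <- sqrt(rowSums(full^2))
  full / pmax(len, 1e-12)
}

# cotangent Laplacian (sparse) and barycentric dual areas
cotan_laplacian <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nvert <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  p1 <- v[i1, , drop = FALSE]; p2 <- v[i2, , drop = FALSE]
  p3 <- v[i3, , drop = FALSE]
  cot_at <- function(a, b, c) {
    # cotangent of the angle at a, spanned by b and c
    u <- b - a; w <- c - a
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    rowSums(u * w) / pmax(sqrt(rowSums(cr^2)), 1e-12)
  }
  c1 <- cot_at(p1, p2, p3)   # angle at vertex 1 faces edge (2,3)
  c2 <- cot_at(p2, p3, p1)
  c3 <- cot_at(p3, p1, p2)
  # each face adds cot(opposite angle) to its edge; both faces of an edge
  # together give (cot a + cot b), the 1/2 lives in the 1/(2A) area factor
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  ww <- c(c1, c1, c2, c2, c3, c3)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nvert, nvert))
  dg <- Matrix::rowSums(W)
  L <- W - Matrix::Diagonal(x = dg)
  areas2 <- sqrt(rowSums((cbind(
    (p2 - p1)[, 2] * (p3 - p1)[, 3] - (p2 - p1)[, 3] * (p3 - p1)[, 2],
    (p2 - p1)[, 3] * (p3 - p1)[, 1] - (p2 - p1)[, 1] * (p3 - p1)[, 3],
    (p2 - p1)[, 1] * (p3 - p1)[, 2] - (p2 - p1)[, 2] * (p3 - p1)[, 1]))^2))
  tri_area <- areas2 / 2
  va <- rowsum(c(tri_area, tri_area, tri_area) / 3,
               group = c(i1, i2, i3), reorder = TRUE)
  vert_area <- numeric(nvert)
  vert_area[as.integer(rownames(va))] <- va
  list(L = L, area = pmax(vert_area, 1e-12))
}

# uniform (graph) Laplacian displacement: mean of neighbours minus vertex
uniform_laplacian_disp <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  nvert <- nrow(v)
  ii <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  jj <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nvert, nvert))
  A@x[] <- 1   # collapse duplicate edges
  deg <- Matrix::rowSums(A)
  as.matrix(A %*% v) / pmax(deg, 1) - v
}

#' Parameters for the Lagrangian mesh evolution
#'
#' @param wa attraction weight (>= 0): strength of the normal motion
#'   `-(grad d . N) N` pulling the surface down the distance function.
#' @param wc smoothing weight (>= 0): strength of the `d * Laplace-Beltrami`
#'   mean-curvature term (vanishes on the cloud where `d = 0`).
#' @param dt time step.
#' @param n_steps maximum number of steps.
#' @param tangential_weight weight of the tangential redistribution field
#'   (mesh-quality motion with no geometric effect).
#' @param tol stop when the maximum vertex displacement per step falls
#'   below `tol` (um).
#' @return `mesh_evolve_params` list.
#' @export
mesh_evolve_params <- function(wa = 1.5, wc = 0.05, dt = 0.5, n_steps = 500,
                               tangential_weight = 0.3, tol = 5e-4) {
  stopifnot(wa >= 0, wc >= 0, dt > 0, n_steps >= 1, tangential_weight >= 0,
            tol >= 0)
  structure(list(wa = wa, wc = wc, dt = dt, n_steps = n_steps,
                 tangential_weight = tangential_weight, tol = tol),
            class = "mesh_evolve_params")
}

#' Evolve a triangulated surface onto a point cloud
#'
#' Integrates `dF/dt = wa (-grad d . N) N + wc d (Laplace-Beltrami F) + vT`:
#' the normal attraction term (explicit) pulls vertices down the distance
#' function, the distance-weighted mean-curvature term (cotangent
#' Laplace-Beltrami with barycentric dual areas, solved semi-implicitly)
#' keeps the surface taut where it is far from the cloud, and the
#' tangential field `vT` (tangential part of the uniform neighbourhood
#' Laplacian) redistributes vertices without moving the geometry.
#'
#' @param mesh initial closed oriented [trimesh()] (see [init_ellipsoid()]).
#' @param field a [distance_field()], or a single number for a spatially
#'   constant driving function (pure weighted mean-curvature flow).
#' @param params a [mesh_evolve_params()].
#' @return list `mesh` (final [trimesh()]), `steps`, `converged`,
#'   `max_disp` (per-step trace).
#' @export
evolve_mesh <- function(mesh, field, params = mesh_evolve_params()) {
  stopifnot(inherits(mesh, "trimesh"))
  const_d <- is.numeric(field) && length(field) == 1
  v <- mesh$vertices
  f <- mesh$faces
  trace <- numeric(0)
  converged <- FALSE
  for (s in seq_len(params$n_steps)) {
    m <- trimesh(v, f)
    nrm <- vertex_normals(m)
    if (const_d) {
      dvals <- rep(field, nrow(v))
      attr_v <- matrix(0, nrow(v), 3)
    } else {
      dvals <- df_value(field, v)
      gd <- df_grad(field, v)
      speed <- -rowSums(gd * nrm)          # -(grad d . N)
      attr_v <- params$wa * speed * nrm
    }
    vT <- if (params$tangential_weight > 0) {
      disp <- uniform_laplacian_disp(m)
      disp - rowSums(disp * nrm) * nrm
    } else matrix(0, nrow(v), 3)
    cl <- cotan_laplacian(m)
    coef <- params$wc * dvals / (2 * cl$area)
    A <- Matrix::Diagonal(nrow(v)) - params$dt * Matrix::Diagonal(x = coef) %*% cl$L
    rhs <- v + params$dt * (attr_v + params$tangential_weight * vT)
    vn <- as.matrix(Matrix::solve(A, rhs))
    disp_max <- max(sqrt(rowSums((vn - v)^2)))
    trace <- c(trace, disp_max)
    v <- vn
    if (disp_max < params$tol) { converged <- TRUE; break }
  }
  out <- trimesh(v, f)
  # degenerate triangles signal a collapsed/self-intersecting evolution
  p1 <- v[f[, 1], ]; e1 <- v[f[, 2], ] - p1; e2 <- v[f[, 3], ] - p1
  a2 <- sqrt(rowSums(cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                           e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                           e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2))
  if (any(!is.finite(a2)) || min(a2) <= 0)
    stop("mesh evolution aborted: degenerate (zero-area) triangle produced",
         call. = FALSE)
  list(mesh = out, steps = length(trace), converged = converged,
       max_disp = trace)
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  sum(p1 * cr) / 6
}

#' Enclosed volume of a closed triangulated surface
#'
#' Signed divergence-theorem volume `V = (1/6) sum p1 . (p2 x p3)`; a
#' negative signed volume means the orientation is inward, in which case the
#' magnitude is returned with a warning.
#'
#' @param mesh a closed, consistently oriented [trimesh()].
#' @return volume in cubic um.
#' @export
mesh_volume <- function(mesh) {
  sv <- mesh_signed_volume(mesh)
  if (sv < 0) {
    warning("mesh is inward-oriented; returning |signed volume|")
    sv <- -sv
  }
  sv
}

#' Reconstruct one vesicle wall from its point cloud
#'
#' Convenience wrapper: distance field, bounding-ellipsoid initial mesh,
#' Lagrangian evolution.
#'
#' @param cloud n x 3 points (um), n >= 4.
#' @param params a [mesh_evolve_params()].
#' @param subdiv,margin_factor initial-mesh settings ([init_ellipsoid()]).
#' @param pitch distance-field grid pitch ([distance_field()]).
#' @return list `mesh`, `volume_um3`, `evolution` diagnostics.
#' @export
reconstruct_surface <- function(cloud, params = mesh_evolve_params(),
                                subdiv = 3, margin_factor = 1.3,
                                pitch = NULL) {
  cloud <- as_points_matrix(cloud)
  if (nrow(cloud) < 4) stop("need at least 4 points", call. = FALSE)
  field <- distance_field(cloud, pitch = pitch)
  mesh0 <- init_ellipsoid(cloud, margin_factor = margin_factor,
                          subdiv = subdiv)
  ev <- evolve_mesh(mesh0, field, params)
  list(mesh = ev$mesh, volume_um3 = mesh_volume(ev$mesh),
       evolution = ev[c("steps", "converged")])
}

#' Vesicle volumes from inner and outer wall clouds
#'
#' Reconstructs both walls and reports the outer-enclosed, inner-enclosed
#' and epithelial shell volume (outer minus inner), all in cubic um.
#'
#' @param inner_cloud,outer_cloud point matrices for the apical (inner) and
#'   basal (outer) walls.
#' @param params a [mesh_evolve_params()].
#' @param ... passed to [reconstruct_surface()].
#' @return list `outer_enclosed, inner_enclosed, shell, meshes`.
#' @export
vesicle_volumes <- function(inner_cloud, outer_cloud,
                            params = mesh_evolve_params(), ...) {
  ri <- reconstruct_surface(inner_cloud, params = params, ...)
  ro <- reconstruct_surface(outer_cloud, params = params, ...)
  if (ri$volume_um3 >= ro$volume_um3)
    stop("inconsistent surfaces: inner enclosed volume (",
         round(ri$volume_um3), ") is not smaller than outer (",
         round(ro$volume_um3), ")", call. = FALSE)
  list(outer_enclosed = ro$volume_um3,
       inner_enclosed = ri$volume_um3,
       shell = ro$volume_um3 - ri$volume_um3,
       meshes = list(inner = ri$mesh, outer = ro$mesh))
}

#' Read/write triangle meshes (ASCII PLY, OBJ or legacy VTK polydata)
#'
#' Format chosen by file extension.
#'
#' @param mesh a [trimesh()].
#' @param path file path (`.ply`, `.obj` or `.vtk`).
#' @return `write_mesh` returns `path` invisibly; `read_mesh` a [trimesh()].
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    writeLines(c(apply(v, 1, function(r)
      paste("v", paste(format(r, trim = TRUE), collapse = " "))),
      apply(f, 1, function(r) paste("f", paste(r, collapse = " ")))), con)
  } else if (grepl("\\.vtk$", path, ignore.case = TRUE)) {
    writeLines(c("# vtk DataFile Version 3.0", "oticmap surface", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(v)),
                 apply(v, 1, function(r)
                   paste(format(r, trim = TRUE), collapse = " ")),
                 sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)),
                 apply(f - 1L, 1, function(r)
                   paste(c(3L, r), collapse = " "))), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header",
                 apply(v, 1, function(r)
                   paste(format(r, trim = TRUE), collapse = " ")),
                 apply(f - 1L, 1, function(r)
                   paste(c(3L, r), collapse = " "))), con)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(vl, function(l)
      as.numeric(strsplit(trimws(sub("^v", "", l)), "\\s+")[[1]][1:3])))
    f <- do.call(rbind, lapply(fl, function(l)
      as.integer(sub("/.*", "", strsplit(trimws(sub("^f", "", l)),
                                         "\\s+")[[1]][1:3]))))
    return(trimesh(v, f))
  }
  if (lines[1] != "ply") stop("unsupported mesh format: ", path, call. = FALSE)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  i0 <- grep("^end_header", lines)[1]
  v <- do.call(rbind, lapply(lines[(i0 + 1):(i0 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  f <- do.call(rbind, lapply(lines[(i0 + nv + 1):(i0 + nv + nf)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]][2:4]) + 1L))
  trimesh(v, f)
}
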