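#' Two-shelled ellipsoidal otic-vesicle geometry
#'
#' The otic vesicle is modelled as the region between two concentric,
#' axis-aligned ellipsoids: the basal (outer) surface and the apical (inner)
#' surface bounding the lumen.  Axes follow the anatomical convention
#' x = anteroposterior (anterior low), y = mediolateral (medial low),
#' z = dorsoventral (ventral low); all lengths in micrometres.
#'
#' @param center numeric length-3, ellipsoid centre (um).
#' @param outer_semiaxes numeric length-3, outer semiaxes along (AP, ML, DV) (um).
#' @param shell_thickness single positive number (um); the inner semiaxes are
#'   `outer_semiaxes - shell_thickness` componentwise and must stay positive.
#' @return An object of class `vesicle_geometry` with fields `center`,
#'   `outer_semiaxes`, `inner_semiaxes`, `shell_thickness`, `axes`.
#' @examples
#' geom <- vesicle_geometry(outer_semiaxes = c(50, 40, 40), shell_thickness = 12)
#' geom$inner_semiaxes  # 38 28 28
#' classify_points(geom, rbind(c(0, 0, 0)))  # "lumen"
#' @export
vesicle_geometry <- function(center = c(0, 0, 0),
                             outer_semiaxes = c(50, 40, 40),
                             shell_thickness = 12) {
  center <- as.numeric(center)
  outer_semiaxes <- as.numeric(outer_semiaxes)
  stopifnot(length(center) == 3, length(outer_semiaxes) == 3,
            length(shell_thickness) == 1)
  if (!all(outer_semiaxes > 0))
    stop("outer semiaxes must all be positive", call. = FALSE)
  if (shell_thickness <= 0)
    stop("shell_thickness must be positive", call. = FALSE)
  if (shell_thickness >= min(outer_semiaxes))
    stop("invalid geometry: shell_thickness (", shell_thickness,
         ") must be smaller than the smallest outer semiaxis (",
         min(outer_semiaxes), ")", call. = FALSE)
  structure(list(
    center = center,
    outer_semiaxes = outer_semiaxes,
    inner_semiaxes = outer_semiaxes - shell_thickness,
    shell_thickness = shell_thickness,
    axes = c(x = "AP", y = "ML", z = "DV")
  ), class = "vesicle_geometry")
}

#' @method print vesicle_geometry
#' @export
print.vesicle_geometry <- function(x, ...) {
  cat("vesicle_geometry (um)\n")
  cat("  center        :", paste(format(x$center), collapse = ", "), "\n")
  cat("  outer semiaxes:", paste(format(x$outer_semiaxes), collapse = ", "),
      "(AP, ML, DV)\n")
  cat("  inner semiaxes:", paste(format(x$inner_semiaxes), collapse = ", "), "\n")
  cat("  shell         :", x$shell_thickness, "\n")
  invisible(x)
}

# implicit function of an axis-aligned ellipsoid: <1 inside, 1 on, >1 outside
ellipsoid_implicit <- function(points, center, semiaxes) {
  points <- as_points_matrix(points)
  q <- sweep(points, 2, center)
  q <- sweep(q, 2, semiaxes, "/")
  rowSums(q * q)
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x_um", "y_um", "z_um")])
  } else {
    points <- rbind(points)  # promote a bare 3-vector
    rownames(points) <- NULL
  }
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}

#' Classify points against the vesicle geometry
#'
#' A point is in the `lumen` if it lies strictly inside the inner (apical)
#' ellipsoid, in the `epithelium` if between inner and outer surfaces
#' (boundaries included), and `outside` beyond the basal surface.
#'
#' @param geom a [vesicle_geometry()].
#' @param points n x 3 matrix (columns x, y, z in um), a single 3-vector, or a
#'   data frame with `x_um`, `y_um`, `z_um` columns.
#' @param tol boundary tolerance on the implicit function (a point within
#'   `tol` of the outer surface still counts as epithelium).
#' @return character vector: "lumen", "epithelium", "outside".
#' @export
classify_points <- function(geom, points, tol = 1e-9) {
  stopifnot(inherits(geom, "vesicle_geometry"))
  fi <- ellipsoid_implicit(points, geom$center, geom$inner_semiaxes)
  fo <- ellipsoid_implicit(points, geom$center, geom$outer_semiaxes)
  ifelse(fi < 1 - tol, "lumen", ifelse(fo <= 1 + tol, "epithelium", "outside"))
}

# uniform random sample inside the epithelial shell (rejection from the
# outer ellipsoid's bounding box)
sample_shell <- function(geom, n) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(4L * (n - nrow(out)), 64L)
    cand <- cbind(runif(m, -1, 1), runif(m, -1, 1), runif(m, -1, 1))
    cand <- sweep(cand, 2, geom$outer_semiaxes, "*")
    cand <- sweep(cand, 2, geom$center, "+")
    keep <- classify_points(geom, cand) == "epithelium"
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# radially project a point into the shell mid-surface band if it drifted out
project_into_shell <- function(geom, points, band = 0.5) {
  points <- as_points_matrix(points)
  cls <- classify_points(geom, points)
  bad <- cls != "epithelium"
  if (any(bad)) {
    mid <- (geom$outer_semiaxes + geom$inner_semiaxes) / 2
    q <- sweep(points[bad, , drop = FALSE], 2, geom$center)
    s <- sqrt(rowSums(sweep(q, 2, mid, "/")^2))
    deg <- s < 1e-12              # point at the centre: pick a direction
    if (any(deg)) {
      q[deg, ] <- rep(c(1, 0, 0), each = sum(deg))
      s[deg] <- 1 / mid[1]
    }
    q <- q / s
    points[bad, ] <- sweep(q, 2, geom$center, "+")
  }
  points
}
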