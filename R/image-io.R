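#' 3D voxel image container
#'
#' A thin wrapper around a 3D numeric array with voxel-size metadata (um per
#' voxel along x, y, z) and the nominal value range of the acquisition
#' (e.g. 0..255 for 8-bit, 0..65535 for 16-bit).
#'
#' @param data 3D numeric array (x, y, z order).
#' @param voxel_size positive length-1 or length-3 numeric, um per voxel.
#' @param range nominal intensity range, length-2.
#' @return object of class `voxel_image`.
#' @export
voxel_image <- function(data, voxel_size = 1, range = c(0, 255)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(dim(data) < 2)) stop("all image dimensions must be >= 2", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size,
                 range = as.numeric(range)),
            class = "voxel_image")
}

#' @method print voxel_image
#' @export
print.voxel_image <- function(x, ...) {
  cat("voxel_image ", paste(dim(x$data), collapse = " x "),
      " | voxel ", paste(format(x$voxel_size), collapse = " x "),
      " um | range [", x$range[1], ", ", x$range[2], "]\n", sep = "")
  invisible(x)
}

#' Read/write a voxel image as multi-page TIFF
#'
#' Pages are z-slices.  Plain TIFF carries no calibrated voxel size, so the
#' reader takes it as an argument (the legacy VTK format stores the spacing
#' natively; see [write_vtk_image()]).
#'
#' @param img a [voxel_image()].
#' @param path file path.
#' @param bits 8 or 16, storage depth.
#' @return `write_tiff` returns `path` invisibly; `read_tiff` a `voxel_image`.
#' @export
write_tiff <- function(img, path, bits = 8) {
  stopifnot(inherits(img, "voxel_image"), bits %in% c(8, 16))
  mx <- max(img$range[2], 1)
  slices <- lapply(seq_len(dim(img$data)[3]), function(k) {
    # tiff::writeTIFF expects [0,1] matrices in row-major (y, x) orientation
    t(pmin(pmax(img$data[, , k] / mx, 0), 1))
  })
  tiff::writeTIFF(slices, path, bits.per.sample = bits,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' @rdname write_tiff
#' @param voxel_size um per voxel of the stored stack (TIFF does not carry it).
#' @param range nominal intensity range the stored values map back onto.
#' @export
read_tiff <- function(path, voxel_size = 1, range = c(0, 255)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    t(pg) * range[2]
  }))
  voxel_image(arr, voxel_size = voxel_size, range = range)
}

#' Read/write a voxel image in legacy VTK structured-points format
#'
#' ASCII legacy VTK, `DATASET STRUCTURED_POINTS`, one scalar field per file
#' (the per-timestep, per-channel convention of light-sheet exports).
#'
#' @param img a [voxel_image()].
#' @param path file path (conventionally `.vtk`).
#' @param name scalar field name.
#' @return `write_vtk_image` returns `path` invisibly; `read_vtk_image` a
#'   `voxel_image`.
#' @export
write_vtk_image <- function(img, path, name = "intensity") {
  stopifnot(inherits(img, "voxel_image"))
  d <- dim(img$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "oticmap structured points",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g %.9g", img$voxel_size[1],
                       img$voxel_size[2], img$voxel_size[3]),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  # VTK expects x fastest, then y, then z: R column-major order already is
  vals <- as.vector(img$data)
  writeLines(vapply(split(vals, ceiling(seq_along(vals) / 9)),
                    function(v) paste(format(v, trim = TRUE), collapse = " "),
                    character(1), USE.NAMES = FALSE), con)
  invisible(path)
}

#' @rdname write_vtk_image
#' @export
read_vtk_image <- function(path) {
  lines <- readLines(path)
  get1 <- function(pat) grep(pat, lines, value = TRUE)[1]
  if (!grepl("STRUCTURED_POINTS", get1("DATASET")))
    stop("not a legacy VTK structured-points file: ", path, call. = FALSE)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "", get1("^DIMENSIONS"))),
                              "\\s+")[[1]])
  sp <- as.numeric(strsplit(trimws(sub("SPACING", "", get1("^SPACING"))),
                            "\\s+")[[1]])
  i_lut <- grep("^LOOKUP_TABLE", lines)[1]
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i_lut + 1):length(lines)]),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims))
    stop("VTK data length mismatch: expected ", prod(dims), ", got ",
         length(vals), call. = FALSE)
  voxel_image(array(vals, dim = dims), voxel_size = sp,
              range = c(0, max(255, max(vals))))
}
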