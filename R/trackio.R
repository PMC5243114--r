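#' Read and write cell-track tables
#'
#' The track dialect is a comma-separated file with header
#' `cell_id,mother_id,t_hpf,x_um,y_um,z_um,labels`: one row per cell per
#' frame, `mother_id` empty for founder cells, `labels` a semicolon-joined
#' set of marker/selection names (empty allowed).  `read_tracks(write_tracks(x))`
#' is the identity on canonical tables.
#'
#' @param path file path.
#' @param validate run [validate_tracks()] after reading (default TRUE).
#' @return `read_tracks` returns the track data frame; `write_tracks` returns
#'   `path` invisibly.
#' @export
read_tracks <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (!length(first) || !nzchar(first)) {
    warning("empty track file: ", path, "; returning empty table")
    return(empty_tracks())
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cell_id = "integer",
                                        mother_id = "integer",
                                        t_hpf = "numeric", x_um = "numeric",
                                        y_um = "numeric", z_um = "numeric",
                                        labels = "character"))
  need <- c("cell_id", "mother_id", "t_hpf", "x_um", "y_um", "z_um", "labels")
  if (!all(need %in% names(tab)))
    stop("track file missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  tab <- tab[, need]
  tab$labels[is.na(tab$labels)] <- ""
  if (!nrow(tab)) {
    warning("track file has a header but no rows: ", path)
    return(empty_tracks())
  }
  if (validate) validate_tracks(tab)
  tab
}

empty_tracks <- function() {
  data.frame(cell_id = integer(0), mother_id = integer(0), t_hpf = numeric(0),
             x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             labels = character(0))
}

#' @rdname read_tracks
#' @param tracks a track data frame.
#' @export
write_tracks <- function(tracks, path) {
  validate_tracks(tracks)
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a track table
#'
#' Checks the schema, uniqueness of `(cell_id, t_hpf)` pairs, and that every
#' non-missing `mother_id` refers to a known cell.
#'
#' @param tracks track data frame.
#' @return the table, invisibly; errors describe all offenders.
#' @export
validate_tracks <- function(tracks) {
  need <- c("cell_id", "mother_id", "t_hpf", "x_um", "y_um", "z_um", "labels")
  if (!all(need %in% names(tracks)))
    stop("track table missing columns: ",
         paste(setdiff(need, names(tracks)), collapse = ", "), call. = FALSE)
  key <- paste(tracks$cell_id, signif(tracks$t_hpf, 10))
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (cell_id, t) rows: ", paste(head(dup, 5), collapse = "; "),
         if (length(dup) > 5) " ...", call. = FALSE)
  }
  mothers <- unique(tracks$mother_id[!is.na(tracks$mother_id)])
  unknown <- setdiff(mothers, unique(tracks$cell_id))
  if (length(unknown))
    stop("dangling mother links: mother_id ",
         paste(sort(unknown), collapse = ", "), " not present as cell_id",
         call. = FALSE)
  invisible(tracks)
}

#' Fixpoint rigid registration
#'
#' Compensates embryo drift by translating every frame so a user-chosen
#' landmark (the fixpoint, clicked once per frame) stays at its first-frame
#' position.  Track coordinates are shifted by the exact per-frame vectors;
#' images are shifted by the nearest integer voxel offset with replicated
#' edge padding (rigid translation only, no interpolation).
#'
#' @param tracks track data frame.
#' @param fixpoints data frame `t_hpf, x_um, y_um, z_um`: the landmark
#'   trajectory, one row per frame of the sequence.
#' @return the registered track table.
#' @export
register_fixpoint <- function(tracks, fixpoints) {
  stopifnot(all(c("t_hpf", "x_um", "y_um", "z_um") %in% names(fixpoints)))
  ts <- sort(unique(tracks$t_hpf))
  ft <- fixpoints$t_hpf
  miss <- ts[!vapply(ts, function(t) any(abs(ft - t) < 1e-9), logical(1))]
  if (length(miss))
    stop("fixpoint trajectory missing frames: t = ",
         paste(head(signif(miss, 6), 5), collapse = ", "),
         if (length(miss) > 5) " ...", call. = FALSE)
  fixpoints <- fixpoints[order(fixpoints$t_hpf), ]
  ref <- as.numeric(fixpoints[1, c("x_um", "y_um", "z_um")])
  idx <- vapply(tracks$t_hpf, function(t) which.min(abs(fixpoints$t_hpf - t)),
                integer(1))
  shift <- as.matrix(fixpoints[idx, c("x_um", "y_um", "z_um")])
  shift <- sweep(shift, 2, ref)
  tracks$x_um <- tracks$x_um - shift[, 1]
  tracks$y_um <- tracks$y_um - shift[, 2]
  tracks$z_um <- tracks$z_um - shift[, 3]
  tracks
}

#' @rdname register_fixpoint
#' @param images list of [voxel_image()]s, one per frame (same order as the
#'   sorted fixpoint times).
#' @return `register_fixpoint_images` returns the list of shifted images.
#' @export
register_fixpoint_images <- function(images, fixpoints) {
  stopifnot(is.list(images), nrow(fixpoints) == length(images))
  fixpoints <- fixpoints[order(fixpoints$t_hpf), ]
  ref <- as.numeric(fixpoints[1, c("x_um", "y_um", "z_um")])
  lapply(seq_along(images), function(i) {
    img <- images[[i]]
    stopifnot(inherits(img, "voxel_image"))
    dvox <- round((as.numeric(fixpoints[i, c("x_um", "y_um", "z_um")]) - ref) /
                    img$voxel_size)
    img$data <- shift_array(img$data, -dvox)
    img
  })
}

# integer shift with replicated edge padding
shift_array <- function(a, dvox) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) pmin(pmax(seq_len(d[k]) - dvox[k], 1), d[k]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Map 16-bit dynamic range onto 8 bits
#'
#' Per-frame linear mapping of the `[P_lo, P_hi]` intensity percentiles onto
#' `[0, 255]` with clipping, compensating for changes in transgene expression
#' level across frames (a per-frame gain/bleaching model maps to identical
#' 8-bit frames).  A constant frame maps to all zeros.
#'
#' @param img a [voxel_image()] (one frame) or a plain numeric array.
#' @param lo_pct,hi_pct percentiles in `[0, 100]`, `lo_pct < hi_pct`.
#' @return a [voxel_image()] with range 0..255 (input arrays come back as
#'   arrays).
#' @export
map_dynamic_range <- function(img, lo_pct = 1, hi_pct = 99) {
  if (!(lo_pct >= 0 && hi_pct <= 100 && lo_pct < hi_pct))
    stop("need 0 <= lo_pct < hi_pct <= 100", call. = FALSE)
  arr <- if (inherits(img, "voxel_image")) img$data else img
  qs <- quantile(arr, c(lo_pct, hi_pct) / 100, names = FALSE)
  out <- if (qs[2] <= qs[1]) {
    array(0, dim(arr))                      # constant (or degenerate) frame
  } else {
    pmin(pmax((arr - qs[1]) / (qs[2] - qs[1]), 0), 1) * 255
  }
  if (inherits(img, "voxel_image"))
    voxel_image(out, img$voxel_size, range = c(0, 255))
  else out
}
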