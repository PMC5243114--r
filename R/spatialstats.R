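bin_key <- function(ix) paste(ix[, 1], ix[, 2], ix[, 3])

# cell-list index: integer bin per point at pitch s
build_bins <- function(pts, s, origin) {
  ix <- floor(sweep(pts, 2, origin) / s)
  storage.mode(ix) <- "integer"
  list(ix = ix, map = split(seq_len(nrow(pts)), bin_key(ix)), s = s,
       origin = origin)
}

neighbors_in_shell <- function(bins, ix0, m) {
  # indices of points in bins at Chebyshev distance exactly m from ix0
  offs <- expand.grid(dx = -m:m, dy = -m:m, dz = -m:m)
  if (m > 0) {
    keep <- pmax(abs(offs$dx), abs(offs$dy), abs(offs$dz)) == m
    offs <- offs[keep, , drop = FALSE]
  }
  keys <- paste(ix0[1] + offs$dx, ix0[2] + offs$dy, ix0[3] + offs$dz)
  unlist(bins$map[keys], use.names = FALSE)
}

#' Local cell density within a fixed radius
#'
#' For each centre, counts the other centres within `r` um (closed ball:
#' neighbours at exactly distance `r` are included; the focal point itself is
#' excluded) and divides by the volume of the sphere of that radius, giving a
#' density in cells per cubic um.  The default radius is 20 um.  No edge
#' correction is applied; nearest-neighbour distances are the boundary-robust
#' alternative for comparing subsets.
#'
#' @param points n x 3 matrix of positions (um) or data frame with
#'   `x_um,y_um,z_um` (a single frame).
#' @param r radius in um (> 0).
#' @param method `"grid"` (cell-list spatial index) or `"brute"` (all-pairs).
#' @return data frame `neighbor_count, density` (one row per input point,
#'   with `cell_id` carried over when present).
#' @export
local_density <- function(points, r = 20, method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(r > 0)
  ids <- if (is.data.frame(points) && "cell_id" %in% names(points))
    points$cell_id else seq_len(NROW(points))
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n < 1) stop("need at least one point", call. = FALSE)
  counts <- integer(n)
  if (n > 1) {
    if (method == "brute") {
      dm <- as.matrix(stats::dist(pts))
      counts <- as.integer(rowSums(dm <= r) - 1L)
    } else {
      bins <- build_bins(pts, r, apply(pts, 2, min))
      for (i in seq_len(n)) {
        cand <- unlist(lapply(0:1, function(m)
          neighbors_in_shell(bins, bins$ix[i, ], m)), use.names = FALSE)
        cand <- cand[cand != i]
        if (length(cand)) {
          dd <- sqrt(colSums((t(pts[cand, , drop = FALSE]) - pts[i, ])^2))
          counts[i] <- sum(dd <= r)
        }
      }
    }
  }
  data.frame(cell_id = ids, neighbor_count = counts,
             density = counts / (4 / 3 * pi * r^3))
}

#' Nearest-neighbour distances within a selection
#'
#' Distance from each point to its nearest other point of the same
#' selection (neighbours outside the selection are deliberately not
#' considered, which limits boundary effects when comparing subsets).
#'
#' @param points n x 3 matrix or data frame (single frame selection), n >= 2.
#' @param method `"grid"` (expanding-shell search on a cell-list index) or
#'   `"brute"` (all-pairs).
#' @return data frame `cell_id, nn_dist`.
#' @export
nn_distance <- function(points, method = c("grid", "brute")) {
  method <- match.arg(method)
  ids <- if (is.data.frame(points) && "cell_id" %in% names(points))
    points$cell_id else seq_len(NROW(points))
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n < 2)
    stop("insufficient data: nearest-neighbour distance needs >= 2 points",
         call. = FALSE)
  nn <- numeric(n)
  if (method == "brute") {
    dm <- as.matrix(stats::dist(pts))
    diag(dm) <- Inf
    nn <- apply(dm, 1, min)
  } else {
    ext <- apply(pts, 2, max) - apply(pts, 2, min)
    # pitch from the mean point spacing, guarded against flat/collinear
    # clouds whose bounding-box volume would collapse
    s <- max((prod(pmax(ext, 1e-9)) / n)^(1 / 3),
             max(ext) / max(ceiling(n^(1 / 3)), 1), 1e-9)
    bins <- build_bins(pts, s, apply(pts, 2, min))
    m_cap <- ceiling(max(ext) / s) + 1
    for (i in seq_len(n)) {
      best <- Inf; m <- 0
      repeat {
        cand <- neighbors_in_shell(bins, bins$ix[i, ], m)
        cand <- cand[cand != i]
        if (length(cand)) {
          dd <- sqrt(colSums((t(pts[cand, , drop = FALSE]) - pts[i, ])^2))
          best <- min(best, min(dd))
        }
        # all unvisited points are at distance >= m*s; safe to stop
        if (best <= m * s || m > m_cap) break
        m <- m + 1
      }
      nn[i] <- best
    }
  }
  data.frame(cell_id = ids, nn_dist = nn)
}

#' Summarise nearest-neighbour records per frame
#'
#' Median and quartiles (exact order statistics, linear interpolation
#' between order statistics as in [stats::quantile()] type 7) of `nn_dist`,
#' grouped by `t_hpf` when present.
#'
#' @param records data frame with `nn_dist` and optionally `t_hpf`.
#' @return data frame `t_hpf, n, q25, median, q75`.
#' @export
summarize_nn <- function(records) {
  grp <- if ("t_hpf" %in% names(records)) records$t_hpf else rep(NA_real_,
                                                                 nrow(records))
  res <- lapply(split(records$nn_dist, grp), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(n = length(v), q25 = q[1], median = q[2], q75 = q[3])
  })
  out <- do.call(rbind, res)
  out <- cbind(t_hpf = as.numeric(names(res)), out)
  rownames(out) <- NULL
  out
}
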