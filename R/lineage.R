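#' Build a lineage forest from a track table
#'
#' Groups rows into per-cell tracks, wires mother/daughter links and checks
#' the forest invariants: at most two daughters per cell, each daughter's
#' first frame is exactly one timestep after the mother's last frame, track
#' times are contiguous on the acquisition grid, and there are no cycles.
#' Cells whose track ends before the last frame without daughters are
#' flagged `censored` (lost/interrupted tracks are retained, not dropped).
#'
#' @param tracks validated track data frame (see [read_tracks()]).
#' @param dt acquisition timestep in hours; inferred as the smallest positive
#'   time difference when missing.
#' @return object of class `lineage_forest`: list with `tracks` (split data
#'   frames keyed by cell id), `parent`, `children`, `founders`, `divisions`
#'   (data frame `mother_id, daughter1, daughter2, t_hpf`), `info` (per-cell
#'   start/end/censoring), and `dt`.
#' @export
build_forest <- function(tracks, dt = NULL) {
  validate_tracks(tracks)
  tracks <- tracks[order(tracks$cell_id, tracks$t_hpf), ]
  tl <- split(tracks, tracks$cell_id)
  ids <- as.integer(names(tl))
  if (is.null(dt)) {
    dts <- unlist(lapply(tl, function(d) diff(d$t_hpf)), use.names = FALSE)
    dts <- dts[dts > 1e-12]
    if (!length(dts)) dts <- 1
    dt <- min(dts)
  }
  tol <- dt / 4
  # contiguity on the grid
  for (d in tl) {
    gaps <- diff(d$t_hpf)
    if (any(abs(gaps - dt) > tol))
      stop("contiguity error: cell ", d$cell_id[1], " has time gaps at t = ",
           paste(signif(d$t_hpf[which(abs(gaps - dt) > tol)], 6),
                 collapse = ", "), call. = FALSE)
  }
  parent <- vapply(tl, function(d) d$mother_id[1], integer(1))
  names(parent) <- names(tl)
  # a mother referenced must have ended before the daughter starts
  children <- split(ids[!is.na(parent)], parent[!is.na(parent)])
  nch <- vapply(children, length, integer(1))
  if (any(nch > 2))
    stop("lineage error: cell(s) ",
         paste(names(children)[nch > 2], collapse = ", "),
         " have more than two daughters", call. = FALSE)
  t_start <- vapply(tl, function(d) d$t_hpf[1], numeric(1))
  t_end <- vapply(tl, function(d) d$t_hpf[nrow(d)], numeric(1))
  for (m in names(children)) {
    for (ch in children[[m]]) {
      if (abs(t_start[as.character(ch)] - (t_end[m] + dt)) > tol)
        stop("lineage error: daughter ", ch, " starts at t = ",
             signif(t_start[as.character(ch)], 6),
             " but mother ", m, " ends at t = ", signif(t_end[m], 6),
             " (expected one timestep apart)", call. = FALSE)
    }
  }
  # cycle check by walking each cell to its founder
  for (id in ids) {
    seen <- integer(0); cur <- id
    while (!is.na(parent[as.character(cur)])) {
      if (cur %in% seen) stop("cycle error in lineage at cell ", id, call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent[as.character(cur)]
      if (!as.character(cur) %in% names(parent))
        stop("dangling mother link at cell ", id, call. = FALSE)
    }
  }
  div <- do.call(rbind, lapply(names(children)[nch == 2], function(m)
    data.frame(mother_id = as.integer(m),
               daughter1 = children[[m]][1], daughter2 = children[[m]][2],
               t_hpf = t_end[m])))
  if (is.null(div))
    div <- data.frame(mother_id = integer(0), daughter1 = integer(0),
                      daughter2 = integer(0), t_hpf = numeric(0))
  div <- div[order(div$t_hpf, div$mother_id), ]
  rownames(div) <- NULL
  t_last <- max(t_end)
  terminal <- !(ids %in% div$mother_id)
  info <- data.frame(cell_id = ids, t_start = unname(t_start),
                     t_end = unname(t_end),
                     terminal = terminal,
                     censored = terminal & (t_end < t_last - tol))
  structure(list(tracks = tl, parent = parent, children = children,
                 founders = ids[is.na(parent)], divisions = div,
                 info = info, dt = dt),
            class = "lineage_forest")
}

#' @method print lineage_forest
#' @export
print.lineage_forest <- function(x, ...) {
  cat("lineage_forest:", length(x$tracks), "tracks,",
      length(x$founders), "founders,", nrow(x$divisions), "divisions,",
      "dt =", signif(x$dt, 4), "h\n")
  invisible(x)
}

#' Position of a cell's ancestor at an earlier time
#'
#' Walks mother links from `cell_id` until the track covering `t_target` is
#' found and returns that ancestor's row (its progenitor state).  Returns
#' `NULL` if the lineage starts after `t_target`.
#'
#' @param forest a [build_forest()] result.
#' @param cell_id cell to backtrack.
#' @param t_target time (hpf), at or before the cell's last frame.
#' @return one-row data frame (a track point) or `NULL`.
#' @export
backtrack <- function(forest, cell_id, t_target) {
  key <- as.character(cell_id)
  if (!key %in% names(forest$tracks))
    stop("unknown cell_id: ", cell_id, call. = FALSE)
  tol <- forest$dt / 4
  cur <- key
  repeat {
    d <- forest$tracks[[cur]]
    if (t_target >= d$t_hpf[1] - tol) {
      if (t_target > d$t_hpf[nrow(d)] + tol && cur == key)
        stop("t_target is after cell ", cell_id, "'s last frame", call. = FALSE)
      i <- which.min(abs(d$t_hpf - t_target))
      return(d[i, , drop = FALSE])
    }
    mo <- forest$parent[[cur]]
    if (is.na(mo)) return(NULL)      # lineage starts after t_target
    cur <- as.character(mo)
  }
}

#' Flat lineage-tree layout
#'
#' Assigns each terminal track one horizontal lane; an internal (dividing)
#' track is drawn at the mean lane of its daughters so branches share the
#' mother's lane until the division.  Lineages (founder subtrees) are sorted
#' by `order_key`; censored tracks keep their truncated interval.
#'
#' @param forest a [build_forest()] result.
#' @param order_key named numeric vector keyed by founder id (e.g. the
#'   lineage's delamination time); unnamed lineages sort last.
#' @return data frame `cell_id, founder_id, lane, t_start, t_end, censored`.
#' @export
flat_layout <- function(forest, order_key = NULL) {
  ids <- forest$info$cell_id
  founder_of <- vapply(as.character(ids), function(k) {
    cur <- k
    while (!is.na(forest$parent[[cur]])) cur <- as.character(forest$parent[[cur]])
    as.integer(cur)
  }, integer(1))
  keys <- rep(Inf, length(forest$founders))
  names(keys) <- as.character(forest$founders)
  if (!is.null(order_key)) {
    common <- intersect(names(order_key), names(keys))
    keys[common] <- order_key[common]
  }
  founders_sorted <- forest$founders[order(keys, forest$founders)]
  lane <- numeric(0)
  next_lane <- 0L
  assign_lanes <- function(id) {
    key <- as.character(id)
    ch <- forest$children[[key]]
    if (is.null(ch) || length(ch) == 0) {
      next_lane <<- next_lane + 1L
      lane[key] <<- next_lane
    } else if (length(ch) == 1) {     # continuation link, shares the lane
      assign_lanes(ch)
      lane[key] <<- lane[[as.character(ch)]]
    } else {
      for (c2 in ch) assign_lanes(c2)
      lane[key] <<- mean(lane[as.character(ch)])
    }
  }
  for (f in founders_sorted) assign_lanes(f)
  out <- data.frame(cell_id = ids, founder_id = founder_of,
                    lane = unname(lane[as.character(ids)]),
                    t_start = forest$info$t_start, t_end = forest$info$t_end,
                    censored = forest$info$censored)
  out[order(out$lane, out$t_start), ]
}
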