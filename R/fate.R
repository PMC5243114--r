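has_label <- function(labels, what) {
  grepl(paste0("(^|;)", what, "(;|$)"), labels)
}

# terminal-path row concatenation: founder -> ... -> terminal track
lineage_path <- function(forest, terminal_id) {
  chain <- character(0)
  cur <- as.character(terminal_id)
  repeat {
    chain <- c(cur, chain)
    mo <- forest$parent[[cur]]
    if (is.na(mo)) break
    cur <- as.character(mo)
  }
  do.call(rbind, forest$tracks[chain])
}

#' Detect delamination events
#'
#' A cell delaminates when its centre first leaves the epithelial shell
#' through the basal (outer) surface and stays outside for at least
#' `k_hysteresis` consecutive frames (suppressing tracking jitter); a track
#' that ends while the cell is still outside also counts, even if fewer than
#' `k_hysteresis` frames remain.  Runs are searched along whole
#' founder-to-terminal paths so an exit just before a division is credited
#' to the mother, and each cell delaminates at most once.
#'
#' @param forest a [build_forest()] result.
#' @param geom a [vesicle_geometry()].
#' @param k_hysteresis minimum number of consecutive outside frames (>= 1).
#' @param intervals passed to [assign_interval()].
#' @return data frame `cell_id, t_delam, x_epi, y_epi, z_epi, interval_class`
#'   (`*_epi` = last position before exit).
#' @export
detect_delamination <- function(forest, geom, k_hysteresis = 3,
                                intervals = c(18, 20, 22, 24, 30)) {
  stopifnot(k_hysteresis >= 1)
  terminals <- forest$info$cell_id[forest$info$terminal]
  found <- list()
  for (tid in terminals) {
    path <- lineage_path(forest, tid)
    out <- classify_points(geom, path) == "outside"
    if (!any(out)) next
    r <- rle(out)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- r$values & (r$lengths >= k_hysteresis | ends == length(out))
    if (!any(ok)) next
    i0 <- starts[which(ok)[1]]
    ev <- data.frame(cell_id = path$cell_id[i0], t_delam = path$t_hpf[i0],
                     x_epi = NA_real_, y_epi = NA_real_, z_epi = NA_real_)
    if (i0 > 1) {
      ev$x_epi <- path$x_um[i0 - 1]
      ev$y_epi <- path$y_um[i0 - 1]
      ev$z_epi <- path$z_um[i0 - 1]
    }
    found[[length(found) + 1L]] <- ev
  }
  if (!length(found))
    return(data.frame(cell_id = integer(0), t_delam = numeric(0),
                      x_epi = numeric(0), y_epi = numeric(0),
                      z_epi = numeric(0), interval_class = character(0)))
  events <- unique(do.call(rbind, found))
  events <- events[order(events$t_delam, events$cell_id), ]
  rownames(events) <- NULL
  events$interval_class <- assign_interval(events$t_delam, intervals)
  events
}

#' Bin delamination times into display intervals
#'
#' Half-open bins `[lo, hi)` named after the conventional colour code
#' (18-20 hpf white, 20-22 yellow, 22-24 orange, 24-30 red); times outside
#' all bins map to `"other"`.
#'
#' @param t numeric times (hpf).
#' @param breaks increasing bin boundaries (default `c(18, 20, 22, 24, 30)`).
#' @param labels one name per bin.
#' @return character vector of interval classes.
#' @export
assign_interval <- function(t, breaks = c(18, 20, 22, 24, 30),
                            labels = c("white", "yellow", "orange", "red")) {
  stopifnot(length(labels) == length(breaks) - 1, !is.unsorted(breaks))
  i <- findInterval(t, breaks, rightmost.closed = FALSE, left.open = FALSE)
  out <- rep("other", length(t))
  ok <- i >= 1 & i <= length(labels) & t < breaks[length(breaks)]
  out[ok] <- labels[i[ok]]
  out
}

#' Posterior expansion of the marker-positive epithelial domain
#'
#' For each frame, the position of the posterior-most marker-positive
#' epithelial cell as a percent of the anteroposterior vesicle length:
#' `front(t) = 100 (x_postmost - x_ant) / (x_post - x_ant)`.
#'
#' @param tracks track data frame with `labels`.
#' @param geom a [vesicle_geometry()] giving the AP extent.
#' @param marker label marking the domain (default `"neurod"`).
#' @return data frame `t_hpf, front_pct, n_marker`; frames with no
#'   marker-positive epithelial cell get `NA` (and a message).
#' @export
expansion_front <- function(tracks, geom, marker = "neurod") {
  x_ant <- geom$center[1] - geom$outer_semiaxes[1]
  ap_len <- 2 * geom$outer_semiaxes[1]
  ts <- sort(unique(tracks$t_hpf))
  res <- lapply(ts, function(t) {
    rows <- tracks[abs(tracks$t_hpf - t) < 1e-9 & has_label(tracks$labels, marker), ]
    if (nrow(rows))
      rows <- rows[classify_points(geom, rows) == "epithelium", , drop = FALSE]
    if (!nrow(rows))
      return(data.frame(t_hpf = t, front_pct = NA_real_, n_marker = 0L))
    data.frame(t_hpf = t,
               front_pct = 100 * (max(rows$x_um) - x_ant) / ap_len,
               n_marker = nrow(rows))
  })
  out <- do.call(rbind, res)
  if (anyNA(out$front_pct))
    message("expansion_front: no marker+ epithelial cells at ",
            sum(is.na(out$front_pct)), " frame(s)")
  out
}

# first delamination time in each founder's subtree, NA when none
subtree_index <- function(forest) {
  vapply(as.character(forest$info$cell_id), function(k) {
    cur <- k
    while (!is.na(forest$parent[[cur]])) cur <- as.character(forest$parent[[cur]])
    as.integer(cur)
  }, integer(1))
}

#' Classify division behaviour of delaminating lineages
#'
#' Each founder whose lineage delaminates within `window` is classified
#' `before` if the lineage's first division precedes its first delamination
#' (an epithelial division whose daughters exit), `after` if the first
#' division follows the exit, and `none` without any division in the window.
#' The classes partition the cohort.
#'
#' @param forest a [build_forest()] result.
#' @param events delamination events from [detect_delamination()].
#' @param window length-2 analysis interval in hpf.
#' @return list with `classes` (data frame `founder_id, class, t_first_division,
#'   t_first_delam`) and `counts` (named vector before/after/none).
#' @export
classify_division_behavior <- function(forest, events,
                                       window = c(-Inf, Inf)) {
  founder_of <- subtree_index(forest)
  names(founder_of) <- as.character(forest$info$cell_id)
  ev <- events[events$t_delam >= window[1] & events$t_delam <= window[2], ]
  ev_founder <- founder_of[as.character(ev$cell_id)]
  div <- forest$divisions
  div <- div[div$t_hpf >= window[1] & div$t_hpf <= window[2], , drop = FALSE]
  div_founder <- founder_of[as.character(div$mother_id)]
  cohort <- sort(unique(ev_founder))
  classes <- vapply(cohort, function(f) {
    t_delam <- min(ev$t_delam[ev_founder == f])
    tdiv <- div$t_hpf[div_founder == f]
    if (!length(tdiv)) return("none")
    if (min(tdiv) < t_delam) "before" else "after"
  }, character(1))
  tfd <- vapply(cohort, function(f) {
    tdiv <- div$t_hpf[div_founder == f]
    if (length(tdiv)) min(tdiv) else NA_real_
  }, numeric(1))
  tde <- vapply(cohort, function(f) min(ev$t_delam[ev_founder == f]), numeric(1))
  out <- data.frame(founder_id = cohort, class = classes,
                    t_first_division = tfd, t_first_delam = tde)
  rownames(out) <- NULL
  counts <- c(before = sum(classes == "before"),
              after = sum(classes == "after"),
              none = sum(classes == "none"))
  list(classes = out, counts = counts)
}

#' Delamination delay between sister cells
#'
#' For every division, takes each daughter subtree's first delamination and
#' reports the absolute delay between the two sisters; pairs where only one
#' sister delaminates are reported `censored` with `NA` delay.  Delays above
#' two hours are flagged.
#'
#' @param forest a [build_forest()] result.
#' @param events delamination events.
#' @param flag_hours threshold for the long-delay flag (default 2 h).
#' @return data frame `mother_id, t_division, t_delam_1, t_delam_2, delay_h,
#'   long_delay, censored`.
#' @export
sister_delay <- function(forest, events, flag_hours = 2) {
  if (!nrow(forest$divisions))
    return(data.frame(mother_id = integer(0), t_division = numeric(0),
                      t_delam_1 = numeric(0), t_delam_2 = numeric(0),
                      delay_h = numeric(0), long_delay = logical(0),
                      censored = logical(0)))
  # first delamination within each cell's own subtree
  desc_delam <- function(id) {
    key <- as.character(id)
    ids <- id
    frontier <- id
    while (length(frontier)) {
      ch <- unlist(forest$children[as.character(frontier)], use.names = FALSE)
      frontier <- ch
      ids <- c(ids, ch)
    }
    tt <- events$t_delam[events$cell_id %in% ids]
    if (length(tt)) min(tt) else NA_real_
  }
  res <- lapply(seq_len(nrow(forest$divisions)), function(i) {
    dv <- forest$divisions[i, ]
    t1 <- desc_delam(dv$daughter1)
    t2 <- desc_delam(dv$daughter2)
    if (is.na(t1) && is.na(t2)) return(NULL)
    delay <- abs(t1 - t2)
    data.frame(mother_id = dv$mother_id, t_division = dv$t_hpf,
               t_delam_1 = t1, t_delam_2 = t2, delay_h = delay,
               long_delay = !is.na(delay) && delay > flag_hours,
               censored = is.na(t1) || is.na(t2))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(mother_id = integer(0), t_division = numeric(0),
                      t_delam_1 = numeric(0), t_delam_2 = numeric(0),
                      delay_h = numeric(0), long_delay = logical(0),
                      censored = logical(0))
  out
}

#' Rank correspondence between epithelial exit and ganglion positions
#'
#' Tests whether the relative order of cells along an anatomical axis at
#' their epithelial exit is maintained in the ganglion: Spearman rank
#' correlation between the exit coordinate and the ganglion coordinate,
#' with a two-sided permutation tail probability from `n_perm` label
#' permutations under a fixed seed.
#'
#' @param events delamination events (with `x_epi`/`y_epi`).
#' @param sag data frame `cell_id, x_um, y_um, z_um`: positions of the same
#'   cells in the ganglion at a reference time.
#' @param axis `"AP"` (x) or `"ML"` (y).
#' @param n_perm number of permutations (>= 999 recommended).
#' @param seed RNG seed for the permutations.
#' @return object of class `correspondence_result`: list `axis, rho, n, p_perm`.
#' @export
positional_correspondence <- function(events, sag, axis = c("AP", "ML"),
                                      n_perm = 999, seed = 1) {
  axis <- match.arg(axis)
  epi_col <- if (axis == "AP") "x_epi" else "y_epi"
  sag_col <- if (axis == "AP") "x_um" else "y_um"
  merged <- merge(events[, c("cell_id", epi_col)],
                  sag[, c("cell_id", sag_col)], by = "cell_id")
  merged <- merged[stats::complete.cases(merged), ]
  n <- nrow(merged)
  if (n < 5)
    stop("insufficient data: need >= 5 paired cells, got ", n, call. = FALSE)
  a <- merged[[epi_col]]; b <- merged[[sag_col]]
  rho <- cor(a, b, method = "spearman")
  set.seed(seed)
  ra <- rank(a); rb <- rank(b)
  perm <- vapply(seq_len(n_perm), function(i)
    cor(ra, sample(rb)), numeric(1))
  p_perm <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  structure(list(axis = axis, rho = rho, n = n, p_perm = p_perm),
            class = "correspondence_result")
}

#' @method print correspondence_result
#' @export
print.correspondence_result <- function(x, ...) {
  cat(sprintf("axis %s: Spearman rho = %.3f (n = %d, permutation p = %.4f)\n",
              x$axis, x$rho, x$n, x$p_perm))
  invisible(x)
}

#' Fraction of epithelial cells lost by delamination
#'
#' Of the cells classified epithelial at `t0`, the fraction whose lineage
#' delaminates within `[t0, t1]`; a cell counts once even if it divides.
#'
#' @param forest a [build_forest()] result.
#' @param events delamination events.
#' @param t0,t1 window in hpf (`t0 < t1`).
#' @param geom a [vesicle_geometry()] used to classify cells at `t0`.
#' @return list `fraction, n_epithelial, n_delaminating`.
#' @export
delaminated_fraction <- function(forest, events, t0, t1, geom) {
  stopifnot(t0 < t1)
  tol <- forest$dt / 4
  at_t0 <- do.call(rbind, lapply(forest$tracks, function(d) {
    i <- which(abs(d$t_hpf - t0) < tol)
    if (length(i)) d[i[1], ] else NULL
  }))
  if (is.null(at_t0) || !nrow(at_t0))
    return(list(fraction = NA_real_, n_epithelial = 0L, n_delaminating = 0L))
  epi <- at_t0[classify_points(geom, at_t0) == "epithelium", ]
  ev <- events[events$t_delam >= t0 & events$t_delam <= t1, ]
  founder_of <- subtree_index(forest)
  names(founder_of) <- as.character(forest$info$cell_id)
  # ancestor chain of each event cell; an epithelial t0-cell counts if it is
  # the event cell itself or one of its ancestors
  hit <- logical(nrow(epi))
  for (ec in ev$cell_id) {
    cur <- as.character(ec)
    repeat {
      hit <- hit | (epi$cell_id == as.integer(cur))
      mo <- forest$parent[[cur]]
      if (is.na(mo)) break
      cur <- as.character(mo)
    }
  }
  list(fraction = sum(hit) / nrow(epi),
       n_epithelial = nrow(epi), n_delaminating = sum(hit))
}

#' Detect hair-cell differentiation onsets
#'
#' The onset time is the first frame carrying the differentiation marker
#' label; label flickering (on-off-on) uses the earliest onset with a
#' warning.  Each event is assigned to the anterior (AM) or posterior (PM)
#' macula by the nearest tether-cell anchor (the tether cells form the
#' posterior pole of each macula); anchors default to the onset positions of
#' tether-labelled cells, split AM/PM by their anteroposterior order.
#'
#' @param forest a [build_forest()] result.
#' @param marker differentiation marker label (default `"hc"`).
#' @param tether tether-cell label (default `"tether"`).
#' @param anchors optional 2 x 3 matrix (rows AM, PM) overriding the
#'   tether-derived anchors.
#' @return data frame `cell_id, t_diff, x_um, y_um, z_um, patch, tether`.
#' @export
detect_differentiation <- function(forest, marker = "hc", tether = "tether",
                                   anchors = NULL) {
  evs <- list()
  for (key in names(forest$tracks)) {
    d <- forest$tracks[[key]]
    on <- has_label(d$labels, marker)
    if (!any(on)) next
    i0 <- which(on)[1]
    if (any(!on[seq(i0, length(on))]))
      warning("label flickering for cell ", d$cell_id[1],
              "; using earliest onset", call. = FALSE)
    evs[[key]] <- data.frame(cell_id = d$cell_id[1], t_diff = d$t_hpf[i0],
                             x_um = d$x_um[i0], y_um = d$y_um[i0],
                             z_um = d$z_um[i0],
                             tether = has_label(d$labels[i0], tether))
  }
  if (!length(evs))
    return(data.frame(cell_id = integer(0), t_diff = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      patch = character(0), tether = logical(0)))
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  if (is.null(anchors)) {
    te <- out[out$tether, , drop = FALSE]
    if (nrow(te) >= 2) {
      te <- te[order(te$x_um), ]
      anchors <- rbind(AM = as.numeric(te[1, c("x_um", "y_um", "z_um")]),
                       PM = as.numeric(te[nrow(te), c("x_um", "y_um", "z_um")]))
    }
  }
  if (is.null(anchors)) {
    out$patch <- NA_character_
  } else {
    dAM <- sqrt(rowSums(sweep(as.matrix(out[, c("x_um", "y_um", "z_um")]),
                              2, anchors[1, ])^2))
    dPM <- sqrt(rowSums(sweep(as.matrix(out[, c("x_um", "y_um", "z_um")]),
                              2, anchors[2, ])^2))
    out$patch <- ifelse(dAM <= dPM, "AM", "PM")
  }
  out[order(out$t_diff, out$cell_id),
      c("cell_id", "t_diff", "x_um", "y_um", "z_um", "patch", "tether")]
}

#' Check that differentiated cells are postmitotic
#'
#' @param forest a [build_forest()] result.
#' @param events differentiation events from [detect_differentiation()].
#' @return data frame of violations (`cell_id, t_diff, t_division`), empty
#'   when every differentiated cell stays undivided after onset.
#' @export
postmitotic_check <- function(forest, events) {
  tol <- forest$dt / 4
  div <- forest$divisions
  bad <- lapply(seq_len(nrow(events)), function(i) {
    m <- div[div$mother_id == events$cell_id[i] &
               div$t_hpf > events$t_diff[i] - tol, , drop = FALSE]
    if (nrow(m))
      data.frame(cell_id = events$cell_id[i], t_diff = events$t_diff[i],
                 t_division = m$t_hpf)
    else NULL
  })
  out <- do.call(rbind, bad)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), t_diff = numeric(0),
                      t_division = numeric(0))
  out
}

#' Cumulative differentiated-cell growth curve
#'
#' @param events differentiation events.
#' @param patch optional `"AM"`/`"PM"` filter.
#' @return data frame `t_hpf, n_cum`: a nondecreasing step curve whose final
#'   value equals the event count.
#' @export
growth_curve <- function(events, patch = NULL) {
  if (!is.null(patch)) events <- events[events$patch %in% patch, ]
  if (!nrow(events)) return(data.frame(t_hpf = numeric(0), n_cum = integer(0)))
  tt <- sort(events$t_diff)
  ts <- unique(tt)
  data.frame(t_hpf = ts,
             n_cum = vapply(ts, function(t) sum(tt <= t), integer(1)))
}

#' Progenitor map at a reference time
#'
#' Backtracks each event cell to its ancestor position at `t_ref`, carrying
#' a colour key (the event time by default).  Cells whose lineage starts
#' after `t_ref` are dropped.
#'
#' @param forest a [build_forest()] result.
#' @param events data frame with `cell_id` and an event-time column.
#' @param t_ref reference time (hpf).
#' @param key name of the event-time column used as colour key
#'   (`"t_diff"` or `"t_delam"`).
#' @return data frame `cell_id, x_um, y_um, z_um, key`.
#' @export
progenitor_map <- function(forest, events, t_ref, key = "t_diff") {
  res <- lapply(seq_len(nrow(events)), function(i) {
    tp <- backtrack(forest, events$cell_id[i], t_ref)
    if (is.null(tp)) return(NULL)
    data.frame(cell_id = events$cell_id[i], x_um = tp$x_um, y_um = tp$y_um,
               z_um = tp$z_um, key = events[[key]][i])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0), key = numeric(0))
  out
}

#' Overlap between two progenitor domains
#'
#' Number of cells of map `a` lying within radius `r` of any cell of map `b`
#' (adjacency of the neuronal and sensory progenitor fields).
#'
#' @param a,b progenitor maps ([progenitor_map()] output).
#' @param r radius in um.
#' @return integer count.
#' @export
progenitor_overlap <- function(a, b, r = 10) {
  if (!nrow(a) || !nrow(b)) return(0L)
  pa <- as.matrix(a[, c("x_um", "y_um", "z_um")])
  pb <- as.matrix(b[, c("x_um", "y_um", "z_um")])
  sum(vapply(seq_len(nrow(pa)), function(i) {
    any(sqrt(colSums((t(pb) - pa[i, ])^2)) <= r)
  }, logical(1)))
}
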