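#' Simulation parameters for the synthetic otic epithelium
#'
#' Bundles the generator settings: cohort size, time window (hours
#' post-fertilization, hpf), acquisition step, per-domain division rates,
#' delamination probability and front speed, hair-cell differentiation rate,
#' positional jitter and the RNG seed.  Defaults emulate the neurogenic phase
#' of the zebrafish otic vesicle (18-30 hpf, 5-min frames, roughly a quarter
#' of eligible epithelial cells delaminating, division behaviours split
#' between before-exit, after-exit and non-dividing).
#'
#' @param n0 initial number of epithelial cells (> 0).
#' @param t0,t1 start/end of the simulated window in hpf.
#' @param dt acquisition timestep in hours (default 1/12 h = 5 min).
#' @param division_rate_nonsensory,division_rate_sensory divisions per cell
#'   per hour in the non-sensory (and neurogenic) vs sensory domains.
#' @param delam_prob probability that an eligible epithelial cell delaminates
#'   within the window.
#' @param delam_front_speed speed of the posterior advance of the delamination
#'   eligibility front, as fraction of the AP vesicle length per hour.
#' @param diff_onset_rate hair-cell differentiation onsets per hour per macula.
#' @param noise_xyz isotropic per-step positional jitter s.d. (um).
#' @param seed integer RNG seed; identical seeds give byte-identical tables.
#' @param delam_domain `"neurogenic"` restricts delamination to the
#'   anteroventrolateral neurogenic domain; `"all"` makes every founder
#'   eligible (useful for parameter-recovery studies).
#' @param max_generations cap on division depth per founder lineage.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(n0 = 300, t0 = 18, t1 = 30, dt = 1 / 12,
                       division_rate_nonsensory = 0.07,
                       division_rate_sensory = 0.03,
                       delam_prob = 0.25,
                       delam_front_speed = 0.125,
                       diff_onset_rate = 0.6,
                       noise_xyz = 0.15,
                       seed = 1L,
                       delam_domain = c("neurogenic", "all"),
                       max_generations = 4L) {
  delam_domain <- match.arg(delam_domain)
  p <- list(n0 = as.integer(n0), t0 = t0, t1 = t1, dt = dt,
            division_rate_nonsensory = division_rate_nonsensory,
            division_rate_sensory = division_rate_sensory,
            delam_prob = delam_prob, delam_front_speed = delam_front_speed,
            diff_onset_rate = diff_onset_rate, noise_xyz = noise_xyz,
            seed = as.integer(seed), delam_domain = delam_domain,
            max_generations = as.integer(max_generations))
  if (p$n0 <= 0L) stop("n0 must be positive", call. = FALSE)
  if (!(p$t1 > p$t0)) stop("t1 must exceed t0", call. = FALSE)
  if (p$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (p$delam_prob < 0 || p$delam_prob > 1)
    stop("delam_prob must lie in [0, 1]", call. = FALSE)
  rates <- c(p$division_rate_nonsensory, p$division_rate_sensory,
             p$delam_front_speed, p$diff_onset_rate, p$noise_xyz)
  if (any(rates < 0)) stop("rates and noise must be non-negative", call. = FALSE)
  class(p) <- "sim_params"
  p
}

# snap a continuous time onto the acquisition grid (nearest frame)
snap_time <- function(t, t0, dt) t0 + round((t - t0) / dt) * dt

# domain assignment from the founder position:
#   ventral floor, lateral  -> neurogenic (delamination-competent)
#   ventral floor, medial   -> sensory (prospective maculae)
#   elsewhere               -> non-sensory (dorsolateral)
assign_domains <- function(geom, pos) {
  cz <- geom$center[3]; az <- geom$outer_semiaxes[3]
  cy <- geom$center[2]
  ventral <- pos[, 3] < cz - 0.25 * az
  lateral <- pos[, 2] >= cy
  domain <- rep("nonsensory", nrow(pos))
  domain[ventral & lateral] <- "neurogenic"
  domain[ventral & !lateral] <- "sensory"
  domain
}

# AP position as fraction of the vesicle length, in [0, 1]
ap_fraction <- function(geom, x) {
  (x - (geom$center[1] - geom$outer_semiaxes[1])) / (2 * geom$outer_semiaxes[1])
}

#' Simulate a tracked otic epithelium with delamination and differentiation
#'
#' Places `n0` cells in the epithelial shell, assigns anatomical domains
#' (neurogenic, sensory, non-sensory), and simulates the window `[t0, t1]`:
#' eligible neurogenic cells delaminate (exit the basal surface into a
#' ganglion region beneath the ventral floor) with probability `delam_prob`,
#' the eligible region's posterior edge advancing at `delam_front_speed`;
#' cells divide as track branchings at per-domain rates; sensory cells near
#' the two macula anchors acquire hair-cell differentiation onsets and are
#' postmitotic afterwards.  Delaminated cells keep their anteroposterior
#' order in the ganglion but settle mediolaterally by arrival order (lateral
#' accretion), scrambling the mediolateral epithelial order.
#'
#' @param geom a [vesicle_geometry()].
#' @param p a [sim_params()].
#' @return A list with
#'   * `tracks`: data frame `cell_id, mother_id, t_hpf, x_um, y_um, z_um, labels`
#'     (one row per cell per frame; `labels` semicolon-joined markers among
#'     `neurod`, `hc`, `tether`);
#'   * `truth`: ground-truth labels — `cells` (per track: domain, founder,
#'     delamination time, differentiation time, patch, tether flag),
#'     `founders` (per founder: domain, delaminating lineage flag, division
#'     behaviour class `before`/`after`/`none`), `delaminations` (cell, time,
#'     last epithelial position), `divisions` (mother, daughters, time),
#'     `founder_positions` (positions at `t0`), and the `params`/`geom` used.
#' @export
simulate_epithelium <- function(geom, p = sim_params()) {
  stopifnot(inherits(geom, "vesicle_geometry"), inherits(p, "sim_params"))
  set.seed(p$seed)
  times <- seq(p$t0, p$t1, by = p$dt)
  nt <- length(times)

  pos0 <- sample_shell(geom, p$n0)
  domain <- assign_domains(geom, pos0)
  eligible <- if (p$delam_domain == "all") rep(TRUE, p$n0) else domain == "neurogenic"

  # --- delamination schedule (per founder Bernoulli, exact binomial count)
  front0 <- 0.25
  delam_founder <- eligible & (runif(p$n0) < p$delam_prob)
  apf <- ap_fraction(geom, pos0[, 1])
  t_elig <- p$t0 + pmax(0, (apf - front0) / max(p$delam_front_speed, 1e-9))
  t_elig <- pmin(t_elig, p$t1 - p$dt)

  # division rate per domain (neurogenic behaves like non-sensory)
  div_rate <- ifelse(domain == "sensory",
                     p$division_rate_sensory, p$division_rate_nonsensory)

  # --- differentiation schedule (two maculae anchored ventromedially)
  anchors <- rbind(
    AM = geom$center + c(-0.45, -0.55, -0.75) * geom$outer_semiaxes,
    PM = geom$center + c(0.45, -0.55, -0.75) * geom$outer_semiaxes)
  sensory_idx <- which(domain == "sensory")
  diff_sched <- list()   # founder -> list(t_diff, patch, tether)
  if (length(sensory_idx) >= 2 && p$diff_onset_rate > 0) {
    d_am <- sqrt(rowSums(sweep(pos0[sensory_idx, , drop = FALSE], 2, anchors[1, ])^2))
    d_pm <- sqrt(rowSums(sweep(pos0[sensory_idx, , drop = FALSE], 2, anchors[2, ])^2))
    patch0 <- ifelse(d_am <= d_pm, "AM", "PM")
    for (pa in c("AM", "PM")) {
      members <- sensory_idx[patch0 == pa]
      if (!length(members)) next
      ord <- members[order(if (pa == "AM") d_am[patch0 == "AM"] else d_pm[patch0 == "PM"])]
      # arrival process: tether first, then Poisson arrivals
      arr <- p$t0 + 0.5
      arrivals <- arr
      while (TRUE) {
        arr <- arr + rexp(1, p$diff_onset_rate)
        if (arr > p$t1) break
        arrivals <- c(arrivals, arr)
      }
      k <- min(length(arrivals), length(ord))
      for (j in seq_len(k)) {
        diff_sched[[as.character(ord[j])]] <-
          list(t_diff = snap_time(arrivals[j], p$t0, p$dt), patch = pa,
               tether = (j == 1L))
      }
    }
  }

  # --- event-schedule simulation per founder lineage -----------------------
  # Cells are track segments; a division ends the mother at the division
  # frame and starts two daughters one frame later.
  cells <- list()   # per track: birth/death frame index, mother, fate fields
  next_id <- 0L
  new_cell <- function(mother, t_birth, pos, founder, gen, delam_t, diff,
                       born_out = FALSE) {
    next_id <<- next_id + 1L
    cells[[next_id]] <<- list(id = next_id, mother = mother, t_birth = t_birth,
                              t_end = p$t1, pos0 = pos, founder = founder,
                              gen = gen, delam_t = delam_t, diff = diff,
                              born_out = born_out,
                              div_t = NA_real_, daughters = NULL)
    next_id
  }

  sister_delays <- function() rexp(1, 1)   # hours; ~13% exceed 2 h

  founder_rows <- vector("list", p$n0)
  queue <- integer(0)
  for (i in seq_len(p$n0)) {
    delam_t <- NA_real_
    if (delam_founder[i]) {
      # the bulk of exits follows the eligibility front within a couple of
      # hours (delamination is massive once the domain is established)
      lo <- max(t_elig[i], p$t0) + p$dt
      delam_t <- snap_time(lo + rexp(1, 0.7), p$t0, p$dt)
      delam_t <- min(max(delam_t, p$t0 + p$dt), p$t1)
    }
    id <- new_cell(NA_integer_, p$t0, pos0[i, ], i, 1L,
                   delam_t, diff_sched[[as.character(i)]])
    queue <- c(queue, id)
  }

  divisions <- list()
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    cl <- cells[[id]]
    rate <- div_rate[cl$founder]
    if (cl$gen >= p$max_generations || rate <= 0) next
    t_div <- cl$t_birth + rexp(1, rate)
    t_div <- snap_time(t_div, p$t0, p$dt)
    # postmitotic after differentiation onset
    if (!is.null(cl$diff) && t_div >= cl$diff$t_diff) next
    if (t_div <= cl$t_birth) t_div <- cl$t_birth + p$dt
    if (t_div > p$t1 - p$dt) next
    # delaminating mother dividing in the epithelium passes the fate to both
    # daughters; the sisters exit with a random delay between them
    d_delam <- c(NA_real_, NA_real_)
    if (!is.na(cl$delam_t)) {
      if (t_div < cl$delam_t) {
        d1 <- max(cl$delam_t, t_div + p$dt)
        d2 <- snap_time(cl$delam_t + sister_delays(), p$t0, p$dt)
        d_delam <- c(d1, min(max(d2, t_div + p$dt), p$t1))
      }                      # else: division happens after exit, in the SAG
    }
    cells[[id]]$div_t <- t_div
    cells[[id]]$t_end <- t_div
    off <- matrix(rnorm(6, 0, 1), 2, 3)
    off <- 2 * off / pmax(sqrt(rowSums(off^2)), 1e-9)   # +-2 um offsets
    diff_inherit <- list(NULL, NULL)
    if (!is.null(cl$diff)) diff_inherit[[1]] <- cl$diff
    delam_inherit <- d_delam
    out_birth <- cl$born_out ||
      (!is.na(cl$delam_t) && t_div >= cl$delam_t)
    if (out_birth) delam_inherit <- c(NA, NA)
    da <- vapply(1:2, function(k)
      new_cell(id, t_div + p$dt, off[k, ], cl$founder, cl$gen + 1L,
               delam_inherit[k], diff_inherit[[k]], born_out = out_birth),
      integer(1))
    cells[[id]]$daughters <- da
    divisions[[length(divisions) + 1L]] <-
      data.frame(mother_id = id, daughter1 = da[1], daughter2 = da[2], t_hpf = t_div)
    queue <- c(queue, da)
  }
  ncell <- next_id

  # --- trajectories --------------------------------------------------------
  # SAG settlement: AP order preserved (compressed toward the centre), ML by
  # arrival order (lateral accretion), depth below the ventral floor.
  floor_z <- geom$center[3] - geom$outer_semiaxes[3]
  delam_tab <- do.call(rbind, lapply(cells, function(cl)
    if (!is.na(cl$delam_t) && cl$delam_t >= cl$t_birth && cl$delam_t <= cl$t_end)
      data.frame(cell_id = cl$id, t_delam = cl$delam_t) else NULL))
  sag_pos <- NULL
  if (!is.null(delam_tab) && nrow(delam_tab)) {
    ord <- order(delam_tab$t_delam, delam_tab$cell_id)
    rank_arr <- integer(nrow(delam_tab)); rank_arr[ord] <- seq_along(ord)
    cy <- geom$center[2]; ay <- geom$outer_semiaxes[2]
    y_lat <- (cy - 0.6 * ay) + 1.2 * ay * (rank_arr - 1) / max(nrow(delam_tab) - 1, 1)
    sag_pos <- data.frame(
      cell_id = delam_tab$cell_id,
      t_delam = delam_tab$t_delam,
      y_sag = y_lat + rnorm(nrow(delam_tab), 0, 0.8),
      z_sag = floor_z - runif(nrow(delam_tab), 5, 12))
  }

  rows <- vector("list", ncell)
  epi_last <- vector("list", ncell)   # last epithelial position per delam cell
  for (id in seq_len(ncell)) {
    cl <- cells[[id]]
    ti <- which(times >= cl$t_birth - 1e-9 & times <= cl$t_end + 1e-9)
    if (!length(ti)) next
    k <- length(ti)
    pos <- matrix(NA_real_, k, 3)
    delam_here <- !is.na(cl$delam_t) && cl$delam_t <= cl$t_end + 1e-9
    # a daughter born from a post-delamination division starts in the SAG
    already_out <- isTRUE(cl$born_out)
    if (is.na(cl$mother)) {
      pos[1, ] <- cl$pos0
    } else {
      mrows <- rows[[cl$mother]]
      pos[1, ] <- as.numeric(mrows[nrow(mrows), c("x_um", "y_um", "z_um")]) +
        cl$pos0   # pos0 holds the +-2 um daughter offset
      if (!already_out)
        pos[1, ] <- project_into_shell(geom, rbind(pos[1, ]))[1, ]
    }
    if (already_out) pos[1, 3] <- min(pos[1, 3], floor_z - 2)
    sag_target <- NULL
    if (delam_here) {
      sp <- sag_pos[sag_pos$cell_id == id, ]
      x_sag <- geom$center[1] + 0.8 * (cl$pos0[1] - geom$center[1]) +
        rnorm(1, 0, 0.8)
      sag_target <- c(x_sag, sp$y_sag[1], sp$z_sag[1])
    }
    # vectorized trajectory: random walk about the start (projected into the
    # shell while epithelial), switching to the ganglion target at exit
    walk <- if (p$noise_xyz > 0 && k > 1) {
      apply(matrix(rnorm(3 * (k - 1), 0, p$noise_xyz), k - 1, 3), 2, cumsum)
    } else matrix(0, max(k - 1, 0), 3)
    walk <- rbind(c(0, 0, 0), matrix(walk, ncol = 3))
    jd <- if (already_out) 1L else if (delam_here)
      which(times[ti] >= cl$delam_t - 1e-9)[1] else k + 1L
    if (jd > 1) {
      epi <- 1:(jd - 1)
      pos[epi, ] <- project_into_shell(
        geom, sweep(walk[epi, , drop = FALSE], 2, pos[1, ], "+"))
    }
    if (jd <= k) {
      outr <- jd:k
      base <- if (already_out) pos[1, ] else sag_target
      off <- sweep(walk[outr, , drop = FALSE], 2, walk[jd, ])
      pos[outr, ] <- sweep(off, 2, base, "+")
      pos[outr, 3] <- pmin(pos[outr, 3], floor_z - 2)  # stay beneath the floor
      if (!already_out && jd > 1) epi_last[[id]] <- pos[jd - 1, ]
    }
    # labels: neurod marks delamination-competent cells once the front passes
    labs <- character(k)
    fo <- cl$founder
    if (eligible[fo]) {
      on <- times[ti] >= t_elig[fo] - 1e-9
      labs[on] <- "neurod"
    }
    if (!is.null(cl$diff)) {
      on <- times[ti] >= cl$diff$t_diff - 1e-9
      tag <- if (isTRUE(cl$diff$tether)) "hc;tether" else "hc"
      labs[on] <- ifelse(nzchar(labs[on]), paste(labs[on], tag, sep = ";"), tag)
    }
    rows[[id]] <- data.frame(
      cell_id = id,
      mother_id = if (is.na(cl$mother)) NA_integer_ else cl$mother,
      t_hpf = times[ti], x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
      labels = labs)
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$cell_id, tracks$t_hpf), ]
  rownames(tracks) <- NULL

  # --- ground truth --------------------------------------------------------
  cell_info <- do.call(rbind, lapply(cells[seq_len(ncell)], function(cl) {
    data.frame(cell_id = cl$id, founder_id = cl$founder,
               domain = domain[cl$founder],
               delam_time = if (!is.na(cl$delam_t) && cl$delam_t <= cl$t_end + 1e-9)
                 cl$delam_t else NA_real_,
               t_diff = if (!is.null(cl$diff) &&
                            cl$diff$t_diff <= cl$t_end + 1e-9)
                 cl$diff$t_diff else NA_real_,   # onset expressed in-track
               patch = if (!is.null(cl$diff) &&
                           cl$diff$t_diff <= cl$t_end + 1e-9)
                 cl$diff$patch else NA_character_,
               tether = if (!is.null(cl$diff)) isTRUE(cl$diff$tether) else FALSE)
  }))
  div_tab <- if (length(divisions)) do.call(rbind, divisions) else
    data.frame(mother_id = integer(0), daughter1 = integer(0),
               daughter2 = integer(0), t_hpf = numeric(0))
  delam_events <- do.call(rbind, lapply(which(!is.na(cell_info$delam_time)),
    function(i) {
      id <- cell_info$cell_id[i]
      pe <- epi_last[[id]]
      if (is.null(pe)) {
        # delamination at birth: last epithelial position is the mother's end
        mo <- cells[[id]]$mother
        if (!is.na(mo) && !is.null(rows[[mo]]) && nrow(rows[[mo]]))
          pe <- as.numeric(rows[[mo]][nrow(rows[[mo]]), c("x_um", "y_um", "z_um")])
        else pe <- c(NA_real_, NA_real_, NA_real_)
      }
      data.frame(cell_id = id, t_delam = cell_info$delam_time[i],
                 x_epi = pe[1], y_epi = pe[2], z_epi = pe[3])
    }))
  if (is.null(delam_events))
    delam_events <- data.frame(cell_id = integer(0), t_delam = numeric(0),
                               x_epi = numeric(0), y_epi = numeric(0),
                               z_epi = numeric(0))
  # per-founder division-behaviour class relative to lineage delamination
  founder_class <- vapply(seq_len(p$n0), function(f) {
    ids <- which(cell_info$founder_id == f)
    dts <- cell_info$delam_time[ids]
    if (all(is.na(dts))) return(NA_character_)
    first_delam <- min(dts, na.rm = TRUE)
    div_f <- div_tab[div_tab$mother_id %in% cell_info$cell_id[ids], , drop = FALSE]
    if (!nrow(div_f)) return("none")
    if (min(div_f$t_hpf) < first_delam) "before" else "after"
  }, character(1))
  founders <- data.frame(
    founder_id = seq_len(p$n0), domain = domain,
    eligible = eligible, delaminates = !is.na(founder_class),
    division_class = founder_class,
    x0 = pos0[, 1], y0 = pos0[, 2], z0 = pos0[, 3])

  list(tracks = tracks,
       truth = list(cells = cell_info, founders = founders,
                    delaminations = delam_events, divisions = div_tab,
                    founder_positions = pos0, anchors = anchors,
                    front0 = front0, params = p, geom = geom))
}
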