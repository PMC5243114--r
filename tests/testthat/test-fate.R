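test_that("a basal exit with persistence is one delamination event", {
  geom <- default_geom()
  forest <- build_forest(toy_exit_track(t_out = 20))
  ev <- detect_delamination(forest, geom, k_hysteresis = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_delam, 20)
  expect_equal(ev$z_epi, -35)
  expect_equal(ev$interval_class, "yellow")
})

test_that("a one-frame dip outside is suppressed by hysteresis", {
  geom <- default_geom()
  forest <- build_forest(toy_exit_track(dip_frames = 10))
  ev <- detect_delamination(forest, geom, k_hysteresis = 3)
  expect_equal(nrow(ev), 0)
})

test_that("noiseless synthetic delaminations are recovered exactly", {
  geom <- default_geom()
  sim <- simulate_epithelium(geom, noiseless_params(n0 = 200, seed = 3))
  forest <- build_forest(sim$tracks)
  ev <- detect_delamination(forest, geom)
  truth <- sim$truth$delaminations
  expect_equal(nrow(ev), nrow(truth))
  m <- merge(ev, truth, by = "cell_id")
  expect_equal(nrow(m), nrow(truth))        # precision = recall = 1
  expect_equal(m$t_delam.x, m$t_delam.y, tolerance = 1e-9)
  expect_equal(m$x_epi.x, m$x_epi.y, tolerance = 1e-9)
  expect_equal(m$z_epi.x, m$z_epi.y, tolerance = 1e-9)
  # pre-event positions classify epithelial
  pre <- data.frame(x_um = m$x_epi.x, y_um = m$y_epi.x, z_um = m$z_epi.x)
  expect_true(all(classify_points(geom, pre) == "epithelium"))
})

test_that("interval binning is half-open with an overflow class", {
  expect_equal(assign_interval(19.5), "white")
  expect_equal(assign_interval(20.0), "yellow")   # boundary joins upper bin
  expect_equal(assign_interval(c(18, 21.9, 23, 29.9, 30, 31)),
               c("white", "yellow", "orange", "red", "other", "other"))
})

test_that("the expansion front is a percentage of the AP vesicle length", {
  geom <- vesicle_geometry(center = c(50, 0, 0),
                           outer_semiaxes = c(50, 40, 40))
  tracks <- data.frame(cell_id = 1:2, mother_id = NA_integer_, t_hpf = 20,
                       x_um = c(30, 10), y_um = 0, z_um = c(-30, -20),
                       labels = c("neurod", "neurod"))
  fr <- expansion_front(tracks, geom)
  expect_equal(fr$front_pct, 30)
  tracks$x_um[1] <- 100    # on the posterior pole of the basal surface
  tracks$z_um[1] <- 0
  expect_equal(expansion_front(tracks, geom)$front_pct, 100)
  tracks$labels <- ""
  expect_message(fr0 <- expansion_front(tracks, geom), "no marker")
  expect_true(is.na(fr0$front_pct))
})

test_that("the synthetic front expands at the configured speed", {
  geom <- default_geom()
  p <- sim_params(n0 = 400, seed = 12, noise_xyz = 0)
  sim <- simulate_epithelium(geom, p)
  fr <- expansion_front(sim$tracks, geom)
  t_sat <- p$t0 + (0.92 - sim$truth$front0) / p$delam_front_speed
  fr <- fr[!is.na(fr$front_pct) & fr$t_hpf <= t_sat, ]
  slope <- unname(coef(lm(front_pct ~ t_hpf, fr))[2])
  expect_lt(abs(slope - 100 * p$delam_front_speed) /
              (100 * p$delam_front_speed), 0.1)
})

test_that("division behaviour classes split before/after/none", {
  geom <- default_geom()
  # division at 19, both daughters exit at 21 -> before
  tr <- toy_division_tracks(t0 = 18, t_div = 19, t_end = 22)
  tr$z_um[tr$cell_id %in% c(2, 3) & tr$t_hpf >= 21] <- -55
  f <- build_forest(tr)
  ev <- detect_delamination(f, geom)
  cb <- classify_division_behavior(f, ev)
  expect_equal(unname(cb$counts), c(1L, 0L, 0L))
  # exit at 19, division at 21 -> after
  tr2 <- toy_division_tracks(t0 = 18, t_div = 21, t_end = 22)
  tr2$z_um[tr2$t_hpf >= 19] <- -55
  f2 <- build_forest(tr2)
  ev2 <- detect_delamination(f2, geom)
  cb2 <- classify_division_behavior(f2, ev2)
  expect_equal(unname(cb2$counts), c(0L, 1L, 0L))
})

test_that("division behaviour is recovered exactly on noiseless tracks", {
  geom <- default_geom()
  sim <- simulate_epithelium(geom, sim_params(n0 = 250, seed = 42,
                                              noise_xyz = 0))
  forest <- build_forest(sim$tracks)
  ev <- detect_delamination(forest, geom)
  cb <- classify_division_behavior(forest, ev)
  truth <- sim$truth$founders
  truth <- truth[!is.na(truth$division_class), ]
  m <- merge(cb$classes, truth[, c("founder_id", "division_class")],
             by = "founder_id")
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$class, m$division_class)
  # classes partition the cohort
  expect_equal(sum(cb$counts), nrow(cb$classes))
})

test_that("sister delays flag pairs exiting more than two hours apart", {
  geom <- default_geom()
  tr <- toy_division_tracks(t0 = 18, t_div = 19, t_end = 24)
  tr$z_um[tr$cell_id == 2 & tr$t_hpf >= 20] <- -55
  tr$z_um[tr$cell_id == 3 & tr$t_hpf >= 23.5] <- -55
  f <- build_forest(tr)
  ev <- detect_delamination(f, geom)
  sd <- sister_delay(f, ev)
  expect_equal(sd$delay_h, 3.5)
  expect_true(sd$long_delay)
  expect_false(sd$censored)
  # simultaneous exits are unflagged
  tr$z_um[tr$cell_id == 3 & tr$t_hpf >= 20] <- -55
  sd2 <- sister_delay(build_forest(tr), detect_delamination(build_forest(tr), geom))
  expect_equal(sd2$delay_h, 0)
  expect_false(sd2$long_delay)
})

test_that("sister-delay summaries match direct order statistics", {
  geom <- default_geom()
  sim <- simulate_epithelium(geom, sim_params(n0 = 300, seed = 55,
                                              noise_xyz = 0,
                                              delam_prob = 0.6,
                                              division_rate_nonsensory = 0.12))
  f <- build_forest(sim$tracks)
  ev <- detect_delamination(f, geom)
  sd <- sister_delay(f, ev)
  d <- sd$delay_h[!sd$censored & !is.na(sd$delay_h)]
  expect_gt(length(d), 3)
  q <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  # direct sorting oracle (type-7 interpolation done by hand)
  oracle_q <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  expect_equal(q, vapply(c(0.25, 0.5, 0.75), function(p) oracle_q(d, p),
                         numeric(1)))
})

test_that("rank correspondence detects preserved and scrambled axes", {
  ev <- data.frame(cell_id = 1:8, x_epi = 1:8, y_epi = 1:8)
  sag_same <- data.frame(cell_id = 1:8, x_um = (1:8) * 2, y_um = 8:1)
  r <- positional_correspondence(ev, sag_same, "AP", n_perm = 199)
  expect_equal(r$rho, 1)
  r2 <- positional_correspondence(ev, sag_same, "ML", n_perm = 199)
  expect_equal(r2$rho, -1)
  expect_error(positional_correspondence(ev[1:4, ], sag_same, "AP"),
               "insufficient")
})

test_that("AP order survives into the ganglion while ML order scrambles", {
  geom <- default_geom()
  p <- noiseless_params(n0 = 100, seed = 9, delam_prob = 1,
                        division_rate_nonsensory = 0,
                        division_rate_sensory = 0, diff_onset_rate = 0)
  sim <- simulate_epithelium(geom, p)
  f <- build_forest(sim$tracks)
  ev <- detect_delamination(f, geom)
  sag <- do.call(rbind, lapply(ev$cell_id, function(id) {
    d <- f$tracks[[as.character(id)]]
    d[nrow(d), c("cell_id", "x_um", "y_um", "z_um")]
  }))
  rAP <- positional_correspondence(ev, sag, "AP", seed = 1)
  rML <- positional_correspondence(ev, sag, "ML", seed = 1)
  expect_equal(rAP$n, 100)
  expect_gte(rAP$rho, 0.8)
  expect_lte(abs(rML$rho), 0.3)
  expect_lte(rAP$p_perm, 0.005)
})

test_that("delaminated fraction counts lineages once", {
  geom <- default_geom()
  tr <- toy_exit_track(t_out = 20)
  tr2 <- toy_exit_track(t_out = 28, t_end = 22)   # never exits in window
  tr2$cell_id <- 2L
  f <- build_forest(rbind(tr, tr2))
  ev <- detect_delamination(f, geom)
  fr <- delaminated_fraction(f, ev, 18, 22, geom)
  expect_equal(fr$fraction, 0.5)
  expect_equal(fr$n_epithelial, 2L)
  # no events -> 0
  f0 <- build_forest(tr2)
  expect_equal(delaminated_fraction(f0, detect_delamination(f0, geom),
                                    18, 22, geom)$fraction, 0)
})

test_that("differentiation onsets, patches and postmitotic state are exact", {
  geom <- default_geom()
  sim <- simulate_epithelium(geom, sim_params(n0 = 250, seed = 42,
                                              noise_xyz = 0))
  f <- build_forest(sim$tracks)
  de <- detect_differentiation(f, anchors = sim$truth$anchors)
  truth <- sim$truth$cells[!is.na(sim$truth$cells$t_diff), ]
  expect_equal(nrow(de), nrow(truth))
  m <- merge(de, truth[, c("cell_id", "t_diff", "patch")], by = "cell_id")
  expect_equal(m$t_diff.x, m$t_diff.y, tolerance = 1e-9)
  expect_equal(m$patch.x, m$patch.y)
  expect_equal(nrow(postmitotic_check(f, de)), 0)
})

test_that("onset is the first labelled frame; flicker warns; violations found", {
  dt <- 1 / 12
  tt <- seq(27, 31, by = dt)
  labs <- ifelse(tt >= 28, "hc", "")
  tr <- data.frame(cell_id = 1L, mother_id = NA_integer_, t_hpf = tt,
                   x_um = 0, y_um = 0, z_um = 0, labels = labs)
  f <- build_forest(tr)
  de <- detect_differentiation(f)
  expect_equal(de$t_diff, 28)
  # flicker: on-off-on keeps the earliest onset with a warning
  labs2 <- labs
  labs2[20] <- ""
  trf <- tr; trf$labels <- labs2
  expect_warning(de2 <- detect_differentiation(build_forest(trf)), "flicker")
  expect_equal(de2$t_diff, 28)
  # a division after onset is a postmitotic violation
  trd <- toy_division_tracks(t0 = 27, t_div = 30, t_end = 31)
  trd$labels[trd$cell_id == 1 & trd$t_hpf >= 28] <- "hc"
  fd <- build_forest(trd)
  ded <- detect_differentiation(fd)
  viol <- postmitotic_check(fd, ded)
  expect_equal(nrow(viol), 1)
  expect_equal(viol$t_division, 30)
})

test_that("growth curves step cumulatively to the event count", {
  ev <- data.frame(cell_id = 1:3, t_diff = c(25, 25, 30),
                   patch = c("AM", "AM", "AM"))
  g <- growth_curve(ev, "AM")
  expect_equal(g$t_hpf, c(25, 30))
  expect_equal(g$n_cum, c(2L, 3L))
  expect_true(all(diff(g$n_cum) >= 0))
  expect_equal(tail(g$n_cum, 1), nrow(ev))
})

test_that("progenitor maps backtrack events and count domain overlap", {
  forest <- build_forest(toy_division_tracks())
  ev <- data.frame(cell_id = 3L, t_diff = 21)
  pm <- progenitor_map(forest, ev, t_ref = 18)
  expect_equal(pm$x_um, 0)   # founder position
  # identity backtrack at the event cell's own first time
  pm2 <- progenitor_map(forest, ev, t_ref = 20 + 1 / 12)
  expect_equal(pm2$x_um, 2)
  # disjoint domains separated by more than r overlap in zero cells
  a <- data.frame(cell_id = 1:3, x_um = 0, y_um = 0, z_um = c(0, 1, 2))
  b <- data.frame(cell_id = 4:6, x_um = 50, y_um = 0, z_um = c(0, 1, 2))
  expect_equal(progenitor_overlap(a, b, r = 10), 0L)
  expect_equal(progenitor_overlap(a, rbind(b, data.frame(
    cell_id = 7, x_um = 5, y_um = 0, z_um = 0)), r = 10), 3L)
})
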