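test_that("degenerate parameters give an unbranched, event-free cohort", {
  geom <- default_geom()
  p <- sim_params(n0 = 30, seed = 3, division_rate_nonsensory = 0,
                  division_rate_sensory = 0, delam_prob = 0,
                  diff_onset_rate = 0)
  sim <- simulate_epithelium(geom, p)
  expect_equal(length(unique(sim$tracks$cell_id)), 30)
  expect_true(all(is.na(sim$tracks$mother_id)))
  expect_equal(nrow(sim$truth$delaminations), 0)
  expect_equal(nrow(sim$truth$divisions), 0)
  expect_true(all(is.na(sim$truth$cells$t_diff)))
})

test_that("invalid simulation parameters error", {
  expect_error(sim_params(n0 = 0), "positive")
  expect_error(sim_params(t0 = 20, t1 = 18), "exceed")
  expect_error(sim_params(delam_prob = 1.5), "0, 1")
})

test_that("identical seeds give identical simulations", {
  geom <- default_geom()
  p <- sim_params(n0 = 60, seed = 17)
  s1 <- simulate_epithelium(geom, p)
  s2 <- simulate_epithelium(geom, p)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth$cells, s2$truth$cells)
  s3 <- simulate_epithelium(geom, sim_params(n0 = 60, seed = 18))
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("delamination count is binomial over eligible founders", {
  geom <- default_geom()
  p <- noiseless_params(n0 = 200, seed = 1, delam_prob = 0.25,
                        division_rate_nonsensory = 0,
                        division_rate_sensory = 0, diff_onset_rate = 0)
  sim <- simulate_epithelium(geom, p)
  n_ev <- nrow(sim$truth$delaminations)
  band <- qbinom(c(0.005, 0.995), 200, 0.25)
  expect_gte(n_ev, band[1])
  expect_lte(n_ev, band[2])
})

test_that("ground truth and track table are mutually consistent", {
  geom <- default_geom()
  sim <- simulate_epithelium(geom, sim_params(n0 = 120, seed = 5))
  tr <- sim$tracks
  th <- sim$truth
  # every labelled cell exists in the table
  expect_true(all(th$cells$cell_id %in% tr$cell_id))
  # delamination times lie in the window and are reproducible from the table:
  # the cell's first frame outside the shell equals the recorded time
  for (i in seq_len(nrow(th$delaminations))) {
    ev <- th$delaminations[i, ]
    expect_gte(ev$t_delam, sim$truth$params$t0)
    expect_lte(ev$t_delam, sim$truth$params$t1)
    rows <- tr[tr$cell_id == ev$cell_id, ]
    out <- classify_points(geom, rows) == "outside"
    first_out <- rows$t_hpf[which(out)[1]]
    expect_equal(first_out, ev$t_delam)
  }
  # divisions appear as track branchings one step after the mother's end
  dt <- th$params$dt
  for (i in seq_len(nrow(th$divisions))) {
    dv <- th$divisions[i, ]
    mo <- tr[tr$cell_id == dv$mother_id, ]
    expect_equal(max(mo$t_hpf), dv$t_hpf)
    for (dgt in c(dv$daughter1, dv$daughter2)) {
      da <- tr[tr$cell_id == dgt, ]
      expect_equal(min(da$t_hpf), dv$t_hpf + dt, tolerance = 1e-9)
    }
  }
})

test_that("eligibility front advances with anteroposterior position", {
  geom <- default_geom()
  p <- noiseless_params(n0 = 150, seed = 8, delam_prob = 1,
                        division_rate_nonsensory = 0,
                        division_rate_sensory = 0, diff_onset_rate = 0)
  sim <- simulate_epithelium(geom, p)
  ev <- merge(sim$truth$delaminations,
              sim$truth$founders[, c("founder_id", "x0")],
              by.x = "cell_id", by.y = "founder_id")
  apf <- (ev$x0 - (geom$center[1] - geom$outer_semiaxes[1])) /
    (2 * geom$outer_semiaxes[1])
  t_elig <- p$t0 + pmax(0, (apf - sim$truth$front0) / p$delam_front_speed)
  # no cell delaminates before the front has reached it
  expect_true(all(ev$t_delam >= pmin(t_elig, p$t1 - p$dt) - p$dt / 2))
})

test_that("differentiated cells never divide after onset", {
  geom <- default_geom()
  sim <- simulate_epithelium(geom, sim_params(n0 = 200, seed = 23,
                                              diff_onset_rate = 1.5))
  diffed <- sim$truth$cells[!is.na(sim$truth$cells$t_diff), ]
  expect_gt(nrow(diffed), 0)
  div <- sim$truth$divisions
  for (i in seq_len(nrow(diffed))) {
    after <- div$t_hpf[div$mother_id == diffed$cell_id[i]] >= diffed$t_diff[i]
    expect_false(any(after))
  }
})

test_that("surface point sampling honours geometry, noise and seed", {
  sph <- sphere_geom(r = 40)
  pts <- sample_surface_points(sph, "outer", 100, noise = 0, seed = 2)
  expect_equal(sqrt(rowSums(pts^2)), rep(40, 100), tolerance = 1e-9)
  # folded-normal bound on jitter
  ptsn <- sample_surface_points(sph, "outer", 300, noise = 0.5, seed = 2)
  dev <- abs(sqrt(rowSums(ptsn^2)) - 40)
  expect_lte(mean(dev), 3 * 0.5)
  # determinism and the degenerate-count error
  expect_identical(sample_surface_points(sph, "inner", 50, 0.2, seed = 9),
                   sample_surface_points(sph, "inner", 50, 0.2, seed = 9))
  expect_error(sample_surface_points(sph, "outer", 3), "at least 4")
})

test_that("point clouds round-trip through XYZ and PLY", {
  set.seed(4)
  pc <- matrix(rnorm(45), 15, 3)
  for (ext in c(".xyz", ".ply")) {
    f <- tempfile(fileext = ext)
    write_pointcloud(pc, f)
    back <- read_pointcloud(f)
    expect_equal(unname(back), unname(pc), tolerance = 1e-6)
  }
})
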