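ball_field <- function(n, r0) {
  ax <- seq_len(n) - (n + 1) / 2
  r0 - sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
}

test_that("the edge detector is 1 on flat images and dips on edges", {
  flat <- voxel_image(array(40, c(8, 8, 8)))
  expect_equal(edge_detector(flat, sigma = 1, K = 100)$g,
               array(1, c(8, 8, 8)))
  set.seed(3)
  img <- voxel_image(array(runif(512, 0, 255), c(8, 8, 8)))
  expect_equal(edge_detector(img, sigma = 0, K = 0)$g, array(1, c(8, 8, 8)))
  # a bright shell puts the g minimum on the shell slope voxels
  n <- 32
  ctr <- data.frame(x_um = 16, y_um = 16, z_um = 16)
  ri <- render_images(ctr, NULL, 1, psf_sigma = 0.5, dim = rep(n, 3),
                      origin = c(0, 0, 0), cell_radius = 9)
  g <- edge_detector(ri$membranes, sigma = 0.5, K = 300)$g
  ax <- seq_len(n) - 17
  rr <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  ring <- abs(rr - 9) <= 2.5
  expect_lt(min(g[ring]), 0.05)
  expect_gt(min(g[rr < 5]), 0.95)
  expect_true(all(g > 0 & g <= 1))
})

test_that("seed initialization builds a clipped union of bumps", {
  u0 <- initialize_levelset(rbind(c(8, 8, 8)), dim = 16, voxel_size = 1,
                            radius = 5)
  expect_equal(u0[9, 9, 9], 1)
  expect_equal(max(u0), 1)
  ax <- seq_len(16) - 9
  rr <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  expect_true(all(u0[rr >= 5] == 0))
  # two disjoint seeds give two disjoint superlevel components
  u2 <- initialize_levelset(rbind(c(4, 8, 8), c(12, 8, 8)), dim = 16,
                            radius = 3)
  expect_equal(u2[5, 9, 9], 1)
  expect_equal(u2[13, 9, 9], 1)
  expect_equal(u2[9, 9, 9], 0)   # gap between the seeds
  # the union is the voxelwise maximum of the individual fields
  ua <- initialize_levelset(rbind(c(7, 8, 8)), dim = 16, radius = 4)
  ub <- initialize_levelset(rbind(c(10, 8, 8)), dim = 16, radius = 4)
  uu <- initialize_levelset(rbind(c(7, 8, 8), c(10, 8, 8)), dim = 16,
                            radius = 4)
  expect_equal(uu, pmax(ua, ub))
  expect_error(initialize_levelset(rbind(c(40, 8, 8)), dim = 16), "outside")
})

test_that("a constant field is a stationary point of the evolution", {
  u0 <- array(0.5, c(12, 12, 12))
  g <- array(1, c(12, 12, 12))
  ev <- evolve_levelset(u0, g, gsubsurf_params(wa = 1, wc = 1))
  expect_equal(ev$iterations, 1)
  expect_equal(ev$u, u0, tolerance = 1e-12)
  # wa = wc = 0 leaves any field untouched
  set.seed(1)
  ur <- array(runif(12^3), c(12, 12, 12))
  ev0 <- evolve_levelset(ur, g, gsubsurf_params(wa = 0, wc = 0, max_iter = 3,
                                                tol = 1e-16))
  expect_equal(ev0$u, ur, tolerance = 1e-12)
})

test_that("mean-curvature flow shrinks a sphere as r(t)^2 = r0^2 - 4t", {
  n <- 48
  r0 <- 8
  u <- ball_field(n, r0)
  g <- array(1, c(n, n, n))
  p <- gsubsurf_params(wa = 0, wc = 1, dt = 0.5, tol = 1e-12, max_iter = 1)
  tcur <- 0
  for (s in 1:20) {
    u_prev <- u
    ev <- evolve_levelset(u, g, p)
    u <- ev$u
    tcur <- tcur + ev$dt
    # discrete maximum principle: each step stays inside the previous range
    expect_gte(min(ev$trace$u_min), min(u_prev) - 1e-9)
    expect_lte(max(ev$trace$u_max), max(u_prev) + 1e-9)
    r_theo <- sqrt(r0^2 - 4 * tcur)
    if (r_theo < 4) break
    r_num <- (3 * sum(u > 0) / (4 * pi))^(1 / 3)
    expect_lt(abs(r_num - r_theo) / r_theo, 0.05)
  }
})

test_that("pure edge advection parks the interface at the g minimum", {
  n <- 40
  ax <- seq_len(n) - (n + 1) / 2
  rr <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  r_wall <- 10
  g <- 1 - 0.99 * exp(-((rr - r_wall) / 1.5)^2)   # analytic valley at r = 10
  u0 <- initialize_levelset(rbind(rep((n + 1) / 2, 3)), dim = n, radius = 11)
  ev <- evolve_levelset(u0, g, gsubsurf_params(wa = 3, wc = 0, dt = 0.25,
                                               tol = 1e-7, max_iter = 300))
  mask <- ev$u >= 0.1 * max(ev$u)
  truth <- rr <= r_wall
  jac <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jac, 0.9)
})

test_that("cell extraction reports consistent voxel and mesh volumes", {
  n <- 40
  r0 <- 9
  u <- ball_field(n, r0)
  res <- extract_cell(u, iso = 0, voxel_size = 1)
  vol_true <- 4 / 3 * pi * r0^3
  expect_lt(abs(res$volume_voxel_um3 - vol_true) / vol_true, 0.1)
  expect_lt(abs(res$volume_mesh_um3 - res$volume_voxel_um3) /
              res$volume_voxel_um3, 0.1)
  expect_gt(nrow(res$mesh$faces), 100)
  expect_error(extract_cell(u, iso = max(u) + 1), "empty segmentation")
})

test_that("halving the voxel size does not worsen the shrink law", {
  err_at <- function(n, r0, steps, dt) {
    u <- ball_field(n, r0)
    g <- array(1, c(n, n, n))
    p <- gsubsurf_params(wa = 0, wc = 1, dt = dt, tol = 1e-12,
                         max_iter = steps)
    ev <- evolve_levelset(u, g, p)
    r_num <- (3 * sum(ev$u > 0) / (4 * pi))^(1 / 3)
    abs(r_num - sqrt(r0^2 - 4 * steps * dt))
  }
  # same physical problem, coarse vs fine grid (radius in voxels doubles,
  # voxel size halves => time step scales with h^2)
  coarse <- err_at(24, 5, 4, 0.5) * 1       # voxel 1 -> error in um
  fine <- err_at(48, 10, 16, 0.5) / 2       # voxel 0.5 -> error in um
  expect_lte(fine, coarse + 0.05)
})
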