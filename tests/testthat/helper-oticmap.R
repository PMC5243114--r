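# shared fixtures, all generated in code

default_geom <- function() vesicle_geometry()

sphere_geom <- function(r = 40, thickness = 10)
  vesicle_geometry(outer_semiaxes = rep(r, 3), shell_thickness = thickness)

# minimal hand-built track table: one founder dividing at t = 20 into two
# daughters followed to t_end (5-min frames)
toy_division_tracks <- function(t0 = 18, t_div = 20, t_end = 21, dt = 1 / 12) {
  tt <- seq(t0, t_div, by = dt)
  td <- seq(t_div + dt, t_end, by = dt)
  rbind(
    data.frame(cell_id = 1L, mother_id = NA_integer_, t_hpf = tt,
               x_um = 0, y_um = 0, z_um = 30, labels = ""),
    data.frame(cell_id = 2L, mother_id = 1L, t_hpf = td,
               x_um = -2, y_um = 0, z_um = 30, labels = ""),
    data.frame(cell_id = 3L, mother_id = 1L, t_hpf = td,
               x_um = 2, y_um = 0, z_um = 30, labels = ""))
}

# straight single-cell track with a basal exit at t_out (stays out after)
toy_exit_track <- function(t0 = 18, t_out = 20, t_end = 22, dt = 1 / 12,
                           dip_frames = NULL) {
  tt <- seq(t0, t_end, by = dt)
  z <- ifelse(tt >= t_out - 1e-9, -55, -35)   # outer ellipsoid z-semiaxis 40
  if (!is.null(dip_frames)) {
    z <- rep(-35, length(tt))
    z[dip_frames] <- -55
  }
  data.frame(cell_id = 1L, mother_id = NA_integer_, t_hpf = tt,
             x_um = 0, y_um = 0, z_um = z, labels = "")
}

noiseless_params <- function(n0 = 200, seed = 1, delam_prob = 0.3, ...) {
  sim_params(n0 = n0, seed = seed, noise_xyz = 0, delam_prob = delam_prob,
             delam_domain = "all", ...)
}

expect_frames_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  for (cn in names(a)) expect_equal(a[[cn]], b[[cn]], tolerance = tol)
}
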