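test_that("track tables round-trip through the CSV dialect", {
  tracks <- toy_division_tracks()
  tracks$labels[1] <- "neurod;hc"
  f <- tempfile(fileext = ".csv")
  write_tracks(tracks, f)
  back <- read_tracks(f)
  expect_frames_equal(back, tracks)
})

test_that("schema violations are reported with offenders", {
  tracks <- toy_division_tracks()
  bad <- tracks
  bad$mother_id[10] <- 99L
  expect_error(validate_tracks(bad), "dangling.*99")
  dup <- rbind(tracks, tracks[1, ])
  expect_error(validate_tracks(dup), "duplicate")
})

test_that("empty files return an empty schema table with a warning", {
  f <- tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_warning(tab <- read_tracks(f), "empty")
  expect_equal(nrow(tab), 0)
  expect_named(tab, c("cell_id", "mother_id", "t_hpf", "x_um", "y_um",
                      "z_um", "labels"))
})

test_that("fixpoint registration shifts frames by the landmark drift", {
  tracks <- data.frame(cell_id = 1L, mother_id = NA_integer_,
                       t_hpf = c(1, 2), x_um = c(5, 7), y_um = c(5, 6),
                       z_um = c(5, 5), labels = "")
  fix <- data.frame(t_hpf = c(1, 2), x_um = c(10, 12), y_um = c(10, 11),
                    z_um = c(10, 10))
  reg <- register_fixpoint(tracks, fix)
  expect_equal(reg$x_um, c(5, 5))
  expect_equal(reg$y_um, c(5, 5))
  expect_equal(reg$z_um, c(5, 5))
  # constant trajectory: identity
  fix0 <- data.frame(t_hpf = c(1, 2), x_um = 3, y_um = 3, z_um = 3)
  expect_equal(register_fixpoint(tracks, fix0), tracks)
  # missing frame errors
  expect_error(register_fixpoint(tracks, fix[1, , drop = FALSE]), "missing")
})

test_that("registration recovers synthetically drifted tracks exactly", {
  geom <- default_geom()
  sim <- simulate_epithelium(geom, sim_params(n0 = 40, seed = 2))
  ts <- sort(unique(sim$tracks$t_hpf))
  # drift accumulates from the first frame (zero at t0), so the registered
  # table recovers the original coordinates exactly
  drift <- data.frame(t_hpf = ts, x_um = 0.5 * (ts - 18),
                      y_um = sin(ts) - sin(ts[1]), z_um = 0.2 * (ts - 18)^1.5)
  drifted <- sim$tracks
  i <- match(drifted$t_hpf, ts)
  drifted$x_um <- drifted$x_um + drift$x_um[i]
  drifted$y_um <- drifted$y_um + drift$y_um[i]
  drifted$z_um <- drifted$z_um + drift$z_um[i]
  fix <- data.frame(t_hpf = ts, x_um = 10 + drift$x_um,
                    y_um = 20 + drift$y_um, z_um = 5 + drift$z_um)
  reg <- register_fixpoint(drifted, fix)
  expect_equal(reg$x_um, sim$tracks$x_um, tolerance = 1e-12)
  expect_equal(reg$y_um, sim$tracks$y_um, tolerance = 1e-12)
  expect_equal(reg$z_um, sim$tracks$z_um, tolerance = 1e-12)
})

test_that("track registration commutes with a rigid dataset translation", {
  tracks <- toy_division_tracks()
  ts <- sort(unique(tracks$t_hpf))
  fix <- data.frame(t_hpf = ts, x_um = cumsum(runif(length(ts))),
                    y_um = 0, z_um = sin(ts))
  shift <- c(7, -3, 11)
  shifted <- tracks
  shifted$x_um <- shifted$x_um + shift[1]
  shifted$y_um <- shifted$y_um + shift[2]
  shifted$z_um <- shifted$z_um + shift[3]
  fix_shifted <- fix
  fix_shifted$x_um <- fix$x_um + shift[1]
  fix_shifted$y_um <- fix$y_um + shift[2]
  fix_shifted$z_um <- fix$z_um + shift[3]
  a <- register_fixpoint(shifted, fix_shifted)
  b <- register_fixpoint(tracks, fix)
  expect_equal(a$x_um, b$x_um + shift[1], tolerance = 1e-12)
  expect_equal(a$z_um, b$z_um + shift[3], tolerance = 1e-12)
})

test_that("image registration shifts voxels by integer offsets", {
  a <- array(0, c(8, 8, 8)); a[4, 5, 6] <- 255
  drifted <- voxel_image(oticmap:::shift_array(a, c(1, 0, -2)), 1)
  imgs <- list(voxel_image(a, 1), drifted)
  fix <- data.frame(t_hpf = 1:2, x_um = c(4, 5), y_um = c(5, 5),
                    z_um = c(6, 4))
  reg <- register_fixpoint_images(imgs, fix)
  expect_identical(reg[[2]]$data, a)
})

test_that("dynamic-range mapping is linear, scale-invariant and monotone", {
  ramp <- voxel_image(array(seq(0, 65535, length.out = 512), c(8, 8, 8)),
                      range = c(0, 65535))
  m8 <- map_dynamic_range(ramp, 0, 100)
  expect_equal(min(m8$data), 0)
  expect_equal(max(m8$data), 255)
  # per-frame mapping removes a global bleaching factor
  bleached <- voxel_image(ramp$data * 0.5, range = c(0, 65535))
  expect_equal(map_dynamic_range(bleached, 0, 100)$data, m8$data,
               tolerance = 1e-9)
  # constant image maps to zero by convention
  expect_true(all(map_dynamic_range(voxel_image(array(7, c(4, 4, 4))),
                                    1, 99)$data == 0))
  # monotone: voxelwise order preserved
  set.seed(1)
  img <- voxel_image(array(runif(512, 0, 65535), c(8, 8, 8)),
                     range = c(0, 65535))
  out <- map_dynamic_range(img, 5, 95)
  ord <- order(img$data)
  expect_true(all(diff(out$data[ord]) >= 0))
  expect_error(map_dynamic_range(img, 90, 10), "lo_pct")
})
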