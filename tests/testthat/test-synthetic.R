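test_that("simulate_surface_walk respects domain and is seed-reproducible", {
  cl <- cell_model("c", 3, 1)
  sw1 <- simulate_surface_walk(0.005, cl, dt = 0.1, n_steps = 20,
                               n_tracks = 10, seed = 7)
  sw2 <- simulate_surface_walk(0.005, cl, dt = 0.1, n_steps = 20,
                               n_tracks = 10, seed = 7)
  expect_equal(as.data.frame(sw1), as.data.frame(sw2))
  expect_true(all(sw1$theta >= 0 & sw1$theta < 2 * pi))
  expect_true(all(sw1$v_um >= 0 & sw1$v_um <= 3))
  expect_identical(nrow(sw1), 10L * 21L)
  expect_equal(attr(sw1, "d_true"), 0.005)
})

test_that("surface walk axial steps have the Brownian variance", {
  # long cell so reflecting ends are irrelevant
  cl <- cell_model("long", length = 20, diameter = 1)
  d_true <- 0.01; dt <- 0.1
  sw <- simulate_surface_walk(d_true, cl, dt = dt, n_steps = 50,
                              n_tracks = 400, seed = 8)
  dv <- unlist(lapply(split(sw$v_um, sw$track_id), diff), use.names = FALSE)
  expect_equal(var(dv), 2 * d_true * dt, tolerance = 0.05)
  expect_lt(abs(mean(dv)), 3 * sd(dv) / sqrt(length(dv)))
})

test_that("surface walk warns when the step rivals the curvature radius", {
  cl <- cell_model("c", 3, 1)
  expect_warning(simulate_surface_walk(1, cl, dt = 0.5, n_steps = 2,
                                       n_tracks = 2, seed = 1),
                 "curvature radius")
})

test_that("project_and_observe applies u = (d/2) sin(theta) and the cell pose", {
  cl <- cell_model("c", 3, 1, centroid_x = 2, centroid_y = -1,
                   orientation = 0.7)
  sw <- simulate_surface_walk(0.004, cl, dt = 0.1, n_steps = 10,
                              n_tracks = 5, seed = 9)
  ob <- project_and_observe(sw, cl, noise_sd = 0)
  cf <- to_cell_frame(ob, cl, tol = 0.01)
  expect_equal(cf$u_um, 0.5 * sin(sw$theta), tolerance = 1e-12)
  expect_equal(cf$v_um, sw$v_um - 1.5, tolerance = 1e-12)
  expect_true(all(abs(cf$u_um) <= 0.5 + 1e-12))
})

test_that("near_hemisphere mode drops the far side and splits tracks at gaps", {
  cl <- cell_model("c", 3, 1)
  sw <- simulate_surface_walk(0.02, cl, dt = 0.5, n_steps = 40,
                              n_tracks = 6, seed = 10)
  ob <- project_and_observe(sw, cl, noise_sd = 0, mode = "near_hemisphere")
  expect_lt(nrow(ob), nrow(sw))
  # every retained frame is on the visible hemisphere
  key_all <- paste(sw$track_id, sw$frame)
  vis <- cos(sw$theta) >= 0
  expect_true(all(paste(sub("\\..*$", "", ob$track_id), ob$frame)
                  %in% key_all[vis]))
  # frames are contiguous within each split track (it is a valid tracks object)
  expect_s3_class(ob, "tracks")
  for (p in split_tracks(ob)) expect_true(all(diff(p$frame) == 1))
})

test_that("bleach trace truth is consistent with the intensity trace", {
  tr <- simulate_bleach_trace(12, unit_intensity = 100, seed = 11)
  expect_s3_class(tr, "bleach_trace")
  expect_identical(tr$truth$n_subunits, 12)
  expect_identical(tr$truth$n_mature, 12L)
  # noiseless, no recruitment: staircase starts at n_alive(0) * unit and
  # never increases
  alive0 <- sum(tr$truth$bleach_times_s > 0)
  expect_equal(tr$intensity[1], 100 * alive0)
  expect_true(all(diff(tr$intensity) <= 0))
  expect_true(all(tr$intensity %% 100 == 0))
  # same seed reproduces
  tr2 <- simulate_bleach_trace(12, unit_intensity = 100, seed = 11)
  expect_equal(tr$intensity, tr2$intensity)
})

test_that("bleach trace recruitment and maturation options", {
  tr <- simulate_bleach_trace(5, p_recruit_per_frame = 0.05, seed = 12)
  expect_true(length(tr$truth$recruit_frames) > 0)
  expect_true(any(diff(tr$intensity) > 0))

  set.seed(13)
  n_mat <- vapply(1:50, function(i)
    simulate_bleach_trace(10, maturation_fraction = 0.5)$truth$n_mature,
    integer(1))
  expect_true(all(n_mat <= 10))
  expect_gt(mean(n_mat), 3)
  expect_lt(mean(n_mat), 7)

  bg <- simulate_bleach_trace(3, background = 50, bleach_rate = 10,
                              n_frames = 100, seed = 14)
  expect_equal(min(bg$intensity), 50)    # fully bleached trace sits at background
})

test_that("render_movie produces a calibrated stack with conserved photons", {
  tr <- as_tracks(data.frame(track_id = 1, frame = 0:2, t_s = 0:2,
                             x_um = c(1, 1.1, 1.2), y_um = 1))
  mv <- render_movie(tr, pixel_size_nm = 100, photons_per_focus = 2000,
                     background = 5, poisson = FALSE)
  expect_identical(length(dim(mv)), 3L)
  expect_identical(dim(mv)[3], 3L)
  expect_equal(attr(mv, "pixel_size_nm"), 100)
  fr1 <- mv[, , 1]
  expect_equal(sum(fr1 - 5), 2000, tolerance = 1e-6)
})

test_that("render_movie warns when foci leave the field of view", {
  tr <- as_tracks(data.frame(track_id = 1, frame = 0:1, t_s = 0:1,
                             x_um = c(1, -2), y_um = 1))
  expect_warning(render_movie(tr, fov_um = c(2, 2), poisson = FALSE),
                 "outside the field of view")
})

test_that("movie TIFF round-trip is exact for integer photon counts", {
  tr <- as_tracks(data.frame(track_id = 1, frame = 0:1, t_s = 0:1,
                             x_um = c(1, 1.1), y_um = 1))
  mv <- render_movie(tr, poisson = TRUE, seed = 15)
  p <- tempfile(fileext = ".tif")
  write_movie_tiff(mv, p)
  back <- read_movie_tiff(p, pixel_size_nm = attr(mv, "pixel_size_nm"))
  expect_equal(dim(back), dim(mv))
  expect_equal(max(abs(back - round(mv))), 0)
  unlink(p)
})

test_that("render_focus encodes the requested half-maximum width", {
  fi <- render_focus(90, pixel_size_nm = 10)
  expect_s3_class(fi, "focus_image")
  expect_equal(fi$truth_width50, c(90, 90))
  # direct check on the rendered profile: half-max width equals 90 nm
  prof <- fi$pixels[which.max(apply(fi$pixels, 1, max)), ]
  m <- profile_width50(fi)
  expect_equal(m$width50_nm, 90, tolerance = 0.01)
  expect_warning(render_focus(20, pixel_size_nm = 10), "unreliable")
  expect_error(render_focus(90, amplitude = 0), "positive")
})
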