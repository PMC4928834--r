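test_that("to_cell_frame / from_cell_frame are exact inverses", {
  set.seed(42)
  for (k in 1:5) {
    cl <- cell_model(paste0("c", k), length = 3, diameter = 1,
                     centroid_x = runif(1, -5, 5), centroid_y = runif(1, -5, 5),
                     orientation = runif(1, 0, pi))
    n <- 20
    u <- runif(n, -0.5, 0.5)
    v <- runif(n, -1.5, 1.5)
    lab <- as_tracks(data.frame(
      track_id = 1, frame = seq_len(n) - 1, t_s = seq_len(n) - 1,
      x_um = cl$centroid_x + v * cos(cl$orientation) - u * sin(cl$orientation),
      y_um = cl$centroid_y + v * sin(cl$orientation) + u * cos(cl$orientation)))
    cf <- to_cell_frame(lab, cl)
    expect_equal(cf$u_um, u, tolerance = 1e-12)
    expect_equal(cf$v_um, v, tolerance = 1e-12)
    back <- from_cell_frame(cf, cl)
    expect_equal(back$x_um, lab$x_um, tolerance = 1e-12)
    expect_equal(back$y_um, lab$y_um, tolerance = 1e-12)
  }
})

test_that("cell-frame axes follow the convention: v longitudinal, u transverse", {
  cl <- cell_model("c", 3, 1, 0, 0, orientation = 0)   # long axis along lab x
  tr <- as_tracks(data.frame(track_id = 1, frame = 0:1, t_s = 0:1,
                             x_um = c(0, 1), y_um = c(0, 0.2)))
  cf <- to_cell_frame(tr, cl)
  expect_equal(diff(cf$v_um), 1)     # motion along the cell axis is v ("y")
  expect_equal(diff(cf$u_um), 0.2)   # transverse motion is u ("x")
})

test_that("to_cell_frame refuses points outside the cell bounding box", {
  cl <- cell_model("cellA", 3, 1)
  tr <- as_tracks(data.frame(track_id = c("t1", "t2"), frame = 0, t_s = 0,
                             x_um = c(0.2, 4), y_um = 0))
  err <- tryCatch(to_cell_frame(tr, cl), error = conditionMessage)
  expect_match(err, "cellA")
  expect_match(err, "t2")
  expect_false(grepl("t1", err))
})

test_that("per_frame_mean drift correction removes common drift exactly", {
  # 4 static particles plus a shared nonlinear drift
  frames <- 0:9
  drift_x <- cumsum(c(0, 0.1 * sin(seq_len(9))))
  drift_y <- cumsum(c(0, rep(0.05, 9)))
  base_x <- c(0, 1, 2, 3)
  base_y <- c(0, 0.5, 1, 1.5)
  df <- do.call(rbind, lapply(1:4, function(i)
    data.frame(track_id = i, frame = frames, t_s = frames,
               x_um = base_x[i] + drift_x, y_um = base_y[i] + drift_y)))
  corr <- drift_correct(as_tracks(df))
  for (i in 1:4) {
    sub <- corr[corr$track_id == i, ]
    expect_equal(sub$x_um, rep(base_x[i], 10), tolerance = 1e-12)
    expect_equal(sub$y_um, rep(base_y[i], 10), tolerance = 1e-12)
  }
})

test_that("per_frame_mean with a single track warns and returns input", {
  tr <- make_brownian_tracks(1, 10, 0.01, 0.1, seed = 2)
  expect_warning(out <- drift_correct(tr), ">= 2 tracks")
  expect_equal(as.data.frame(out), as.data.frame(tr))
})

test_that("linear_fit drift correction removes constant-velocity drift", {
  frames <- 0:19
  tr <- as_tracks(data.frame(track_id = 1, frame = frames, t_s = frames,
                             x_um = 2 + 0.03 * frames,
                             y_um = 1 - 0.02 * frames))
  corr <- drift_correct(tr, mode = "linear_fit")
  expect_equal(corr$x_um, rep(2, 20), tolerance = 1e-12)
  expect_equal(corr$y_um, rep(1, 20), tolerance = 1e-12)
})

test_that("drift correction works in the cell frame too", {
  df <- do.call(rbind, lapply(1:3, function(i)
    data.frame(track_id = i, frame = 0:4, t_s = 0:4,
               u_um = i / 10 + 0.01 * (0:4), v_um = i / 5)))
  corr <- drift_correct(as_tracks(df, "cell"))
  expect_identical(track_coords(corr), "cell")
  d <- step_displacements(corr)
  expect_equal(as.numeric(tapply(d$d1, d$frame, mean)), rep(0, 4),
               tolerance = 1e-12)
})

test_that("cylinder_surface_area is pi * d * L and validates input", {
  expect_equal(cylinder_surface_area(3, 1), 3 * pi)
  expect_equal(cylinder_surface_area(2, 0.5), pi)
  expect_error(cylinder_surface_area(0, 1), "positive")
  expect_error(cylinder_surface_area(3, -1), "positive")
})

test_that("curvature correction factor and application", {
  expect_equal(curvature_correction_factor(), 1.35)
  expect_equal(curvature_correction_factor(anisotropy = 2, x_fraction = 0.5), 1.5)
  expect_equal(curvature_correction_factor(anisotropy = 1.7, x_fraction = 0), 1)
  expect_equal(apply_curvature_correction(0.01), 0.0135)
  expect_equal(apply_curvature_correction(c(0.01, 0.02)), c(0.0135, 0.027))
  expect_error(curvature_correction_factor(anisotropy = 0.5), ">= 1")
  expect_error(curvature_correction_factor(x_fraction = 1.2), "\\[0, 1\\]")
  expect_error(apply_curvature_correction(-1), ">= 0")
})

test_that("projection_anisotropy validates d_true", {
  expect_error(projection_anisotropy(0.5, 0, 0.1, seed = 1), "positive")
})
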