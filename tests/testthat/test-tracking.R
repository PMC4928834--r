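test_that("detect_spots finds a single rendered focus to sub-pixel accuracy", {
  tr <- as_tracks(data.frame(track_id = 1, frame = 0, t_s = 0,
                             x_um = 1.234, y_um = 0.876))
  mv <- render_movie(tr, pixel_size_nm = 100, psf_sigma_nm = 130,
                     photons_per_focus = 3000, background = 10,
                     poisson = FALSE, fov_um = c(2.5, 2))
  sp <- detect_spots(mv[, , 1], pixel_size_nm = 100)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$x_um - 1.234), 0.02)
  expect_lt(abs(sp$y_um - 0.876), 0.02)
  expect_gt(sp$intensity, 0)
  expect_gt(sp$quality, 5)
})

test_that("detect_spots returns no spots on featureless images", {
  expect_identical(nrow(detect_spots(matrix(7, 20, 20))), 0L)
  set.seed(16)
  noise_only <- matrix(rpois(400, 10), 20, 20)
  expect_identical(nrow(detect_spots(noise_only, threshold_snr = 8)), 0L)
})

test_that("detect_spots separates well-spaced foci under Poisson noise", {
  truth <- data.frame(x_um = c(0.8, 2.4), y_um = c(0.7, 1.6))
  tr <- as_tracks(cbind(data.frame(track_id = 1:2, frame = 0, t_s = 0), truth))
  mv <- render_movie(tr, photons_per_focus = 3000, poisson = TRUE,
                     fov_um = c(3.2, 2.4), seed = 17)
  sp <- detect_spots(mv[, , 1])
  expect_identical(nrow(sp), 2L)
  sp <- sp[order(sp$x_um), ]
  expect_lt(max(abs(sp$x_um - truth$x_um)), 0.05)
  expect_lt(max(abs(sp$y_um - truth$y_um)), 0.05)
})

test_that("link_tracks links nearest neighbours deterministically", {
  spots <- data.frame(
    frame = c(0, 0, 1, 1, 2, 2),
    x_um = c(0, 2, 0.1, 2.1, 0.2, 2.2),
    y_um = c(0, 0, 0, 0.1, 0, 0.2))
  tr <- link_tracks(spots, max_disp = 0.5)
  expect_s3_class(tr, "tracks")
  expect_identical(length(unique(tr$track_id)), 2L)
  pieces <- split_tracks(tr)
  xs <- sort(vapply(pieces, function(p) p$x_um[1], numeric(1)))
  expect_equal(unname(xs), c(0, 2))
  expect_true(all(vapply(pieces, nrow, integer(1)) == 3L))
})

test_that("link_tracks starts a new track beyond max_disp", {
  spots <- data.frame(frame = c(0, 1), x_um = c(0, 3), y_um = 0)
  tr <- link_tracks(spots, max_disp = 1)
  expect_identical(length(unique(tr$track_id)), 2L)
})

test_that("link_tracks bridges detection gaps up to max_gap", {
  spots <- data.frame(frame = c(0, 1, 3, 4), x_um = c(0, 0.1, 0.3, 0.4),
                      y_um = 0)
  no_gap <- link_tracks(spots, max_disp = 0.5, max_gap = 0)
  expect_identical(length(unique(no_gap$track_id)), 2L)
  with_gap <- link_tracks(spots, max_disp = 0.5, max_gap = 1)
  expect_identical(length(unique(with_gap$track_id)), 1L)
  expect_identical(with_gap$frame, c(0, 1, 3, 4))
})

test_that("link_tracks fills t_s from dt and keeps intensity", {
  spots <- data.frame(frame = 0:2, x_um = c(0, 0.1, 0.2), y_um = 0,
                      intensity = c(10, 11, 12))
  tr <- link_tracks(spots, max_disp = 0.5, dt = 0.25)
  expect_equal(tr$t_s, c(0, 0.25, 0.5))
  expect_equal(tr$intensity, c(10, 11, 12))
})

test_that("rendered movie round-trips through detection and linking", {
  set.seed(18)
  truth <- make_brownian_tracks(2, 10, 0.02, 0.1, seed = 18, coords = "lab")
  truth$x_um <- truth$x_um + rep(c(1, 3), each = 10)
  truth$y_um <- truth$y_um + 1.5
  mv <- render_movie(truth, photons_per_focus = 3000, poisson = TRUE,
                     fov_um = c(4.5, 3), seed = 19)
  sp <- detect_spots_movie(mv)
  tr <- link_tracks(sp, max_disp = 0.5, dt = 0.1)
  expect_identical(length(unique(tr$track_id)), 2L)
  expect_identical(nrow(tr), 20L)
  # localization errors stay small compared to the PSF
  err <- vapply(seq_len(nrow(tr)), function(i) {
    sel <- truth$frame == tr$frame[i]
    min(sqrt((truth$x_um[sel] - tr$x_um[i])^2 +
               (truth$y_um[sel] - tr$y_um[i])^2))
  }, numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("import_trackmate_xml applies the file calibration", {
  path <- write_trackmate_fixture()
  tr <- import_trackmate_xml(path)
  expect_s3_class(tr, "tracks")
  expect_identical(sort(unique(tr$track_id)), c("0", "1"))
  t0 <- tr[tr$track_id == "0", ]
  expect_identical(t0$frame, 0:2)
  expect_equal(t0$x_um, c(1.0, 1.1, 1.2))   # 10, 11, 12 px at 0.1 um/px
  expect_equal(t0$y_um, c(2.0, 2.1, 2.2))
  expect_equal(t0$t_s, c(0, 0.5, 1.0))      # timeinterval 0.5 s
  expect_identical(nrow(tr[tr$track_id == "1", ]), 2L)
  unlink(path)
})

test_that("import_trackmate_xml without calibration needs explicit fallback", {
  path <- write_trackmate_fixture(with_calibration = FALSE)
  expect_error(import_trackmate_xml(path), "calibration")
  tr <- import_trackmate_xml(path, pixel_size_um = 0.2, dt = 1)
  expect_equal(tr$x_um[tr$track_id == "0"], c(2.0, 2.2, 2.4))
  expect_equal(track_dt(tr), 1)
  unlink(path)
})
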