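test_that("msd_per_track is exact on a deterministic ballistic track", {
  n <- 6; c_step <- 0.3
  tr <- as_tracks(data.frame(track_id = 1, frame = 0:(n - 1),
                             t_s = (0:(n - 1)) * 0.5,
                             u_um = c_step * (0:(n - 1)), v_um = 0), "cell")
  cv <- msd_per_track(tr, axis = "xy")
  expect_equal(cv$delay_s, (1:5) * 0.5)
  expect_equal(cv$msd_um2, (c_step * (1:5))^2)   # all pairs at a lag are equal
  expect_equal(cv$weight, 5:1)                   # overlapping pair counts
  expect_identical(attr(cv, "axis"), "xy")
})

test_that("msd_per_track handles gaps and separates axes", {
  tr <- as_tracks(data.frame(track_id = 1, frame = c(0, 1, 3),
                             t_s = c(0, 1, 3),
                             u_um = c(0, 1, 2), v_um = c(0, 2, 4)), "cell")
  cvx <- msd_per_track(tr, axis = "x")
  expect_equal(cvx$delay_s, c(1, 2, 3))   # lag 1: 0->1; lag 2: 1->3; lag 3: 0->3
  expect_equal(cvx$msd_um2, c(1, 1, 4))
  expect_equal(cvx$weight, c(1, 1, 1))
  cvy <- msd_per_track(tr, axis = "y")
  expect_equal(cvy$msd_um2, c(4, 4, 16))
  expect_error(msd_per_track(make_brownian_tracks(2, 5, 0.01, 0.1), "xy"),
               "single track")
})

test_that("per-axis analysis refuses lab-frame tracks", {
  tr <- make_brownian_tracks(3, 5, 0.01, 0.1, coords = "lab")
  expect_error(msd_per_track(as_tracks(tr[tr$track_id == 1, ]), "x"),
               "cell-frame")
  expect_error(cve_diffusion(tr, "y"), "cell-frame")
  expect_error(per_axis_estimates(tr), "cell-frame")
})

test_that("ensemble_msd computes the weighted mean with pair-count weights", {
  mk <- function(msd, w) structure(
    data.frame(delay_s = 1, msd_um2 = msd, weight = w),
    class = c("msd_curve", "data.frame"), axis = "xy", dt = 1)
  ens <- ensemble_msd(list(mk(1, 9), mk(3, 1)))
  expect_equal(ens$msd_um2, (9 * 1 + 1 * 3) / 10)
  expect_equal(ens$weight, 10)
  expect_error(ensemble_msd(list()), "no MSD curves")
})

test_that("fit_msd_diffusion inverts an exact linear MSD curve", {
  D <- 0.007; sigma2 <- 0.004
  cv <- structure(data.frame(delay_s = (1:5) * 0.1,
                             msd_um2 = 4 * D * (1:5) * 0.1 + 4 * sigma2,
                             weight = c(50, 40, 30, 20, 10)),
                  class = c("msd_curve", "data.frame"), axis = "xy", dt = 0.1)
  fit <- fit_msd_diffusion(cv, n_points = 3)
  expect_equal(fit$D, D, tolerance = 1e-10)
  expect_equal(fit$intercept, 4 * sigma2, tolerance = 1e-10)
  expect_identical(fit$method, "msd_fit")
  # single-axis curves use slope / 2
  cv1 <- structure(data.frame(delay_s = (1:3) * 0.1,
                              msd_um2 = 2 * D * (1:3) * 0.1,
                              weight = 10),
                   class = c("msd_curve", "data.frame"), axis = "y", dt = 0.1)
  expect_equal(fit_msd_diffusion(cv1)$D, D, tolerance = 1e-10)
  expect_error(fit_msd_diffusion(cv, n_points = 1), ">= 2")
  expect_error(fit_msd_diffusion(cv1, n_points = 5), "need")
})

test_that("plain CVE matches the hand-computed variance", {
  # one track, known displacements
  u <- c(0, 0.1, 0.1, 0.3)
  v <- c(0, -0.1, 0.1, 0.1)
  tr <- as_tracks(data.frame(track_id = 1, frame = 0:3, t_s = (0:3) * 0.5,
                             u_um = u, v_um = v), "cell")
  est <- cve_diffusion(tr, "x")
  expect_equal(est$D, var(diff(u)) / (2 * 0.5))
  est_xy <- cve_diffusion(tr, "xy")
  expect_equal(est_xy$D, (var(diff(u)) + var(diff(v))) / 2 / (2 * 0.5))
  expect_identical(est$n_displacements, 3L)
})

test_that("noise-corrected CVE matches its formula and may go negative", {
  # pure localization noise on a static particle: plain CVE sees sigma^2/dt,
  # the corrected estimator cancels it (and can scatter below zero)
  tr <- make_brownian_tracks(300, 10, d_true = 0, dt = 0.1,
                             noise_sd = 0.05, seed = 21)
  plain <- cve_diffusion(tr, "xy")
  corr <- cve_diffusion(tr, "xy", noise_corrected = TRUE)
  expect_gt(plain$D, 0.02)                  # ~ sigma^2/dt = 0.025
  expect_lt(abs(corr$D), 0.002)             # unbiased around 0
  # formula check on one axis of one track
  one <- as_tracks(as.data.frame(tr)[tr$track_id == 1, ], "cell")
  d <- diff(one$u_um)
  expected <- mean(d^2) / (2 * 0.1) + mean(d[-length(d)] * d[-1]) / 0.1
  expect_equal(cve_diffusion(one, "x", noise_corrected = TRUE)$D, expected)
})

test_that("per_axis_estimates recovers anisotropic diffusion", {
  # build cell-frame tracks with different D along u and v
  set.seed(22)
  n <- 2000; len <- 10; dt <- 0.1
  du <- matrix(rnorm(n * (len - 1), 0, sqrt(2 * 0.005 * dt)), n)
  dv <- matrix(rnorm(n * (len - 1), 0, sqrt(2 * 0.010 * dt)), n)
  df <- data.frame(track_id = rep(seq_len(n), each = len),
                   frame = rep(0:(len - 1), n),
                   t_s = rep(0:(len - 1), n) * dt,
                   u_um = as.vector(t(cbind(0, t(apply(du, 1, cumsum))))),
                   v_um = as.vector(t(cbind(0, t(apply(dv, 1, cumsum))))))
  tr <- as_tracks(df, "cell")
  for (m in c("cve", "msd_fit")) {
    est <- per_axis_estimates(tr, method = m)
    expect_equal(est$x$D, 0.005, tolerance = 0.05)
    expect_equal(est$y$D, 0.010, tolerance = 0.05)
    expect_identical(est$x$axis, "x")
    expect_identical(est$y$axis, "y")
  }
})

test_that("velocity_histogram bins displacements symmetrically about zero", {
  tr <- make_brownian_tracks(50, 10, 0.01, 0.1, seed = 23)
  vh <- velocity_histogram(tr, bin_width = 0.02)
  n_disp <- 50L * 9L
  expect_identical(sum(vh$counts_x), n_disp)
  expect_identical(sum(vh$counts_y), n_disp)
  expect_equal(vh$breaks, -rev(vh$breaks))
  expect_length(vh$d_x, n_disp)
  # a faster species has a visibly broader displacement distribution
  fast <- velocity_histogram(make_brownian_tracks(50, 10, 0.04, 0.1, seed = 24))
  expect_gt(sd(fast$d_x), sd(vh$d_x))
})

test_that("ecdf_of_tracks summarizes per-track estimates without clipping", {
  tr <- make_brownian_tracks(40, 12, 0.008, 0.1, noise_sd = 0.03, seed = 25)
  ec <- ecdf_of_tracks(tr, method = "cve_noise_corrected")
  expect_identical(ec$n_tracks, 40L)
  expect_equal(ec$d_values, sort(ec$d_values))
  expect_equal(ec$mean, mean(ec$d_values))
  expect_equal(ec$ecdf(max(ec$d_values)), 1)
  # short-track scatter of the corrected estimator produces negatives,
  # which must be kept
  expect_true(any(ec$d_values < 0))
  expect_error(ecdf_of_tracks(tr[tr$track_id == 1, ]), "at least 2 tracks")
})
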