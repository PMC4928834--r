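# Synthetic-data generators: every pipeline stage has a generator with
# known ground truth, so estimator correctness is testable end-to-end.

row_cumsum <- function(m) {
  if (ncol(m) == 1) m else t(apply(m, 1, cumsum))
}

reflect_interval <- function(x, lo, hi) {
  span <- hi - lo
  r <- (x - lo) %% (2 * span)
  lo + ifelse(r > span, 2 * span - r, r)
}

#' Simulate Brownian walks on a cylindrical cell surface
#'
#' Isotropic surface diffusion is simulated in unwrapped (arc, axial)
#' coordinates with Euler steps: per frame interval the arc displacement
#' `R * dtheta` and the axial displacement `dv` are drawn independently
#' from `N(0, 2 * d_true * dt)`.  The azimuth is wrapped to `[0, 2*pi)`
#' and the axial coordinate reflects at the cylinder ends (the polar caps
#' are excluded from the model).  Curvature corrections to the diffusion
#' operator are neglected, which is valid while the RMS step is small
#' compared to the radius; a warning is issued otherwise.
#'
#' @param d_true surface diffusion coefficient, um^2/s (>= 0).
#' @param cell a [cell_model()]; its diameter sets the radius and its
#'   length the reflecting axial range `[0, length]`.
#' @param dt frame interval, s.
#' @param n_steps steps per track (track length is `n_steps + 1`).
#' @param n_tracks number of tracks; starts uniform on the surface.
#' @param seed RNG seed; required so ground truth is reproducible.
#' @return A `surface_tracks` data frame with columns `track_id`, `frame`,
#'   `t_s`, `theta` (azimuth, radians) and `v_um` (axial position), plus
#'   attributes `d_true` and `cell`.
#' @examples
#' cl <- cell_model()
#' sw <- simulate_surface_walk(0.005, cl, dt = 1, n_steps = 10,
#'                             n_tracks = 3, seed = 1)
#' head(sw)
#' @export
simulate_surface_walk <- function(d_true, cell, dt, n_steps, n_tracks, seed) {
  stopifnot(inherits(cell, "cell_model"), d_true >= 0, dt > 0,
            n_steps >= 1, n_tracks >= 1)
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  R <- cell$diameter / 2
  if (d_true * dt > (cell$diameter / 4)^2)
    warning("RMS step is comparable to the curvature radius; ",
            "flat-surface Euler stepping is inaccurate at this dt")
  sd_step <- sqrt(2 * d_true * dt)
  theta0 <- stats::runif(n_tracks, 0, 2 * pi)
  v0 <- stats::runif(n_tracks, 0, cell$length)
  # increments: n_tracks x n_steps
  d_arc <- matrix(stats::rnorm(n_tracks * n_steps, 0, sd_step), n_tracks)
  d_v <- matrix(stats::rnorm(n_tracks * n_steps, 0, sd_step), n_tracks)
  theta <- (theta0 + cbind(0, row_cumsum(d_arc / R))) %% (2 * pi)
  v <- reflect_interval(v0 + cbind(0, row_cumsum(d_v)), 0, cell$length)
  nf <- n_steps + 1
  out <- data.frame(
    track_id = rep(seq_len(n_tracks), each = nf),
    frame = rep.int(0:n_steps, n_tracks),
    t_s = rep.int(0:n_steps, n_tracks) * dt,
    theta = as.vector(t(theta)),
    v_um = as.vector(t(v)))
  structure(out, class = c("surface_tracks", "data.frame"),
            d_true = d_true, cell = cell, dt = dt)
}

#' Project surface walks onto the image plane and add localization noise
#'
#' Emulates what a camera sees of motion on the membrane of a rod-shaped
#' cell: the azimuth collapses to the apparent transverse coordinate
#' `u = (d/2) * sin(theta)` while the axial coordinate is observed
#' faithfully — the source of the systematic transverse underestimation
#' that [apply_curvature_correction()] undoes.  The projected cell-frame
#' point (centred axially) is rotated and translated by the cell pose, and
#' independent Gaussian localization noise of SD `noise_sd` is added per
#' coordinate.
#'
#' In `near_hemisphere` mode only the camera-facing half of the cylinder is
#' visible: frames with `cos(theta) < 0` are dropped and tracks are split
#' at the resulting gaps into separate track ids.  The default observes the
#' full circumference, as epifluorescence integrates over depth.
#'
#' @param surface a `surface_tracks` data frame from
#'   [simulate_surface_walk()].
#' @param cell the [cell_model()] providing diameter, length and pose.
#' @param noise_sd localization noise SD per coordinate, micrometres.
#' @param mode `"full"` or `"near_hemisphere"`.
#' @param seed RNG seed for the noise draws.
#' @return A lab-frame `tracks` data frame.
#' @export
project_and_observe <- function(surface, cell, noise_sd = 0.03,
                                mode = c("full", "near_hemisphere"),
                                seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cell, "cell_model"), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(surface)
  if (mode == "near_hemisphere") {
    df <- df[cos(df$theta) >= 0, , drop = FALSE]
    if (nrow(df) == 0) stop("no visible frames in near_hemisphere mode")
    # split at dropped frames: new id per contiguous run
    runs <- unlist(lapply(split(df$frame, df$track_id), function(fr) {
      cumsum(c(1L, diff(fr) != 1L))
    }), use.names = FALSE)
    df$track_id <- paste0(df$track_id, ".", runs)
  }
  u <- (cell$diameter / 2) * sin(df$theta)
  vc <- df$v_um - cell$length / 2
  phi <- cell$orientation
  x <- cell$centroid_x + vc * cos(phi) - u * sin(phi)
  y <- cell$centroid_y + vc * sin(phi) + u * cos(phi)
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise_sd)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  as_tracks(data.frame(track_id = df$track_id, frame = df$frame,
                       t_s = df$t_s, x_um = x, y_um = y,
                       cell_id = cell$cell_id), "lab")
}

#' Simulate a stepwise photobleaching trace
#'
#' Each fluorophore in a focus bleaches irreversibly at an exponentially
#' distributed time, so the focus intensity decays as a descending
#' staircase with unit-height steps — the basis of subunit counting.
#' Optional recruitment adds one fluorescent molecule per frame with a
#' small probability, producing the positive intensity steps (regain of
#' fluorescence) seen in live-cell acquisitions.  A maturation fraction
#' below 1 makes a subset of subunits dark from the start, which is why
#' step counts are lower bounds on true stoichiometry.
#'
#' @param n_subunits true number of subunits (>= 1).
#' @param unit_intensity intensity of one chromophore, arbitrary units.
#' @param bleach_rate per-fluorophore bleach rate, 1/s.  The default
#'   1.2 /s lets ~12 fluorophores all bleach within roughly 100-150 frames
#'   at the 20 ms frame time typical of stream acquisitions.
#' @param dt frame interval, s (default 0.02).
#' @param n_frames trace length in frames (default 150).
#' @param noise_sd additive Gaussian noise SD, same units as intensity.
#' @param p_recruit_per_frame per-frame probability of recruiting one new
#'   fluorescent molecule.
#' @param maturation_fraction probability that an initial subunit carries a
#'   mature (fluorescent) chromophore.
#' @param background constant baseline added to the trace.
#' @param seed RNG seed.
#' @return A `bleach_trace`: list with `dt`, `intensity` (numeric vector),
#'   and `truth` (n_subunits, n_mature, unit_intensity, bleach_times_s,
#'   recruit_frames, background).
#' @export
simulate_bleach_trace <- function(n_subunits, unit_intensity = 100,
                                  bleach_rate = 1.2, dt = 0.02,
                                  n_frames = 150, noise_sd = 0,
                                  p_recruit_per_frame = 0,
                                  maturation_fraction = 1,
                                  background = 0, seed = NULL) {
  stopifnot(n_subunits >= 1, bleach_rate > 0, dt > 0, n_frames >= 10)
  if (!is.null(seed)) set.seed(seed)
  mature <- stats::runif(n_subunits) < maturation_fraction
  n_mature <- sum(mature)
  t_frames <- (seq_len(n_frames) - 1) * dt
  counts <- integer(n_frames)
  bleach_times <- stats::rexp(n_mature, bleach_rate)
  for (tb in bleach_times) counts <- counts + (t_frames < tb)
  recruit_frames <- which(stats::runif(n_frames) < p_recruit_per_frame)
  for (fr in recruit_frames) {
    tb <- t_frames[fr] + stats::rexp(1, bleach_rate)
    counts <- counts + (t_frames >= t_frames[fr] & t_frames < tb)
  }
  intensity <- unit_intensity * counts + background
  if (noise_sd > 0)
    intensity <- intensity + stats::rnorm(n_frames, 0, noise_sd)
  structure(list(
    dt = dt,
    intensity = intensity,
    truth = list(n_subunits = n_subunits, n_mature = n_mature,
                 unit_intensity = unit_intensity,
                 bleach_times_s = bleach_times,
                 recruit_frames = recruit_frames,
                 background = background)
  ), class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("<bleach_trace> %d frames at %.3g s, truth: %d subunits (%d mature), %d recruitment event(s)\n",
              length(x$intensity), x$dt, x$truth$n_subunits,
              x$truth$n_mature, length(x$truth$recruit_frames)))
  invisible(x)
}
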