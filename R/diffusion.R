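# Diffusion estimation from single-particle tracks: time-averaged and
# ensemble MSD curves with count weights, weighted linear fits restricted
# to the first few (least correlated) delay points, and the
# covariance/variance estimator on one-step displacements with an optional
# localization-noise correction.
#
# Axis convention (cell frame): axis "x" is the apparent transverse
# coordinate u (circumferential projection), axis "y" the longitudinal
# coordinate v.  1D estimates use MSD = 2*D*tau; pooled "xy" estimates use
# MSD = 4*D*tau.

axis_columns <- function(tracks, axis) {
  co <- track_coords(tracks)
  if (axis %in% c("x", "y") && co != "cell")
    stop("per-axis analysis (axis = '", axis,
         "') requires cell-frame tracks; run to_cell_frame() first")
  cols <- coord_cols(tracks)
  switch(axis, x = cols[1], y = cols[2], xy = cols)
}

#' Construct a diffusion estimate record
#'
#' Container for a diffusion coefficient together with how it was obtained:
#' the estimator (`msd_fit`, `cve` or `cve_noise_corrected`), the axis it
#' refers to (`xy` pooled 2D, or cell-frame `x` / `y`), and sample sizes.
#' Covariance-based estimates may legitimately be negative on short
#' tracks — that is statistical scatter of an unbiased estimator, and such
#' values are preserved, never clipped.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param method estimator tag.
#' @param axis axis tag.
#' @param n_tracks,n_displacements sample sizes.
#' @param stderr approximate standard error, um^2/s (NA if not available).
#' @param intercept MSD-fit intercept, um^2 (localization-noise proxy).
#' @return Object of class `diffusion_estimate`.
#' @export
diffusion_estimate <- function(D, method, axis, n_tracks = NA_integer_,
                               n_displacements = NA_integer_,
                               stderr = NA_real_, intercept = NA_real_) {
  method <- match.arg(method, c("msd_fit", "cve", "cve_noise_corrected"))
  axis <- match.arg(axis, c("xy", "x", "y"))
  structure(list(D = D, method = method, axis = axis, n_tracks = n_tracks,
                 n_displacements = n_displacements, stderr = stderr,
                 intercept = intercept),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4g um^2/s (%s, axis %s, %s tracks, %s displacements)\n",
              x$D, x$method, x$axis,
              ifelse(is.na(x$n_tracks), "?", x$n_tracks),
              ifelse(is.na(x$n_displacements), "?", x$n_displacements)))
  invisible(x)
}

#' Time-averaged MSD curve of a single track
#'
#' For each delay `k * dt` the mean squared displacement is averaged over
#' all pairs of localizations that many frames apart (overlapping pairs);
#' the number of pairs is kept as the weight for downstream ensemble
#' averaging and fitting.  `axis = "x"` uses only the transverse cell
#' coordinate u, `"y"` only the longitudinal v (both require a cell-frame
#' track); `"xy"` sums the squared displacements of both coordinates.
#'
#' @param track a `tracks` data frame holding one track (extra tracks are
#'   an error).
#' @param axis `"xy"`, `"x"` or `"y"`.
#' @return An `msd_curve` data frame: `delay_s`, `msd_um2`, `weight`.
#' @export
msd_per_track <- function(track, axis = c("xy", "x", "y")) {
  axis <- match.arg(axis)
  if (length(unique(track$track_id)) != 1)
    stop("msd_per_track expects a single track; see ensemble_msd_tracks()")
  if (nrow(track) < 2) stop("need at least 2 points")
  cols <- axis_columns(track, axis)
  dt <- track_dt(track)
  xy <- as.matrix(as.data.frame(track)[, cols, drop = FALSE])
  out <- msd_core(track$frame, xy, dt)
  structure(out, class = c("msd_curve", "data.frame"), axis = axis, dt = dt)
}

msd_core <- function(fr, xy, dt) {
  # time-averaged MSD over all overlapping pairs, one row per frame lag
  lags <- seq_len(max(fr) - min(fr))
  dl <- ms <- numeric(length(lags))
  wt <- integer(length(lags))
  n_out <- 0L
  for (k in lags) {
    i <- match(fr + k, fr)
    ok <- which(!is.na(i))
    if (length(ok) == 0) next
    sq <- rowSums((xy[i[ok], , drop = FALSE] - xy[ok, , drop = FALSE])^2)
    n_out <- n_out + 1L
    dl[n_out] <- k * dt
    ms[n_out] <- mean(sq)
    wt[n_out] <- length(sq)
  }
  keep <- seq_len(n_out)
  data.frame(delay_s = dl[keep], msd_um2 = ms[keep], weight = wt[keep])
}

#' Weighted ensemble mean of MSD curves
#'
#' Per delay, the ensemble MSD is the mean of the per-track values weighted
#' by their pair counts, so long tracks contribute proportionally to the
#' number of displacements they measured.  The uncertainty reported per
#' delay is the weighted standard deviation divided by the number of
#' degrees of freedom, with the degrees of freedom taken as the effective
#' sample size `(sum w)^2 / sum(w^2)` minus one.
#'
#' @param curves list of `msd_curve` data frames on a shared `dt` grid.
#' @return An `msd_curve` with columns `delay_s`, `msd_um2`, `weight`
#'   (summed pair counts) and `uncertainty_um2`.
#' @export
ensemble_msd <- function(curves) {
  if (length(curves) == 0) stop("no MSD curves supplied")
  dts <- vapply(curves, function(cv) attr(cv, "dt"), numeric(1))
  if (any(abs(dts - dts[1]) > 1e-9 * dts[1]))
    stop("curves do not share a common dt grid")
  all_df <- do.call(rbind, lapply(curves, as.data.frame))
  delays <- sort(unique(all_df$delay_s))
  res <- lapply(delays, function(d) {
    sel <- abs(all_df$delay_s - d) < 1e-12 + 1e-9 * d
    w <- all_df$weight[sel]
    m <- all_df$msd_um2[sel]
    wm <- sum(w * m) / sum(w)
    n_eff <- sum(w)^2 / sum(w^2)
    unc <- if (length(m) > 1 && n_eff > 1) {
      wsd <- sqrt(sum(w * (m - wm)^2) / sum(w) * n_eff / (n_eff - 1))
      wsd / (n_eff - 1)
    } else NA_real_
    data.frame(delay_s = d, msd_um2 = wm, weight = sum(w),
               uncertainty_um2 = unc)
  })
  out <- do.call(rbind, res)
  structure(out, class = c("msd_curve", "data.frame"),
            axis = attr(curves[[1]], "axis"), dt = dts[1])
}

#' @rdname ensemble_msd
#' @param tracks a multi-track `tracks` data frame.
#' @param axis axis tag, as in [msd_per_track()].
#' @param min_length minimum localizations per track.
#' @export
ensemble_msd_tracks <- function(tracks, axis = c("xy", "x", "y"),
                                min_length = 2) {
  axis <- match.arg(axis)
  cols <- axis_columns(tracks, axis)
  dt <- track_dt(tracks)
  xy <- as.matrix(as.data.frame(tracks)[, cols, drop = FALSE])
  idx <- split(seq_len(nrow(tracks)),
               factor(tracks$track_id, levels = unique(tracks$track_id)))
  idx <- idx[lengths(idx) >= max(2, min_length)]
  if (length(idx) == 0) stop("no tracks of sufficient length")
  curves <- lapply(idx, function(ii)
    structure(msd_core(tracks$frame[ii], xy[ii, , drop = FALSE], dt),
              class = c("msd_curve", "data.frame"), axis = axis, dt = dt))
  ensemble_msd(curves)
}

#' Diffusion coefficient from a weighted fit of the first MSD points
#'
#' Fits a weighted least-squares line through the first `n_points` delays
#' of an MSD curve (weights = pair counts).  Only the first few points are
#' used because successive MSD values of overlapping time averages are
#' strongly correlated, and the short-delay slope carries most of the
#' information; three points is the conventional choice.  The diffusion
#' coefficient is `slope / 4` for pooled 2D curves and `slope / 2` for
#' single-axis curves; the intercept is retained as a proxy for the
#' localization-noise floor.
#'
#' @param curve an `msd_curve`.
#' @param n_points number of leading delay points to fit (>= 2).
#' @param axis axis tag; defaults to the curve's own.
#' @return A [diffusion_estimate] with method `"msd_fit"`.
#' @export
fit_msd_diffusion <- function(curve, n_points = 3, axis = NULL) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (nrow(curve) < n_points)
    stop("curve has ", nrow(curve), " delays; need ", n_points)
  if (is.null(axis)) axis <- attr(curve, "axis")
  axis <- match.arg(axis, c("xy", "x", "y"))
  cv <- as.data.frame(curve)[seq_len(n_points), ]
  fit <- stats::lm(msd_um2 ~ delay_s, data = cv, weights = cv$weight)
  slope <- unname(stats::coef(fit)["delay_s"])
  # an exact linear curve makes summary.lm warn about a perfect fit;
  # the fit itself is still the right answer
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["delay_s", "Std. Error"]),
    error = function(e) NA_real_)
  div <- if (axis == "xy") 4 else 2
  diffusion_estimate(D = slope / div, method = "msd_fit", axis = axis,
                     n_displacements = sum(cv$weight),
                     stderr = se / div,
                     intercept = unname(stats::coef(fit)["(Intercept)"]))
}

#' Covariance/variance-based diffusion estimator
#'
#' Works on the one-step displacements of one track or, when several
#' tracks are supplied, on all their one-step displacements pooled
#' (displacements across gaps are excluded).  Two modes:
#'
#' * plain (`noise_corrected = FALSE`, default): per axis
#'   `D = var(displacement) / (2 * dt)` — the direct rearrangement of
#'   `var(v) = 2 D / dt` for instantaneous velocities.  Localization noise
#'   adds `sigma^2 / dt` of upward bias.
#' * noise-corrected: per axis
#'   `D = mean(d_n^2) / (2 * dt) + mean(d_n * d_(n+1)) / dt`, using the
#'   lag-1 covariance of consecutive displacements to cancel the
#'   localization-noise contribution; unbiased, and may return negative
#'   values on short tracks, which are preserved.
#'
#' For `axis = "xy"` the two per-axis estimates are averaged.
#'
#' @param tracks a `tracks` data frame (one or many tracks).
#' @param axis `"xy"`, `"x"` or `"y"` (cell frame required for x/y).
#' @param noise_corrected use the lag-1 covariance correction.
#' @return A [diffusion_estimate].
#' @export
cve_diffusion <- function(tracks, axis = c("xy", "x", "y"),
                          noise_corrected = FALSE) {
  axis <- match.arg(axis)
  cols <- axis_columns(tracks, axis)
  dt <- track_dt(tracks)
  disp <- step_displacements(tracks)
  if (nrow(disp) < 2) stop("need at least 2 one-step displacements")
  dmat <- cbind(disp$d1, disp$d2)
  colnames(dmat) <- coord_cols(tracks)
  use <- match(cols, colnames(dmat))
  per_axis <- vapply(use, function(j) {
    d <- dmat[, j]
    if (!noise_corrected) return(stats::var(d) / (2 * dt))
    # lag-1 products within the same track, consecutive frames only
    same <- disp$track_id[-nrow(disp)] == disp$track_id[-1] &
      disp$frame[-1] == disp$frame[-nrow(disp)] + 1L
    lag1 <- mean(d[-length(d)][same] * d[-1][same])
    mean(d^2) / (2 * dt) + lag1 / dt
  }, numeric(1))
  D <- mean(per_axis)
  n <- nrow(disp) * length(use)
  se <- if (!noise_corrected) {
    abs(D) * sqrt(2 / (n - 1))
  } else {
    # moment-based approximation, quadrature of the two term SEs
    d_all <- as.vector(dmat[, use])
    sqrt(stats::var(d_all^2) / n) / (2 * dt) * sqrt(2)
  }
  method <- if (noise_corrected) "cve_noise_corrected" else "cve"
  diffusion_estimate(D = D, method = method, axis = axis,
                     n_tracks = length(unique(tracks$track_id)),
                     n_displacements = nrow(disp), stderr = se)
}

#' Per-axis diffusion estimates of cell-frame tracks
#'
#' Applies the chosen estimator independently to the transverse (u, "x")
#' and longitudinal (v, "y") coordinate series, pooling information across
#' tracks: CVE modes pool one-step displacements, the MSD fit uses the
#' weighted ensemble MSD per axis.
#'
#' @param tracks cell-frame `tracks`.
#' @param method `"msd_fit"`, `"cve"` or `"cve_noise_corrected"`.
#' @param n_points leading MSD points for the fit.
#' @return List with elements `x` and `y`, each a [diffusion_estimate].
#' @export
per_axis_estimates <- function(tracks,
                               method = c("msd_fit", "cve",
                                          "cve_noise_corrected"),
                               n_points = 3) {
  method <- match.arg(method)
  if (track_coords(tracks) != "cell")
    stop("per_axis_estimates requires cell-frame tracks")
  one <- function(ax) {
    if (method == "msd_fit") {
      fit_msd_diffusion(ensemble_msd_tracks(tracks, ax), n_points = n_points)
    } else {
      cve_diffusion(tracks, ax, noise_corrected =
                      method == "cve_noise_corrected")
    }
  }
  list(x = one("x"), y = one("y"))
}

#' Instantaneous-velocity (one-step displacement) histograms
#'
#' Histograms of the signed one-step displacements along each coordinate
#' — the "instantaneous velocity" view of mobility.  For drift-free motion
#' both histograms are symmetric about zero; a faster species shows
#' visibly broader tails (larger variance, hence larger D).
#'
#' @param tracks a `tracks` data frame.
#' @param bin_width bin width in micrometres per frame interval.
#' @return A `velocity_histogram`: list with `breaks` (shared bin edges,
#'   symmetric about 0), `counts_x`, `counts_y` (transverse u and
#'   longitudinal v in cell frame; lab x and y otherwise), and the raw
#'   displacement vectors `d_x`, `d_y`.
#' @export
velocity_histogram <- function(tracks, bin_width = 0.02) {
  disp <- step_displacements(tracks)
  if (nrow(disp) < 1) stop("need at least one displacement")
  lim <- max(abs(c(disp$d1, disp$d2))) + bin_width
  breaks <- seq(-ceiling(lim / bin_width) * bin_width,
                ceiling(lim / bin_width) * bin_width, by = bin_width)
  h1 <- graphics::hist(disp$d1, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(disp$d2, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, counts_x = h1$counts, counts_y = h2$counts,
                 d_x = disp$d1, d_y = disp$d2,
                 coords = track_coords(tracks)),
            class = "velocity_histogram")
}

#' @export
print.velocity_histogram <- function(x, ...) {
  cat(sprintf("<velocity_histogram> %d displacements, sd_x = %.4g um, sd_y = %.4g um\n",
              length(x$d_x), stats::sd(x$d_x), stats::sd(x$d_y)))
  invisible(x)
}

#' Empirical cumulative distribution of per-track diffusion coefficients
#'
#' Estimates D for every track individually (default: plain CVE) and
#' returns the empirical cumulative distribution together with its
#' arithmetic mean.  Negative per-track values — expected statistical
#' scatter of covariance-based estimators on short tracks — are included,
#' not discarded.  A slowly diffusing species shows a steep rise of the
#' ECDF at small coefficients.
#'
#' @param tracks a `tracks` data frame with at least 2 tracks.
#' @param method per-track estimator.
#' @param axis axis tag.
#' @param min_length minimum localizations per track (default 5: shorter
#'   tracks inflate estimator variance).
#' @return List of class `track_ecdf`: `d_values` (sorted), `ecdf`
#'   (a [stats::ecdf] function), `mean`, `n_tracks`, `method`.
#' @export
ecdf_of_tracks <- function(tracks, method = c("cve", "cve_noise_corrected",
                                              "msd_fit"),
                           axis = "xy", min_length = 5) {
  method <- match.arg(method)
  pieces <- split_tracks(tracks)
  pieces <- pieces[vapply(pieces, nrow, integer(1)) >= max(3, min_length)]
  if (length(pieces) < 2) stop("need at least 2 tracks of sufficient length")
  co <- track_coords(tracks)
  dv <- vapply(pieces, function(p) {
    tr <- as_tracks(p, co)
    if (method == "msd_fit")
      fit_msd_diffusion(msd_per_track(tr, axis), n_points =
                          min(3, nrow(p) - 1))$D
    else
      cve_diffusion(tr, axis, noise_corrected =
                      method == "cve_noise_corrected")$D
  }, numeric(1))
  dv <- sort(unname(dv))
  structure(list(d_values = dv, ecdf = stats::ecdf(dv), mean = mean(dv),
                 n_tracks = length(dv), method = method),
            class = "track_ecdf")
}

#' @export
print.track_ecdf <- function(x, ...) {
  cat(sprintf("<track_ecdf> %d tracks (%s), mean D = %.4g um^2/s, %d negative\n",
              x$n_tracks, x$method, x$mean, sum(x$d_values < 0)))
  invisible(x)
}
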