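# Focus size (50%-intensity width of a line profile) and dual-colour
# colocalization scoring.

half_crossings <- function(profile, peak_idx, half_level) {
  # linear interpolation of the half-level crossing on each side of peak
  n <- length(profile)
  left <- NA_real_; right <- NA_real_
  for (i in seq(peak_idx, 2)) {
    if (profile[i - 1] <= half_level && profile[i] >= half_level) {
      left <- (i - 1) + (half_level - profile[i - 1]) /
        (profile[i] - profile[i - 1])
      break
    }
  }
  for (i in seq(peak_idx, n - 1)) {
    if (profile[i + 1] <= half_level && profile[i] >= half_level) {
      right <- i + (profile[i] - half_level) /
        (profile[i] - profile[i + 1])
      break
    }
  }
  c(left, right)
}

measure_profile <- function(profile, pixel_size_nm) {
  n <- length(profile)
  n_tail <- max(2, round(0.1 * n))
  tails <- c(profile[seq_len(n_tail)], profile[(n - n_tail + 1):n])
  background <- stats::median(tails)
  noise <- stats::mad(tails)
  p <- profile - background
  peak_idx <- which.max(p)
  # parabolic refinement of the peak amplitude
  amp <- p[peak_idx]
  if (peak_idx > 1 && peak_idx < n) {
    y1 <- p[peak_idx - 1]; y2 <- p[peak_idx]; y3 <- p[peak_idx + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) amp <- y2 - (y1 - y3)^2 / (8 * den)
  }
  if (amp <= 2 * max(noise, .Machine$double.eps * abs(background)) ||
      amp <= 0) {
    return(list(ok = FALSE, reason = "peak below 2x background noise",
                width50_nm = NA_real_, peak = amp, background = background))
  }
  cr <- half_crossings(p, peak_idx, amp / 2)
  if (anyNA(cr)) {
    return(list(ok = FALSE, reason = "half-maximum crossing not found",
                width50_nm = NA_real_, peak = amp, background = background))
  }
  list(ok = TRUE, reason = NA_character_,
       width50_nm = (cr[2] - cr[1]) * pixel_size_nm,
       peak = amp, background = background)
}

#' Measure the 50%-intensity width of a fluorescent focus
#'
#' Extracts line profiles through the focus peak along the image axes,
#' subtracts a background estimated from the profile ends (median of the
#' outer ~20%), and measures the full width at 50% of the
#' background-subtracted peak by linear interpolation of the half-level
#' crossings.  For `axis = "both"` the x (along-row) and y (along-column)
#' widths are both measured; the mean width and the aspect ratio are
#' reported, since not all assemblies are perfectly round.
#'
#' A measurement is rejected (with `ok = FALSE` and a reason) when the
#' peak does not rise at least 2x above the background noise.
#'
#' @param image a `focus_image` (see [render_focus()]) or a numeric
#'   matrix; for a matrix, `pixel_size_nm` must be given.
#' @param center_guess optional `c(col, row)` pixel position near the
#'   focus; by default the image maximum.
#' @param axis `"both"`, `"x"` or `"y"`.
#' @param pixel_size_nm pixel size when `image` is a bare matrix.
#' @return Object of class `focus_measurement`: list with `ok`, `reason`,
#'   `width50_nm` (mean over measured axes), `width50_x_nm`,
#'   `width50_y_nm`, `aspect_ratio`, `peak`, `background`, `center_px`.
#' @export
profile_width50 <- function(image, center_guess = NULL,
                            axis = c("both", "x", "y"),
                            pixel_size_nm = NULL) {
  axis <- match.arg(axis)
  if (inherits(image, "focus_image")) {
    px <- image$pixel_size_nm
    img <- image$pixels
  } else {
    if (is.null(pixel_size_nm))
      stop("pixel_size_nm required for a bare matrix")
    px <- pixel_size_nm
    img <- image
  }
  stopifnot(is.matrix(img), nrow(img) >= 5, ncol(img) >= 5)
  if (is.null(center_guess)) {
    idx <- which(img == max(img), arr.ind = TRUE)[1, ]
  } else {
    half <- 3L
    rr <- max(1, round(center_guess[2]) - half):min(nrow(img), round(center_guess[2]) + half)
    cc <- max(1, round(center_guess[1]) - half):min(ncol(img), round(center_guess[1]) + half)
    sub <- img[rr, cc, drop = FALSE]
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    idx <- c(rr[w[1]], cc[w[2]])
  }
  mx <- if (axis %in% c("both", "x"))
    measure_profile(img[idx[1], ], px) else NULL
  my <- if (axis %in% c("both", "y"))
    measure_profile(img[, idx[2]], px) else NULL
  parts <- Filter(Negate(is.null), list(x = mx, y = my))
  bad <- !vapply(parts, `[[`, logical(1), "ok")
  if (any(bad)) {
    reason <- parts[[which(bad)[1]]]$reason
    return(structure(list(ok = FALSE, reason = reason, width50_nm = NA_real_,
                          width50_x_nm = NA_real_, width50_y_nm = NA_real_,
                          aspect_ratio = NA_real_,
                          peak = parts[[1]]$peak,
                          background = parts[[1]]$background,
                          center_px = unname(idx[c(2, 1)])),
                     class = "focus_measurement"))
  }
  wx <- if (is.null(mx)) NA_real_ else mx$width50_nm
  wy <- if (is.null(my)) NA_real_ else my$width50_nm
  ws <- c(wx, wy)
  structure(list(ok = TRUE, reason = NA_character_,
                 width50_nm = mean(ws, na.rm = TRUE),
                 width50_x_nm = wx, width50_y_nm = wy,
                 aspect_ratio = if (!anyNA(ws)) max(ws) / min(ws) else NA_real_,
                 peak = parts[[1]]$peak, background = parts[[1]]$background,
                 center_px = unname(idx[c(2, 1)])),
            class = "focus_measurement")
}

#' @export
print.focus_measurement <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<focus_measurement> width50 = %.1f nm (x %.1f, y %.1f; aspect %.2f)\n",
                x$width50_nm, x$width50_x_nm, x$width50_y_nm, x$aspect_ratio))
  else
    cat(sprintf("<focus_measurement> rejected: %s\n", x$reason))
  invisible(x)
}

#' Summary statistics of an ensemble of focus widths
#'
#' @param widths numeric vector of widths, nm.
#' @return Object of class `size_stats`: list with `mean_nm`, `sd_nm`
#'   (sample SD, n-1 denominator; 0 with `sd_defined = FALSE` for a single
#'   value) and `n`.
#' @export
size_stats <- function(widths) {
  widths <- widths[!is.na(widths)]
  if (length(widths) == 0) stop("no widths supplied")
  sd_def <- length(widths) > 1
  structure(list(mean_nm = mean(widths),
                 sd_nm = if (sd_def) stats::sd(widths) else 0,
                 sd_defined = sd_def, n = length(widths)),
            class = "size_stats")
}

#' @export
print.size_stats <- function(x, ...) {
  cat(sprintf("<size_stats> %.1f +/- %.1f nm (SD, n = %d)\n",
              x$mean_nm, x$sd_nm, x$n))
  invisible(x)
}

#' Colocalization fraction of two focus lists
#'
#' Fraction of channel-A foci that have a channel-B focus within `radius`,
#' matching each B focus at most once (candidate pairs are accepted
#' greedily by increasing distance).  With `mutual = TRUE` only mutual
#' nearest neighbours within the radius count, which makes the score
#' symmetric under swapping the channels.
#'
#' Visual "overlap" scoring has no intrinsic chance level; use
#' [colocalization_null()] for the fraction that random placement alone
#' would produce at the same densities.
#'
#' @param foci_a,foci_b data frames with `x_um`, `y_um` (or 2-column
#'   matrices), in the same frame of reference.
#' @param radius_nm match radius, nanometres (default 100, about one focus
#'   diameter).
#' @param mutual require mutual nearest neighbours.
#' @return Fraction in `[0, 1]` (0 if either list is empty).
#' @export
colocalization_fraction <- function(foci_a, foci_b, radius_nm = 100,
                                    mutual = FALSE) {
  a <- as_xy_matrix(foci_a)
  b <- as_xy_matrix(foci_b)
  if (nrow(a) == 0) return(0)
  if (nrow(b) == 0) return(0)
  r_um <- radius_nm / 1000
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  if (mutual) {
    hit <- vapply(seq_len(nrow(a)), function(i) {
      j <- which.min(d[i, ])
      d[i, j] <= r_um && which.min(d[, j]) == i
    }, logical(1))
    return(mean(hit))
  }
  cand <- which(d <= r_um, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_a <- rep(FALSE, nrow(a)); used_b <- rep(FALSE, nrow(b))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
  }
  mean(used_a)
}

as_xy_matrix <- function(f) {
  if (is.matrix(f)) {
    m <- f[, 1:2, drop = FALSE]
  } else {
    m <- cbind(f$x_um, f$y_um)
  }
  if (is.null(m) || any(dim(m) == 0)) m <- matrix(numeric(0), 0, 2)
  m
}

#' Chance-coincidence level for colocalization scoring
#'
#' Under a Poisson null (channel-B foci placed uniformly at random), the
#' probability that a given A focus has at least one B focus within the
#' match radius is `1 - exp(-n_b * pi * r^2 / area)`.  Comparing a measured
#' colocalization fraction to this value shows how much apparent overlap
#' chance alone produces at the observed densities.
#'
#' @param n_b number of channel-B foci on the surface.
#' @param area_um2 surface area, um^2.
#' @param radius_nm match radius, nm.
#' @return Expected chance fraction in `[0, 1]`.
#' @export
colocalization_null <- function(n_b, area_um2, radius_nm = 100) {
  stopifnot(n_b >= 0, area_um2 > 0)
  1 - exp(-n_b * pi * (radius_nm / 1000)^2 / area_um2)
}
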