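# Rendering of synthetic fluorescence images: movie stacks for the
# detection/linking stage and single-focus images for size measurement.
#
# Pixel convention used throughout: the image is a matrix indexed
# [row, col]; the centre of pixel (i, j) sits at physical position
# x = (j - 0.5) * pixel_size (columns) and y = (i - 0.5) * pixel_size
# (rows), measured from the image origin.

gaussian_spot <- function(nrow, ncol, x_px, y_px, sigma_px, total) {
  # separable normalized Gaussian; `total` is the summed intensity
  gx <- stats::dnorm(seq_len(ncol) - 0.5, x_px, sigma_px)
  gy <- stats::dnorm(seq_len(nrow) - 0.5, y_px, sigma_px)
  total * outer(gy, gx) / (sum(gy) * sum(gx) + .Machine$double.xmin)
}

#' Render tracks into a synthetic fluorescence movie
#'
#' Each focus is drawn as a 2D Gaussian of integrated intensity
#' `photons_per_focus` at its tracked position; a constant background is
#' added and, by default, per-pixel Poisson photon noise is applied.  The
#' stack is the ground-truth fixture for [detect_spots()] and
#' [link_tracks()].
#'
#' @param tracks a lab-frame `tracks` data frame; coordinates in
#'   micrometres relative to the field-of-view origin.
#' @param pixel_size_nm pixel size, nanometres.
#' @param psf_sigma_nm Gaussian PSF standard deviation, nanometres.
#' @param photons_per_focus integrated photons per focus per frame.
#' @param background mean background photons per pixel.
#' @param poisson apply Poisson noise (`TRUE`) or render noiselessly.
#' @param fov_um field of view `c(width, height)` in micrometres; by
#'   default the track bounding box plus a 5-sigma margin.
#' @param seed RNG seed for the photon noise.
#' @return A `movie_stack`: 3D array `[row, col, frame]` with attributes
#'   `pixel_size_nm` and `frames` (the frame numbers rendered).  Foci
#'   outside the field of view are clipped with a warning.
#' @export
render_movie <- function(tracks, pixel_size_nm = 100, psf_sigma_nm = 130,
                         photons_per_focus = 2000, background = 10,
                         poisson = TRUE, fov_um = NULL, seed = NULL) {
  stopifnot(pixel_size_nm > 0, psf_sigma_nm > 0)
  if (!is.null(seed)) set.seed(seed)
  px_um <- pixel_size_nm / 1000
  margin <- 5 * psf_sigma_nm / 1000
  if (is.null(fov_um))
    fov_um <- c(max(tracks$x_um) + margin, max(tracks$y_um) + margin)
  ncol_px <- max(4L, ceiling(fov_um[1] / px_um))
  nrow_px <- max(4L, ceiling(fov_um[2] / px_um))
  frames <- sort(unique(tracks$frame))
  stack <- array(0, dim = c(nrow_px, ncol_px, length(frames)))
  sigma_px <- psf_sigma_nm / pixel_size_nm
  clipped <- FALSE
  for (k in seq_along(frames)) {
    img <- matrix(background, nrow_px, ncol_px)
    sel <- tracks$frame == frames[k]
    xs <- tracks$x_um[sel] / px_um
    ys <- tracks$y_um[sel] / px_um
    out_of_fov <- xs < 0 | xs > ncol_px | ys < 0 | ys > nrow_px
    clipped <- clipped || any(out_of_fov)
    for (s in seq_along(xs)) {
      img <- img + gaussian_spot(nrow_px, ncol_px, xs[s], ys[s],
                                 sigma_px, photons_per_focus)
    }
    if (poisson) img <- matrix(stats::rpois(length(img), img), nrow_px)
    stack[, , k] <- img
  }
  if (clipped) warning("some foci fell outside the field of view and were clipped")
  structure(stack, class = "movie_stack",
            pixel_size_nm = pixel_size_nm, frames = frames)
}

#' Write / read a movie stack as multi-page TIFF
#'
#' Photon counts are stored as 16-bit grayscale (rounded, clipped at
#' 65535), one page per frame — integer-valued stacks round-trip exactly.
#'
#' @param movie a `movie_stack` array.
#' @param path TIFF path.
#' @param pixel_size_nm pixel size to attach on reading.
#' @return `read_movie_tiff` returns a `movie_stack`.
#' @export
write_movie_tiff <- function(movie, path) {
  pages <- lapply(seq_len(dim(movie)[3]), function(k)
    pmin(round(movie[, , k]), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, pixel_size_nm) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- round(pages[[k]] * 65535)
  structure(stack, class = "movie_stack", pixel_size_nm = pixel_size_nm,
            frames = seq_along(pages) - 1L)
}

#' Render a single fluorescent focus of known half-maximum width
#'
#' Draws an isotropic (or, if `width50_y` is given, elliptical) Gaussian
#' spot whose full width at 50% of peak intensity equals `width50`
#' (`sigma = width50 / (2 * sqrt(2 * log(2)))`), on a constant background
#' with optional Gaussian noise.  Ground truth is recorded so measurement
#' accuracy ([profile_width50()]) is testable.
#'
#' @param width50 target 50%-intensity full width along x, nanometres.
#' @param pixel_size_nm pixel size, nanometres; should be at most a third
#'   of the width for a meaningful measurement (warned otherwise).
#' @param amplitude peak intensity above background, arbitrary units.
#' @param background constant baseline.
#' @param noise_sd additive Gaussian noise SD.
#' @param width50_y optional width along y for an elliptical focus;
#'   defaults to `width50`.
#' @param center_offset_px subpixel offset `c(x, y)` of the spot centre
#'   from the image centre, in pixels.
#' @param seed RNG seed.
#' @return A `focus_image`: list with `pixel_size_nm`, `pixels` (matrix)
#'   and `truth_width50` (length-2 vector, x then y).
#' @export
render_focus <- function(width50, pixel_size_nm = 10, amplitude = 1000,
                         background = 100, noise_sd = 0, width50_y = NULL,
                         center_offset_px = c(0, 0), seed = NULL) {
  stopifnot(width50 > 0, pixel_size_nm > 0)
  if (amplitude <= 0) stop("amplitude must be positive")
  if (pixel_size_nm > width50 / 3)
    warning("pixel size coarser than width50/3; width measurement will be unreliable")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(width50_y)) width50_y <- width50
  sx <- width50 / (2 * sqrt(2 * log(2))) / pixel_size_nm
  sy <- width50_y / (2 * sqrt(2 * log(2))) / pixel_size_nm
  half <- ceiling(4 * max(sx, sy)) + 2
  n <- 2 * half + 1
  cx <- half + 0.5 + center_offset_px[1]
  cy <- half + 0.5 + center_offset_px[2]
  gx <- exp(-((seq_len(n) - 0.5 - cx)^2) / (2 * sx^2))
  gy <- exp(-((seq_len(n) - 0.5 - cy)^2) / (2 * sy^2))
  img <- background + amplitude * outer(gy, gx)
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  structure(list(pixel_size_nm = pixel_size_nm, pixels = img,
                 truth_width50 = c(width50, width50_y)),
            class = "focus_image")
}
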