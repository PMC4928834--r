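# Spot detection and frame-to-frame linking: a compact stand-in for the
# TrackMate step of the pipeline, adequate at the low focus densities
# (tens of foci per cell) typical of membrane microdomain imaging, plus an
# importer for real TrackMate XML exports.

#' Detect fluorescent spots in one image
#'
#' Band-pass filters the image with a difference of Gaussians (sigma and
#' 2*sigma, with sigma matched to the expected spot scale), finds local
#' maxima above a signal-to-noise threshold (noise estimated as the robust
#' MAD of the filtered image), and refines each maximum to sub-pixel
#' precision with an intensity-weighted centroid in a 5x5 window on the
#' background-subtracted raw image.
#'
#' @param image numeric matrix (one movie frame), photons per pixel.
#' @param pixel_size_nm pixel size, nanometres.
#' @param sigma_band_nm spot scale for the band-pass, nanometres; use
#'   roughly the PSF sigma.
#' @param threshold_snr minimum filtered-peak height in units of the
#'   filtered-image MAD.
#' @return Data frame of spots: `x_um`, `y_um`, `intensity` (background
#'   subtracted, summed over the 5x5 window), `quality` (peak SNR).
#'   Zero rows for an empty or featureless image.
#' @export
detect_spots <- function(image, pixel_size_nm = 100, sigma_band_nm = 130,
                         threshold_snr = 5) {
  stopifnot(is.matrix(image), pixel_size_nm > 0, sigma_band_nm > 0)
  if (length(image) == 0) return(empty_spots())
  if (max(image) > min(image)) {
    frac_at_max <- mean(image >= max(image) - .Machine$double.eps * max(image))
    if (frac_at_max > 0.01)
      warning("image looks saturated: >1% of pixels at the maximum value")
  }
  sigma_px <- sigma_band_nm / pixel_size_nm
  band <- EBImage::gblur(image, sigma = sigma_px) -
    EBImage::gblur(image, sigma = 2 * sigma_px)
  noise <- stats::mad(band)
  if (noise <= 0) return(empty_spots())
  nr <- nrow(band); nc <- ncol(band)
  # local maxima over the 8-neighbourhood, excluding a 2-px border
  is_max <- matrix(FALSE, nr, nc)
  ri <- 3:(nr - 2); ci <- 3:(nc - 2)
  if (length(ri) == 0 || length(ci) == 0) return(empty_spots())
  ctr <- band[ri, ci]
  ok <- ctr > threshold_snr * noise
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (ctr >= band[ri + dr, ci + dc])
  }
  is_max[ri, ci] <- ok
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_spots())
  bg <- stats::median(image)
  px_um <- pixel_size_nm / 1000
  out <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    win_r <- max(1, i - 2):min(nr, i + 2)
    win_c <- max(1, j - 2):min(nc, j + 2)
    w <- pmax(image[win_r, win_c] - bg, 0)
    if (sum(w) <= 0) return(NULL)
    ci_w <- sum(outer(rep(1, length(win_r)), win_c) * w) / sum(w)
    ri_w <- sum(outer(win_r, rep(1, length(win_c))) * w) / sum(w)
    data.frame(x_um = (ci_w - 0.5) * px_um, y_um = (ri_w - 0.5) * px_um,
               intensity = sum(w), quality = band[i, j] / noise)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_spots())
  rownames(out) <- NULL
  out
}

empty_spots <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0),
             intensity = numeric(0), quality = numeric(0))
}

#' Detect spots in every frame of a movie stack
#'
#' @param movie a `movie_stack` (see [render_movie()]).
#' @inheritParams detect_spots
#' @return Data frame of spots with a leading `frame` column.
#' @export
detect_spots_movie <- function(movie, sigma_band_nm = 130, threshold_snr = 5) {
  px <- attr(movie, "pixel_size_nm")
  frames <- attr(movie, "frames")
  if (is.null(frames)) frames <- seq_len(dim(movie)[3]) - 1L
  out <- lapply(seq_len(dim(movie)[3]), function(k) {
    sp <- detect_spots(movie[, , k], pixel_size_nm = px,
                       sigma_band_nm = sigma_band_nm,
                       threshold_snr = threshold_snr)
    if (nrow(sp) == 0) return(NULL)
    cbind(frame = frames[k], sp)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- cbind(frame = integer(0), empty_spots())
  rownames(out) <- NULL
  out
}

#' Link detected spots into trajectories
#'
#' Greedy nearest-neighbour linking: for each consecutive frame, candidate
#' links between open track ends and new spots are sorted by squared
#' distance and accepted greedily, rejecting links longer than `max_disp`.
#' Track ends may stay open across up to `max_gap` missed frames, so brief
#' detection dropouts do not split tracks (the spanned frames are simply
#' absent, flagged as gaps downstream).  The assignment is deterministic:
#' ties are broken by lowest spot index, then lowest track index.  Greedy
#' linking (rather than a global assignment) is adequate at microdomain
#' densities where foci are many PSF widths apart.
#'
#' @param spots data frame with `frame`, `x_um`, `y_um` and optionally
#'   `intensity` (as from [detect_spots_movie()]).
#' @param max_disp maximum link distance, micrometres.  Should be at least
#'   `3 * sqrt(4 * D * dt)` for the motion under study.
#' @param max_gap maximum number of consecutive missed frames to bridge.
#' @param dt frame interval in seconds, used to fill `t_s`.
#' @return A lab-frame `tracks` data frame.
#' @export
link_tracks <- function(spots, max_disp, max_gap = 0, dt = 1) {
  stopifnot(max_disp > 0, max_gap >= 0)
  if (nrow(spots) == 0)
    return(as_tracks(data.frame(track_id = integer(0), frame = integer(0),
                                t_s = numeric(0), x_um = numeric(0),
                                y_um = numeric(0)), "lab"))
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  # open track ends: id, last frame, last x, y
  ends <- data.frame(id = integer(0), frame = integer(0),
                     x = numeric(0), y = numeric(0))
  rows <- list()
  next_id <- 1L
  add_point <- function(id, frame, x, y, intensity) {
    rows[[length(rows) + 1L]] <<- data.frame(
      track_id = id, frame = frame, t_s = frame * dt,
      x_um = x, y_um = y,
      intensity = if (is.null(intensity)) NA_real_ else intensity)
  }
  for (f in frames) {
    sp <- spots[spots$frame == f, , drop = FALSE]
    open <- ends[ends$frame >= f - 1L - max_gap & ends$frame < f, , drop = FALSE]
    assigned_spot <- rep(FALSE, nrow(sp))
    assigned_end <- rep(FALSE, nrow(open))
    if (nrow(open) > 0 && nrow(sp) > 0) {
      cand <- expand.grid(s = seq_len(nrow(sp)), e = seq_len(nrow(open)))
      cand$d2 <- (sp$x_um[cand$s] - open$x[cand$e])^2 +
        (sp$y_um[cand$s] - open$y[cand$e])^2
      cand <- cand[cand$d2 <= max_disp^2, , drop = FALSE]
      cand <- cand[order(cand$d2, cand$s, cand$e), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        s <- cand$s[k]; e <- cand$e[k]
        if (assigned_spot[s] || assigned_end[e]) next
        assigned_spot[s] <- TRUE
        assigned_end[e] <- TRUE
        id <- open$id[e]
        add_point(id, f, sp$x_um[s], sp$y_um[s], sp$intensity[s])
        ends[ends$id == id, c("frame", "x", "y")] <-
          list(f, sp$x_um[s], sp$y_um[s])
      }
    }
    for (s in which(!assigned_spot)) {
      add_point(next_id, f, sp$x_um[s], sp$y_um[s], sp$intensity[s])
      ends <- rbind(ends, data.frame(id = next_id, frame = f,
                                     x = sp$x_um[s], y = sp$y_um[s]))
      next_id <- next_id + 1L
    }
  }
  df <- do.call(rbind, rows)
  if (all(is.na(df$intensity))) df$intensity <- NULL
  as_tracks(df, "lab")
}

#' Import trajectories from a TrackMate XML file
#'
#' Reads the spots and track edges of a TrackMate export and returns them
#' as a `tracks` data frame in physical units.  Spatial and temporal
#' calibration are taken from the file's `ImageData` element
#' (`pixelwidth`, `timeinterval`); when `spatialunits` is `"pixel"` the
#' stored positions are multiplied by the pixel width.  If the file lacks
#' calibration, explicit `pixel_size_um` and `dt` must be supplied.
#'
#' @param path path to the TrackMate XML file.
#' @param pixel_size_um,dt fallback calibration, used only when missing
#'   from the file.
#' @return A lab-frame `tracks` data frame; `track_id` is the TrackMate
#'   track id.
#' @export
import_trackmate_xml <- function(path, pixel_size_um = NULL, dt = NULL) {
  doc <- xml2::read_xml(path)
  img <- xml2::xml_find_first(doc, ".//ImageData")
  px <- NA_real_; dt_file <- NA_real_; units <- ""
  if (!inherits(img, "xml_missing")) {
    px <- as.numeric(xml2::xml_attr(img, "pixelwidth"))
    dt_file <- as.numeric(xml2::xml_attr(img, "timeinterval"))
    model <- xml2::xml_find_first(doc, ".//Model")
    units <- if (!inherits(model, "xml_missing"))
      xml2::xml_attr(model, "spatialunits") else xml2::xml_attr(doc, "spatialunits")
    if (is.na(units)) units <- ""
  }
  if (is.na(px)) {
    if (is.null(pixel_size_um))
      stop("TrackMate file has no spatial calibration; supply pixel_size_um")
    px <- pixel_size_um
    units <- "pixel"
  }
  if (is.na(dt_file)) {
    if (is.null(dt))
      stop("TrackMate file has no temporal calibration; supply dt")
    dt_file <- dt
  }
  scale <- if (identical(tolower(units), "pixel")) px else 1
  spot_nodes <- xml2::xml_find_all(doc, ".//Spot")
  if (length(spot_nodes) == 0) stop("no spots found in ", path)
  spots <- data.frame(
    id = xml2::xml_attr(spot_nodes, "ID"),
    frame = as.integer(xml2::xml_attr(spot_nodes, "FRAME")),
    x = as.numeric(xml2::xml_attr(spot_nodes, "POSITION_X")) * scale,
    y = as.numeric(xml2::xml_attr(spot_nodes, "POSITION_Y")) * scale,
    stringsAsFactors = FALSE)
  track_nodes <- xml2::xml_find_all(doc, ".//Track")
  out <- lapply(track_nodes, function(tn) {
    tid <- xml2::xml_attr(tn, "TRACK_ID")
    edges <- xml2::xml_find_all(tn, ".//Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    sp <- spots[spots$id %in% ids, , drop = FALSE]
    sp <- sp[order(sp$frame), , drop = FALSE]
    data.frame(track_id = tid, frame = sp$frame, t_s = sp$frame * dt_file,
               x_um = sp$x, y_um = sp$y, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df) || nrow(df) == 0) stop("no tracks found in ", path)
  as_tracks(df, "lab")
}
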