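#' Track tables
#'
#' Tracks are stored in long ("tidy") form: one row per localization, with
#' columns `track_id`, `frame`, `t_s` and either lab-frame coordinates
#' `x_um`, `y_um` or cell-frame coordinates `u_um` (apparent transverse,
#' the paper-convention "x") and `v_um` (along the long axis, "y").
#' Optional columns `intensity` and `cell_id` are carried through.
#' `as_tracks()` validates a data frame and tags its coordinate frame.
#'
#' Within each track, frames must be strictly increasing and `t_s` must be
#' `frame * dt` for one fixed positive `dt`.  Missing frames (gaps) are
#' permitted; estimators that use one-step displacements skip across them.
#'
#' @param df data frame with the columns above.
#' @param coords `"lab"` (columns `x_um`, `y_um`) or `"cell"`
#'   (columns `u_um`, `v_um`).
#' @return `df`, ordered by track and frame, with class `tracks` and
#'   attribute `coords`.
#' @examples
#' tr <- as_tracks(data.frame(track_id = 1, frame = 0:3, t_s = 0:3,
#'                            x_um = cumsum(rnorm(4, 0, .1)),
#'                            y_um = cumsum(rnorm(4, 0, .1))))
#' track_coords(tr)
#' @export
as_tracks <- function(df, coords = c("lab", "cell")) {
  coords <- match.arg(coords)
  cols <- if (coords == "lab") c("x_um", "y_um") else c("u_um", "v_um")
  need <- c("track_id", "frame", "t_s", cols)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("track table is missing columns: ", paste(missing, collapse = ", "))
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1) {
    same <- df$track_id[-1] == df$track_id[-nrow(df)]
    bad <- same & diff(df$frame) <= 0
    if (any(bad))
      stop("frames must be strictly increasing within each track; ",
           "offending track(s): ",
           paste(unique(df$track_id[-1][bad]), collapse = ", "))
  }
  structure(df, class = c("tracks", "data.frame"), coords = coords)
}

#' @rdname as_tracks
#' @param tracks a `tracks` object.
#' @export
track_coords <- function(tracks) {
  co <- attr(tracks, "coords")
  if (is.null(co)) co <- if ("u_um" %in% names(tracks)) "cell" else "lab"
  co
}

coord_cols <- function(tracks) {
  if (track_coords(tracks) == "cell") c("u_um", "v_um") else c("x_um", "y_um")
}

#' Split a track table into per-track data frames
#'
#' @param tracks a `tracks` data frame.
#' @return Named list of data frames, one per `track_id`, order preserved.
#' @export
split_tracks <- function(tracks) {
  split(as.data.frame(tracks), factor(tracks$track_id,
                                      levels = unique(tracks$track_id)))
}

#' Frame interval of a track table
#'
#' Returns the (common) frame interval `dt` in seconds, inferred from
#' consecutive `t_s` values.  Errors if the sampling is not uniform,
#' listing the offending frames; gaps of whole missed frames are fine.
#'
#' @param tracks a `tracks` data frame.
#' @param tol relative tolerance for uniformity.
#' @return dt in seconds.
#' @export
track_dt <- function(tracks, tol = 1e-6) {
  n <- nrow(tracks)
  same <- if (n > 1) tracks$track_id[-1] == tracks$track_id[-n] else logical(0)
  dts <- (diff(tracks$t_s) / diff(tracks$frame))[same]
  if (length(dts) == 0) stop("need at least one displacement to infer dt")
  dt <- stats::median(dts)
  off <- which(abs(dts - dt) > tol * dt)
  if (length(off) > 0)
    stop("non-uniform frame interval; offending displacement indices: ",
         paste(utils::head(off, 10), collapse = ", "))
  dt
}

#' One-step displacements of a track table
#'
#' Signed per-axis displacements between consecutive frames.  Pairs that
#' span a gap (frame difference > 1) are excluded, so one-step statistics
#' are never diluted by multi-frame jumps.
#'
#' @param tracks a `tracks` data frame.
#' @return Data frame with columns `track_id`, `frame` (of the first point
#'   of the pair), `d1`, `d2`: the two coordinate displacements in
#'   micrometres (`x`,`y` in lab frame; `u`,`v` in cell frame).
#' @export
step_displacements <- function(tracks) {
  cols <- coord_cols(tracks)
  n <- nrow(tracks)
  if (n < 2)
    return(data.frame(track_id = character(0), frame = integer(0),
                      d1 = numeric(0), d2 = numeric(0)))
  # rows are ordered by (track_id, frame) by construction, so consecutive
  # one-step pairs are adjacent rows of the same track one frame apart
  keep <- which(tracks$track_id[-1] == tracks$track_id[-n] &
                  diff(tracks$frame) == 1L)
  out <- data.frame(track_id = tracks$track_id[keep],
                    frame = tracks$frame[keep],
                    d1 = tracks[[cols[1]]][keep + 1L] - tracks[[cols[1]]][keep],
                    d2 = tracks[[cols[2]]][keep + 1L] - tracks[[cols[2]]][keep])
  rownames(out) <- NULL
  out
}

#' Read / write track CSV
#'
#' The track CSV schema is `track_id,frame,t_s,x_um,y_um[,intensity,cell_id]`
#' for lab-frame tracks and the same with `u_um,v_um` for cell-frame tracks
#' (v runs along the cell's long axis, u is the apparent transverse
#' coordinate).
#'
#' @param path CSV path.
#' @return For `read_tracks_csv`, a `tracks` data frame.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coords <- if ("u_um" %in% names(df)) "cell" else "lab"
  as_tracks(df, coords)
}

#' @rdname read_tracks_csv
#' @param tracks a `tracks` data frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Drop tracks shorter than a minimum length
#'
#' Diffusion estimators are noisy on very short tracks; the pipeline
#' default keeps tracks with at least 5 localizations.
#'
#' @param tracks a `tracks` data frame.
#' @param min_length minimum number of localizations.
#' @return Filtered `tracks`.
#' @export
filter_min_length <- function(tracks, min_length = 5) {
  n <- table(tracks$track_id)
  keep <- names(n)[n >= min_length]
  as_tracks(as.data.frame(tracks)[tracks$track_id %in% keep, , drop = FALSE],
            track_coords(tracks))
}
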