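#' Rod-shaped cell geometry
#'
#' A `cell_model` describes one rod-shaped cell as a cylinder seen in 2D
#' projection: its length and diameter, the lab-frame centroid, and the
#' orientation of the long axis relative to the lab x-axis.  It is the
#' reference geometry for cell-frame coordinate transforms
#' ([to_cell_frame()]) and for the membrane coverage / encounter model
#' ([encounter_model()]).
#'
#' @param cell_id identifier (character or integer).
#' @param length cell length in micrometres (cylindrical part, poles
#'   excluded); must be positive.
#' @param diameter cell diameter in micrometres; must be positive.
#' @param centroid_x,centroid_y lab-frame centroid in micrometres.
#' @param orientation angle of the long axis versus the lab x-axis, in
#'   radians.  Stored normalized to `[0, pi)` (a rod has no head or tail).
#'
#' @return An object of class `cell_model`: a list with fields `cell_id`,
#'   `length`, `diameter`, `centroid_x`, `centroid_y`, `orientation`.
#' @examples
#' cell_model("c1", length = 3, diameter = 1)
#' @export
cell_model <- function(cell_id = "cell", length = 3, diameter = 1,
                       centroid_x = 0, centroid_y = 0, orientation = 0) {
  stopifnot(is.numeric(length), length > 0,
            is.numeric(diameter), diameter > 0,
            is.finite(orientation))
  structure(list(
    cell_id = cell_id,
    length = as.numeric(length),
    diameter = as.numeric(diameter),
    centroid_x = as.numeric(centroid_x),
    centroid_y = as.numeric(centroid_y),
    orientation = orientation %% pi
  ), class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model> %s: L = %.3g um, d = %.3g um, centroid (%.3g, %.3g), orientation %.3g rad\n",
    x$cell_id, x$length, x$diameter, x$centroid_x, x$centroid_y, x$orientation))
  invisible(x)
}

#' Read a cell geometry table
#'
#' Reads a CSV with columns `cell_id, centroid_x_um, centroid_y_um,
#' length_um, diameter_um, orientation_rad` and returns a list of
#' [cell_model()] objects, named by `cell_id`.
#'
#' @param path path to the CSV file.
#' @return Named list of `cell_model` objects.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "centroid_x_um", "centroid_y_um",
            "length_um", "diameter_um", "orientation_rad")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("cell table is missing columns: ", paste(missing, collapse = ", "))
  cells <- lapply(seq_len(nrow(df)), function(i) {
    cell_model(df$cell_id[i], df$length_um[i], df$diameter_um[i],
               df$centroid_x_um[i], df$centroid_y_um[i], df$orientation_rad[i])
  })
  names(cells) <- df$cell_id
  cells
}

#' Write a cell geometry table
#'
#' @param cells a `cell_model` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  if (inherits(cells, "cell_model")) cells <- list(cells)
  df <- do.call(rbind, lapply(cells, function(cl) data.frame(
    cell_id = cl$cell_id, centroid_x_um = cl$centroid_x,
    centroid_y_um = cl$centroid_y, length_um = cl$length,
    diameter_um = cl$diameter, orientation_rad = cl$orientation)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
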