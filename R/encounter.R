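# Membrane coverage / encounter-time model: how long does a diffusing
# microdomain need to reach its nearest neighbour, given how much membrane
# each assembly has "for itself"?  A back-of-envelope chain —
# surface area -> area per assembly -> A / D — plus an independent
# Monte-Carlo first-passage oracle to check the heuristic's order of
# magnitude.

#' Total assemblies per cell from a one-sided focus count
#'
#' Focus counts from single-view images see one side of the cell; the
#' whole-cell total is twice the per-side mean, rounded to the nearest
#' integer (e.g. 12.3 per side -> 25, 8.6 -> 17).
#'
#' @param per_side_mean mean number of foci visible on one side (>= 0).
#' @return Integer total count.
#' @export
total_assemblies <- function(per_side_mean) {
  if (any(per_side_mean < 0)) stop("per_side_mean must be >= 0")
  as.integer(round(2 * per_side_mean))
}

#' Membrane area available per assembly
#'
#' Divides the (lateral) cell surface area equally among `n` assemblies
#' and reports both the area and the side of the equivalent square — the
#' characteristic distance an assembly must diffuse to reach its
#' neighbour's patch.
#'
#' @param surface_area lateral membrane area, um^2.
#' @param n number of assemblies (>= 1).
#' @return List with `area_um2` and `side_um`.
#' @examples
#' area_per_assembly(9, 25)  # 0.36 um^2, 0.6 um square
#' @export
area_per_assembly <- function(surface_area, n) {
  if (n < 1) stop("n must be >= 1")
  if (surface_area <= 0) stop("surface_area must be positive")
  area <- surface_area / n
  list(area_um2 = area, side_um = sqrt(area))
}

#' Heuristic encounter time of diffusing membrane assemblies
#'
#' The time for an assembly to traverse its private membrane patch — and
#' so, on average, to meet a neighbouring assembly or cover its share of
#' the surface — is estimated as `area / D`, the 2D diffusion time across
#' an area.  This is a deliberate order-of-magnitude heuristic: it is the
#' formula that ties the measured areas per assembly and corrected
#' diffusion coefficients into encounter times of tens of seconds (0.36
#' um^2 at 0.0084 um^2/s gives ~43 s; at 0.004 um^2/s, 90 s).  The
#' Monte-Carlo oracle [first_passage_oracle()] provides the independent
#' check that true mean first-passage times agree within a small factor.
#'
#' @param area_per_assembly membrane area per assembly, um^2.
#' @param D diffusion coefficient, um^2/s (> 0).
#' @return Time in seconds.
#' @export
encounter_time <- function(area_per_assembly, D) {
  if (any(D <= 0)) stop("D must be positive")
  if (any(area_per_assembly <= 0)) stop("area_per_assembly must be positive")
  area_per_assembly / D
}

#' Full encounter-model chain for one cell and one protein
#'
#' Runs the whole chain from geometry and focus counts to encounter time:
#' lateral surface area, total assemblies (2x per-side count), area and
#' square side per assembly, and `area / D`.
#'
#' @param length,diameter cell dimensions, micrometres.
#' @param per_side_foci mean focus count on one side of the cell.
#' @param D corrected diffusion coefficient, um^2/s.
#' @param area_override optionally use this area per assembly (um^2)
#'   instead of `surface/n` in the encounter time — e.g. to compare two
#'   proteins at a common reference area.
#' @return Object of class `encounter_model`: list with `surface_area_um2`,
#'   `n_assemblies`, `area_per_assembly_um2`, `side_length_um`, `D_um2_s`,
#'   `encounter_time_s`.
#' @examples
#' encounter_model(3, 1, per_side_foci = 12.3, D = 0.0084)
#' @export
encounter_model <- function(length = 3, diameter = 1, per_side_foci, D,
                            area_override = NULL) {
  sa <- cylinder_surface_area(length, diameter)
  n <- total_assemblies(per_side_foci)
  ap <- area_per_assembly(sa, n)
  area_used <- if (is.null(area_override)) ap$area_um2 else area_override
  structure(list(
    surface_area_um2 = sa,
    n_assemblies = n,
    area_per_assembly_um2 = ap$area_um2,
    side_length_um = ap$side_um,
    D_um2_s = D,
    encounter_time_s = encounter_time(area_used, D)
  ), class = "encounter_model")
}

#' @export
print.encounter_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<encounter_model>\n",
    "  surface area      %.3g um^2\n",
    "  assemblies        %d\n",
    "  area per assembly %.3g um^2 (square side %.2g um)\n",
    "  D                 %.3g um^2/s\n",
    "  encounter time    %.0f s\n"),
    x$surface_area_um2, x$n_assemblies, x$area_per_assembly_um2,
    x$side_length_um, x$D_um2_s, x$encounter_time_s))
  invisible(x)
}

#' Monte-Carlo first-passage oracle for the encounter heuristic
#'
#' Simulates a Brownian walker on a periodic rectangle (a torus — the
#' unwrapped membrane patch, or the whole unrolled cylinder surface when a
#' `cell` is given) and measures the mean time to first come within
#' `target_radius` of a fixed target at the domain centre, averaged over
#' uniform random start positions.  This is the brute-force check of the
#' `A / D` heuristic: 2D narrow-escape theory predicts
#' `(A / (2 pi D)) * ln(L / a)` plus an O(1) constant, the same order of
#' magnitude.
#'
#' Two start conditions are offered.  `"uniform"` (default) averages over
#' start positions uniform on the domain.  `"site"` starts every walker at
#' the point maximally distant from the target — the physical picture of
#' an assembly sitting at the centre of its own membrane patch with its
#' neighbours at the patch corners.  Uniform starts include positions
#' already close to the target and give shorter means.
#'
#' The time step is chosen so the RMS step is `target_radius / 3` unless
#' given explicitly; trials still outside the target at `max_time` are
#' censored at `max_time` (counted into the mean, reported in `censored`).
#'
#' @param D diffusion coefficient, um^2/s (> 0).
#' @param target_radius capture radius, um; must be small versus the
#'   domain.
#' @param n_trials number of independent walkers.
#' @param seed RNG seed.
#' @param domain `c(width, height)` of the periodic domain, um.
#' @param cell optional [cell_model()]; overrides `domain` with the
#'   unrolled cylinder `c(pi * diameter, length)`.
#' @param dt time step, s (default `(target_radius/3)^2 / (4 D)`).
#' @param max_time censoring horizon, s.
#' @param start `"uniform"` or `"site"` (see Details).
#' @return List: `mean_time_s`, `median_time_s`, `times` (per trial),
#'   `censored` (count), `dt`.
#' @export
first_passage_oracle <- function(D, target_radius, n_trials = 200, seed = 1,
                                 domain = c(0.6, 0.6), cell = NULL,
                                 dt = NULL, max_time = NULL,
                                 start = c("uniform", "site")) {
  start <- match.arg(start)
  stopifnot(D > 0, target_radius > 0, n_trials >= 1)
  if (!is.null(cell)) domain <- c(pi * cell$diameter, cell$length)
  if (target_radius >= min(domain) / 2)
    warning("target_radius is not small compared to the domain; ",
            "the A/D comparison is meaningless at this size")
  if (is.null(dt)) dt <- (target_radius / 3)^2 / (4 * D)
  if (is.null(max_time)) max_time <- 50 * prod(domain) / D
  set.seed(seed)
  sd_step <- sqrt(2 * D * dt)
  tx <- domain[1] / 2; ty <- domain[2] / 2
  if (start == "uniform") {
    x <- stats::runif(n_trials, 0, domain[1])
    y <- stats::runif(n_trials, 0, domain[2])
  } else {
    # maximally distant point on the torus: half a period away in both axes
    x <- rep((tx + domain[1] / 2) %% domain[1], n_trials)
    y <- rep((ty + domain[2] / 2) %% domain[2], n_trials)
  }
  times <- rep(NA_real_, n_trials)
  active <- seq_len(n_trials)
  wrap_dist <- function(p, tp, span) {
    d <- (p - tp + span / 2) %% span - span / 2
    d
  }
  n_steps <- ceiling(max_time / dt)
  r2 <- target_radius^2
  hit0 <- wrap_dist(x, tx, domain[1])^2 + wrap_dist(y, ty, domain[2])^2 <= r2
  times[active[hit0]] <- 0
  active <- active[!hit0]
  x <- x[!hit0]; y <- y[!hit0]
  for (step in seq_len(n_steps)) {
    if (length(active) == 0) break
    x <- (x + stats::rnorm(length(active), 0, sd_step)) %% domain[1]
    y <- (y + stats::rnorm(length(active), 0, sd_step)) %% domain[2]
    hit <- wrap_dist(x, tx, domain[1])^2 + wrap_dist(y, ty, domain[2])^2 <= r2
    if (any(hit)) {
      times[active[hit]] <- step * dt
      active <- active[!hit]
      x <- x[!hit]; y <- y[!hit]
    }
  }
  censored <- sum(is.na(times))
  times[is.na(times)] <- max_time
  list(mean_time_s = mean(times), median_time_s = stats::median(times),
       times = times, censored = censored, dt = dt)
}
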