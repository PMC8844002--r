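#' Sun/shade fractions of one path strip by ray casting
#'
#' Lays a square lattice of pitch `grid_step` over the strip polygon and
#' shoots one ray from every interior lattice-cell centre towards the sun. A
#' ray hitting a building extrusion counts the point as building shade; a ray
#' intersecting a tree-crown ellipsoid (and no building) counts it as tree
#' shade; otherwise the point is sun-lit. Building occlusion takes precedence
#' over tree occlusion: a building blocks the sun completely, a crown only
#' partially. The fractions are hit counts over total grid points, so they
#' sum to one exactly.
#'
#' @param scn A [scene()] providing the occluders.
#' @param strip An `n x 2` polygon matrix (local metric coordinates).
#' @param sun A [sun_position()] with `elevation > 0`.
#' @param grid_step Lattice pitch in metres (default 0.1).
#' @param strip_label Optional label used in error messages.
#' @return A [shade_fractions()] with attribute `n_rays`.
#' @examples
#' scn <- scene(1.35, 103.68)
#' strip <- cbind(c(0, 2, 2, 0), c(0, 0, 1.2, 1.2))
#' cast_fractions(scn, strip, sun_position(180, 60))
#' @export
cast_fractions <- function(scn, strip, sun, grid_step = 0.1,
                           strip_label = "strip") {
  stopifnot(inherits(scn, "scene"), inherits(sun, "sun_position"))
  if (sun$elevation <= 0)
    stop("sun at or below the horizon (elevation ", round(sun$elevation, 2),
         " deg): shading is undefined at night")
  if (!is.finite(grid_step) || grid_step <= 0)
    stop("grid_step must be a positive pitch in metres")
  strip <- check_polygon(strip, strip_label)
  pts <- .grid_points_cpp(strip, grid_step)
  if (nrow(pts) == 0L)
    stop(strip_label, ": no lattice points of pitch ", grid_step,
         " m fall inside the polygon; use a finer grid_step")
  footprints <- lapply(scn$buildings, `[[`, "footprint")
  heights <- vapply(scn$buildings, `[[`, 0, "height")
  trees <- as.matrix(scn$trees[, c("x", "y", "z", "rx", "rz")])
  code <- .cast_rays_cpp(pts, footprints, heights, trees, sun_direction(sun))
  n <- length(code)
  out <- shade_fractions(sum(code == 0L) / n, sum(code == 1L) / n,
                         sum(code == 2L) / n)
  attr(out, "n_rays") <- n
  out
}

#' Metric composition of a path option at a given sun position
#'
#' Runs the full per-option procedure: ray-cast every strip of the option,
#' keep the strip with the lowest sun fraction as representative, drop
#' insufficient building shade on wide paths (see
#' [apply_min_building_shade_rule()]), and convert the surviving fractions to
#' metric lengths along the option's centreline.
#'
#' @param scn A [scene()].
#' @param option_id Path-option id (a name of `scn$paths`).
#' @param sun A [sun_position()].
#' @param grid_step Lattice pitch in metres.
#' @param min_building_shade Threshold for the wide-path building-shade rule.
#' @return A [path_composition()] with attributes `fractions` (the
#'   representative [shade_fractions()] after the rule) and `strip` (index of
#'   the representative strip).
#' @export
path_option_composition <- function(scn, option_id, sun, grid_step = 0.1,
                                    min_building_shade = 0.15) {
  stopifnot(inherits(scn, "scene"))
  p <- scn$paths[[option_id]]
  if (is.null(p)) stop("unknown path option '", option_id, "'")
  fr <- lapply(seq_along(p$strips), function(s)
    cast_fractions(scn, p$strips[[s]], sun, grid_step,
                   strip_label = sprintf("path '%s' strip %d", option_id, s)))
  rep_fr <- representative_composition(fr)
  strip_idx <- attr(rep_fr, "strip")
  rep_fr <- apply_min_building_shade_rule(rep_fr, p$is_wide,
                                          threshold = min_building_shade)
  out <- compose_lengths(p$length, rep_fr)
  attr(out, "fractions") <- rep_fr
  attr(out, "strip") <- strip_idx
  out
}

#' Compositions of all path options at given instants
#'
#' Convenience wrapper chaining [solar_position()] and
#' [path_option_composition()] over decision timestamps.
#'
#' @param scn A [scene()].
#' @param instants Timezone-aware `POSIXct` vector of decision times.
#' @param option_ids Which options to evaluate (default: all in the scene).
#' @param ... Passed to [path_option_composition()].
#' @return A data frame with one row per (instant, option):
#'   `instant`, `option_id`, `a_sun`, `a_tree`, `a_shade`.
#' @export
scene_compositions <- function(scn, instants, option_ids = names(scn$paths),
                               ...) {
  stopifnot(inherits(scn, "scene"))
  rows <- list()
  for (i in seq_along(instants)) {
    sp <- solar_position(scn$site_latitude, scn$site_longitude, instants[i])
    sun <- sun_position(sp$azimuth, sp$elevation)
    for (id in option_ids) {
      cmp <- path_option_composition(scn, id, sun, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        instant = instants[i], option_id = id,
        a_sun = cmp$a_sun, a_tree = cmp$a_tree, a_shade = cmp$a_shade)
    }
  }
  do.call(rbind, rows)
}
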