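#' Build a 2.5D scene
#'
#' A scene holds everything the shading calculator needs: building footprints
#' extruded to their heights, tree crowns modelled as axis-aligned ellipsoids
#' (the simplest parametric convex hull of a crown), and the path-option
#' strips. Coordinates are a local metric east/north/up frame; polygons are
#' stored counter-clockwise (flipped on input if needed).
#'
#' Wide paths (6 m in the study area) are represented by parallel strips --
#' by convention 5 strips of 1.2 m -- and the constructor checks that wide
#' options carry exactly `wide_strip_count` strips.
#'
#' @param site_latitude,site_longitude Geographic site coordinates in degrees.
#' @param buildings List of `list(footprint = <n x 2 matrix>, height = <m>)`.
#' @param trees Data frame with columns `x`, `y`, `z` (crown centre, m),
#'   `rx` (horizontal semi-axis, m) and `rz` (vertical semi-axis, m).
#' @param paths Named list (names are path-option ids); each element is
#'   `list(strips = <list of n x 2 matrices>, length = <centreline m>,`
#'   `width = <m>, is_wide = <flag>)`.
#' @param wide_strip_count Required number of strips for a wide path.
#' @return An object of class `scene`.
#' @export
scene <- function(site_latitude, site_longitude, buildings = list(),
                  trees = NULL, paths = list(), wide_strip_count = 5L) {
  if (is.null(trees))
    trees <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                        rx = numeric(), rz = numeric())
  stopifnot(is.data.frame(trees),
            all(c("x", "y", "z", "rx", "rz") %in% names(trees)))
  if (nrow(trees) && any(trees$rx <= 0 | trees$rz <= 0))
    stop("tree crown semi-axes must be positive")

  buildings <- lapply(seq_along(buildings), function(i) {
    b <- buildings[[i]]
    if (!is.finite(b$height) || b$height <= 0)
      stop("building ", i, ": height must be positive")
    b$footprint <- check_polygon(b$footprint, sprintf("building %d footprint", i))
    b
  })

  if (length(paths)) {
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
      stop("paths must be a named list keyed by path-option id")
    path_ids <- names(paths)
    paths <- lapply(path_ids, function(id) {
      p <- paths[[id]]
      if (length(p$strips) < 1L)
        stop("path option '", id, "' has no strips")
      if (isTRUE(p$is_wide) && length(p$strips) != wide_strip_count)
        stop("wide path option '", id, "' must have exactly ", wide_strip_count,
             " strips (got ", length(p$strips), ")")
      if (!is.finite(p$length) || p$length <= 0)
        stop("path option '", id, "': centreline length must be positive")
      p$strips <- lapply(seq_along(p$strips), function(s)
        check_polygon(p$strips[[s]], sprintf("path '%s' strip %d", id, s)))
      p$is_wide <- isTRUE(p$is_wide)
      p
    })
    names(paths) <- path_ids
  }

  structure(list(site_latitude = site_latitude,
                 site_longitude = site_longitude,
                 buildings = buildings, trees = trees, paths = paths,
                 wide_strip_count = wide_strip_count),
            class = "scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a polygon matrix, drop a repeated closing vertex and force
# counter-clockwise orientation.
check_polygon <- function(poly, what) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3 || any(!is.finite(poly)))
    stop(what, ": polygon must be a finite n x 2 matrix with n >= 3 vertices")
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  a <- polygon_area(poly)
  if (abs(a) < 1e-9) stop(what, ": degenerate polygon (zero area)")
  if (a < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  unname(poly)
}

# Signed shoelace area; positive for counter-clockwise vertex order.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> site (%.4f, %.4f): %d building(s), %d tree(s), %d path option(s)\n",
    x$site_latitude, x$site_longitude, length(x$buildings), nrow(x$trees),
    length(x$paths)))
  invisible(x)
}

#' Read a scene from GeoJSON
#'
#' The file is a GeoJSON `FeatureCollection` in a local metric CRS with
#' top-level `properties` `site_latitude` and `site_longitude`. Features:
#' * buildings: `Polygon` with property `height_m`;
#' * trees: `Point` (x, y) with properties `crown_cx_m` (horizontal
#'   semi-axis), `crown_cz_m` (vertical semi-axis) and `crown_base_m`
#'   (height of the crown underside; the crown centre sits at
#'   `crown_base_m + crown_cz_m`);
#' * path strips: `Polygon` with properties `option_id`, `strip_index`
#'   (1-based), `is_wide`, `width_m` and `option_length_m`.
#'
#' @param path Path to a GeoJSON file.
#' @param wide_strip_count Passed through to [scene()].
#' @return A [scene()].
#' @export
read_scene_geojson <- function(path, wide_strip_count = 5L) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection in ", path)
  lat <- gj$properties$site_latitude
  lon <- gj$properties$site_longitude
  if (is.null(lat) || is.null(lon))
    stop("FeatureCollection properties must include site_latitude and site_longitude")

  buildings <- list()
  trees <- list()
  strips <- list()
  for (ft in gj$features) {
    pr <- ft$properties
    gt <- ft$geometry$type
    if (identical(gt, "Polygon") && !is.null(pr$height_m)) {
      ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]], unlist))
      buildings[[length(buildings) + 1L]] <-
        list(footprint = ring, height = pr$height_m)
    } else if (identical(gt, "Point") && !is.null(pr$crown_cx_m)) {
      xy <- unlist(ft$geometry$coordinates)
      trees[[length(trees) + 1L]] <- data.frame(
        x = xy[1], y = xy[2], z = pr$crown_base_m + pr$crown_cz_m,
        rx = pr$crown_cx_m, rz = pr$crown_cz_m)
    } else if (identical(gt, "Polygon") && !is.null(pr$option_id)) {
      ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]], unlist))
      strips[[length(strips) + 1L]] <- list(
        option_id = as.character(pr$option_id),
        strip_index = pr$strip_index, is_wide = isTRUE(pr$is_wide),
        width = pr$width_m, length = pr$option_length_m, poly = ring)
    } else {
      stop("unrecognised feature (type ", gt, "): not a building, tree or path strip")
    }
  }

  paths <- list()
  for (id in unique(vapply(strips, `[[`, "", "option_id"))) {
    ss <- Filter(function(s) s$option_id == id, strips)
    ord <- order(vapply(ss, function(s) as.numeric(s$strip_index), 0))
    ss <- ss[ord]
    paths[[id]] <- list(strips = lapply(ss, `[[`, "poly"),
                        length = ss[[1]]$length, width = ss[[1]]$width,
                        is_wide = ss[[1]]$is_wide)
  }
  trees <- if (length(trees)) do.call(rbind, trees) else NULL
  scene(lat, lon, buildings = buildings, trees = trees, paths = paths,
        wide_strip_count = wide_strip_count)
}

#' Write a scene to GeoJSON
#'
#' Inverse of [read_scene_geojson()].
#'
#' @param x A [scene()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene_geojson <- function(x, path) {
  stopifnot(inherits(x, "scene"))
  close_ring <- function(m) {
    m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  }
  feats <- list()
  for (b in x$buildings) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(height_m = b$height),
      geometry = list(type = "Polygon", coordinates = list(close_ring(b$footprint))))
  }
  for (i in seq_len(nrow(x$trees))) {
    tr <- x$trees[i, ]
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(crown_cx_m = tr$rx, crown_cz_m = tr$rz,
                        crown_base_m = tr$z - tr$rz),
      geometry = list(type = "Point", coordinates = c(tr$x, tr$y)))
  }
  for (id in names(x$paths)) {
    p <- x$paths[[id]]
    for (s in seq_along(p$strips)) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(option_id = id, strip_index = s, is_wide = p$is_wide,
                          width_m = p$width, option_length_m = p$length),
        geometry = list(type = "Polygon",
                        coordinates = list(close_ring(p$strips[[s]]))))
    }
  }
  gj <- list(type = "FeatureCollection",
             properties = list(site_latitude = x$site_latitude,
                               site_longitude = x$site_longitude),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
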