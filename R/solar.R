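#' Topocentric solar position
#'
#' Computes the sun's azimuth and elevation for a site and instant using the
#' NOAA solar-position equations (Meeus' abridged VSOP87 series as used by the
#' NOAA solar calculator). Accuracy is better than 0.5 degrees for years
#' 1950--2100, which is ample for shadow casting at the street scale.
#'
#' @param site_latitude Geographic latitude in degrees (north positive).
#' @param site_longitude Geographic longitude in degrees (east positive).
#' @param instant A timezone-aware `POSIXct` timestamp (vectorised). Timestamps
#'   without an explicit timezone are rejected: a naive clock time is ambiguous
#'   and would silently shift the sun by whole hours.
#' @param refraction Apply the NOAA atmospheric refraction correction to the
#'   elevation? Default `FALSE`: shadow geometry uses the geometric ray
#'   direction, and refraction only matters within a degree of the horizon.
#' @return A data frame with columns `azimuth` (degrees clockwise from north,
#'   in `[0, 360)`) and `elevation` (degrees above the horizon).
#' @examples
#' noon_sgt <- as.POSIXct("2019-03-21 13:07:00", tz = "Asia/Singapore")
#' solar_position(1.35, 103.68, noon_sgt)
#' @export
solar_position <- function(site_latitude, site_longitude, instant,
                           refraction = FALSE) {
  if (!is.finite(site_latitude) || abs(site_latitude) > 90)
    stop("site_latitude must be a latitude in [-90, 90] degrees")
  if (!is.finite(site_longitude) || abs(site_longitude) > 360)
    stop("site_longitude must be a longitude in degrees")
  if (!inherits(instant, "POSIXct"))
    stop("instant: expected a timezone-aware POSIXct timestamp")
  tz <- attr(instant, "tzone")
  if (is.null(tz) || identical(tz, ""))
    stop("instant: timezone-naive timestamp; attach an explicit timezone ",
         "(e.g. as.POSIXct(..., tz = \"Asia/Singapore\") or tz = \"UTC\")")
  yr <- as.POSIXlt(instant, tz = "UTC")$year + 1900L
  if (any(yr < 1950L | yr > 2100L))
    stop("instant: outside the supported range of years 1950-2100")

  d2r <- pi / 180
  jd <- as.numeric(instant) / 86400 + 2440587.5   # Unix epoch -> Julian day
  jc <- (jd - 2451545) / 36525                    # Julian century (J2000)

  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(M * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * M * d2r) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(obliq * d2r) * sin(app_long * d2r)) / d2r

  var_y <- tan(obliq / 2 * d2r)^2
  eq_time <- 4 / d2r * (var_y * sin(2 * L0 * d2r) - 2 * ecc * sin(M * d2r) +
    4 * ecc * var_y * sin(M * d2r) * cos(2 * L0 * d2r) -
    0.5 * var_y^2 * sin(4 * L0 * d2r) - 1.25 * ecc^2 * sin(2 * M * d2r))

  lt <- as.POSIXlt(instant, tz = "UTC")
  min_utc <- lt$hour * 60 + lt$min + lt$sec / 60
  tst <- (min_utc + eq_time + 4 * site_longitude) %% 1440
  ha <- tst / 4 - 180
  ha <- ifelse(ha < -180, ha + 360, ha)

  lat <- site_latitude * d2r
  cos_zen <- sin(lat) * sin(decl * d2r) + cos(lat) * cos(decl * d2r) * cos(ha * d2r)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen) / d2r
  elev <- 90 - zen

  az_arg <- (sin(lat) * cos_zen - sin(decl * d2r)) / (cos(lat) * sin(zen * d2r))
  az_arg <- pmin(1, pmax(-1, az_arg))
  az0 <- acos(az_arg) / d2r
  azimuth <- ifelse(ha > 0, (az0 + 180) %% 360, (540 - az0) %% 360)
  azimuth[zen < 1e-9 | zen > 180 - 1e-9] <- 0  # sun at zenith/nadir: azimuth degenerate

  if (refraction) {
    e <- elev
    r <- numeric(length(e))
    te <- tan(e * d2r)
    hi <- e > 5 & e <= 85
    lo <- e > -0.575 & e <= 5
    vlo <- e <= -0.575
    r[hi] <- 58.1 / te[hi] - 0.07 / te[hi]^3 + 0.000086 / te[hi]^5
    r[lo] <- 1735 + e[lo] * (-518.2 + e[lo] * (103.4 + e[lo] * (-12.79 + e[lo] * 0.711)))
    r[vlo] <- -20.772 / te[vlo]
    elev <- elev + r / 3600
  }

  data.frame(azimuth = azimuth, elevation = elev)
}

#' Sun position container
#'
#' Light validation wrapper for a (azimuth, elevation) pair used by the
#' shading routines.
#'
#' @param azimuth Degrees clockwise from north, in `[0, 360)`.
#' @param elevation Degrees above the horizon, in `[-90, 90]`.
#' @return An object of class `sun_position`.
#' @export
sun_position <- function(azimuth, elevation) {
  if (!is.finite(azimuth) || azimuth < 0 || azimuth >= 360)
    stop("azimuth must lie in [0, 360) degrees clockwise from north")
  if (!is.finite(elevation) || abs(elevation) > 90)
    stop("elevation must lie in [-90, 90] degrees")
  structure(list(azimuth = azimuth, elevation = elevation),
            class = "sun_position")
}

#' @export
print.sun_position <- function(x, ...) {
  cat(sprintf("<sun_position> azimuth %.2f deg, elevation %.2f deg\n",
              x$azimuth, x$elevation))
  invisible(x)
}

# Unit vector pointing from the ground towards the sun, in the local
# east/north/up frame (azimuth clockwise from north).
sun_direction <- function(sun) {
  stopifnot(inherits(sun, "sun_position"))
  az <- sun$azimuth * pi / 180
  el <- sun$elevation * pi / 180
  c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
}
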