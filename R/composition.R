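#' Sun/tree/building shade fractions of a path strip
#'
#' Container for the fractional decomposition of a path polygon into sun-lit,
#' tree-shaded and building-shaded area. Fractions must be non-negative and
#' sum to one.
#'
#' @param f_sun Fraction of the strip lit by direct sun.
#' @param f_tree Fraction shaded by tree crowns.
#' @param f_building Fraction shaded by building extrusions.
#' @return An object of class `shade_fractions` (a named list).
#' @examples
#' shade_fractions(0.5, 0.2, 0.3)
#' @export
shade_fractions <- function(f_sun, f_tree, f_building) {
  f <- c(f_sun = f_sun, f_tree = f_tree, f_building = f_building)
  if (any(!is.finite(f))) stop("shade fractions must be finite numbers")
  if (any(f < -1e-9)) stop("shade fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9)
    stop("shade fractions must sum to 1 (got ", format(sum(f), digits = 12), ")")
  structure(list(f_sun = f_sun, f_tree = f_tree, f_building = f_building),
            class = "shade_fractions")
}

#' @export
print.shade_fractions <- function(x, ...) {
  cat(sprintf("<shade_fractions> sun %.3f | tree %.3f | building %.3f\n",
              x$f_sun, x$f_tree, x$f_building))
  invisible(x)
}

#' Metric sun/shade composition of a path option
#'
#' Lengths (in metres) of the sun-lit, tree-shaded and building-shaded
#' stretches of one path option. All fields are vectorised so a single object
#' can hold the compositions of many options.
#'
#' @param a_sun Metres walked in direct sun.
#' @param a_tree Metres walked under tree shade.
#' @param a_shade Metres walked under building shade.
#' @return An object of class `path_composition`.
#' @examples
#' path_composition(50, 20, 30)
#' @export
path_composition <- function(a_sun, a_tree, a_shade) {
  n <- max(length(a_sun), length(a_tree), length(a_shade))
  a_sun <- rep_len(as.numeric(a_sun), n)
  a_tree <- rep_len(as.numeric(a_tree), n)
  a_shade <- rep_len(as.numeric(a_shade), n)
  if (any(!is.finite(c(a_sun, a_tree, a_shade))))
    stop("composition lengths must be finite")
  if (any(c(a_sun, a_tree, a_shade) < 0))
    stop("composition lengths must be non-negative")
  structure(list(a_sun = a_sun, a_tree = a_tree, a_shade = a_shade),
            class = "path_composition")
}

#' @export
print.path_composition <- function(x, ...) {
  n <- length(x$a_sun)
  cat(sprintf("<path_composition> %d option%s\n", n, if (n == 1) "" else "s"))
  print(data.frame(a_sun = x$a_sun, a_tree = x$a_tree, a_shade = x$a_shade,
                   total = total_length(x)))
  invisible(x)
}

#' @export
length.path_composition <- function(x) length(x$a_sun)

#' Total length of a path option
#'
#' @param option A [path_composition()].
#' @return Numeric vector of total lengths in metres.
#' @export
total_length <- function(option) {
  stopifnot(inherits(option, "path_composition"))
  option$a_sun + option$a_tree + option$a_shade
}

#' Pick the representative strip of a wide path
#'
#' Wide paths are decomposed into parallel strips; the strip with the lowest
#' sun fraction stands for the whole path option. Ties go to the
#' lowest-indexed strip.
#'
#' @param fractions_per_strip A list of [shade_fractions()], ordered by strip
#'   index.
#' @return The representative `shade_fractions`, with attribute `strip` giving
#'   its (1-based) index in the input.
#' @examples
#' representative_composition(list(
#'   shade_fractions(0.8, 0.1, 0.1),
#'   shade_fractions(0.2, 0.3, 0.5)
#' ))
#' @export
representative_composition <- function(fractions_per_strip) {
  if (length(fractions_per_strip) == 0)
    stop("fractions_per_strip is empty: a path option needs at least one strip")
  stopifnot(all(vapply(fractions_per_strip, inherits, TRUE, "shade_fractions")))
  f_sun <- vapply(fractions_per_strip, `[[`, 0, "f_sun")
  i <- which.min(f_sun)  # which.min returns the first minimum: the tie rule
  out <- fractions_per_strip[[i]]
  attr(out, "strip") <- i
  out
}

#' Drop insufficient building shade on wide paths
#'
#' Building shade narrower than a threshold fraction of a wide path (by
#' default 15%, i.e. under 0.9 m of a 6 m path) is treated as too thin to be
#' registered by a walker: its mass is reassigned to sun. The rule is strictly
#' "less than": a fraction exactly at the threshold is kept. Narrow paths are
#' never modified.
#'
#' @param fractions A [shade_fractions()].
#' @param path_is_wide Logical flag; the rule only applies to wide paths.
#' @param threshold Minimum building-shade fraction considered sufficient.
#' @return A `shade_fractions`, possibly with `f_building` zeroed.
#' @export
apply_min_building_shade_rule <- function(fractions, path_is_wide,
                                          threshold = 0.15) {
  stopifnot(inherits(fractions, "shade_fractions"),
            is.logical(path_is_wide), length(path_is_wide) == 1L)
  if (path_is_wide && fractions$f_building < threshold && fractions$f_building > 0) {
    fractions <- shade_fractions(fractions$f_sun + fractions$f_building,
                                 fractions$f_tree, 0)
  }
  fractions
}

#' Turn fractions into metric lengths
#'
#' Multiplies a path option's centreline length by its shade fractions to get
#' the metric sun/tree/building-shade decomposition.
#'
#' @param option_length Centreline length of the option in metres (> 0).
#' @param fractions A [shade_fractions()].
#' @return A [path_composition()] whose components sum to `option_length`.
#' @examples
#' compose_lengths(100, shade_fractions(0.5, 0.2, 0.3))
#' @export
compose_lengths <- function(option_length, fractions) {
  stopifnot(inherits(fractions, "shade_fractions"))
  if (!is.finite(option_length) || option_length <= 0)
    stop("option_length must be a positive length in metres")
  path_composition(option_length * fractions$f_sun,
                   option_length * fractions$f_tree,
                   option_length * fractions$f_building)
}
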