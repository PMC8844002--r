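#' Perceived cost of walking a path option
#'
#' The cost of a path option is its length with the sun-exposed part inflated
#' by the walker's sun-cost factor `beta`, and tree shade split between sun
#' and building shade according to the perceived tree-shade intensity `rho`:
#'
#' \deqn{c = \beta\,[a_{sun} + (1-\rho)\,a_{tree}] + a_{shade} + \rho\,a_{tree}}
#'
#' At `beta = 1` the cost collapses to the total length for every `rho`.
#' `beta > 1` means walking in the sun is perceived as costlier than the same
#' distance in the shade; `rho = 1` makes tree shade equivalent to building
#' shade and `rho = 0` makes it equivalent to full sun.
#'
#' @param option A [path_composition()] (fields may be vectors).
#' @param beta Positive distance-inflating sun coefficient.
#' @param rho Perceived tree-shade intensity in `[0, 1]`.
#' @return Numeric vector of costs, in the same units as the input lengths.
#' @examples
#' path_cost(path_composition(86, 0, 0), beta = 1.16, rho = 0.5)
#' @export
path_cost <- function(option, beta, rho = 1) {
  stopifnot(inherits(option, "path_composition"))
  check_choice_params(beta = beta, rho = rho)
  beta * (option$a_sun + (1 - rho) * option$a_tree) +
    option$a_shade + rho * option$a_tree
}

check_choice_params <- function(beta = NULL, rho = NULL, tau = NULL) {
  if (!is.null(beta) && (any(!is.finite(beta)) || any(beta <= 0)))
    stop("beta must be a positive cost factor (got ", deparse(beta), ")")
  if (!is.null(rho) && (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1)))
    stop("rho must lie in [0, 1] (got ", deparse(rho), ")")
  if (!is.null(tau) && (any(!is.finite(tau)) || any(tau <= 0)))
    stop("tau must be a positive scale (got ", deparse(tau), ")")
  invisible(TRUE)
}

#' Cost difference between the two options of a trial
#'
#' \eqn{\Delta c = c(A) - c(B)}; antisymmetric under swapping the options.
#'
#' @param option_a,option_b [path_composition()] objects for options A and B.
#' @inheritParams path_cost
#' @return Numeric vector of cost differences.
#' @export
cost_difference <- function(option_a, option_b, beta, rho = 1) {
  path_cost(option_a, beta, rho) - path_cost(option_b, beta, rho)
}

#' Probability of choosing option A
#'
#' Logistic choice rule on the cost difference:
#' \deqn{p(y = 1) = \frac{1}{1 + \exp(\Delta c / \tau)}}
#' `tau` is the cost-difference scale ("temperature"): as `tau` shrinks the
#' cheaper option is chosen almost surely. Evaluated on the log-odds scale so
#' extreme `delta_c / tau` saturate at 0/1 without overflow.
#'
#' @param delta_c Cost difference `c(A) - c(B)` (already on the model's
#'   working length scale).
#' @param tau Positive cost-difference scale.
#' @return Probability of choosing option A, in `[0, 1]`.
#' @examples
#' choice_probability(0, 0.2)       # 0.5
#' choice_probability(0.2, 0.2)     # 1 / (1 + e)
#' @export
choice_probability <- function(delta_c, tau) {
  check_choice_params(tau = tau)
  stats::plogis(-delta_c / tau)
}

#' Length of a path option expressed as equivalent full sun
#'
#' Tree shade of intensity `rho` over a stretch is perceived as `rho` of it in
#' full (building) shade and `1 - rho` in full sun, so the effective sun-lit
#' length of an option is `a_sun + (1 - rho) * a_tree`.
#'
#' @inheritParams path_cost
#' @return Numeric vector of effective sun-exposed lengths in metres.
#' @examples
#' effective_sun_length(path_composition(0, 100, 0), rho = 0.5)  # 50
#' @export
effective_sun_length <- function(option, rho) {
  stopifnot(inherits(option, "path_composition"))
  check_choice_params(rho = rho)
  option$a_sun + (1 - rho) * option$a_tree
}

#' Classify trials and chosen strategies
#'
#' With `L` the total length and `S` the effective sun length of each option
#' (at tree-shade intensity `rho`), a trial is a
#' * `trade_off` if one option is strictly shorter and the other strictly less
#'   sunny: the chosen option is labelled `sun_minimising` (the less sunny
#'   one) or `distance_minimising` (the shorter one);
#' * `dominance` if one option is no longer *and* no sunnier, with at least
#'   one strict inequality: choosing the dominating option is `optimal`,
#'   choosing the other `non_optimal`;
#' * `indifferent` if the options tie on both axes.
#'
#' At `rho = 1` the classification depends only on `a_sun` and the total
#' length (tree shade counted as building shade).
#'
#' @param option_a,option_b [path_composition()] objects (vectorised).
#' @param chose_a Logical/0-1 vector: did the walker take option A?
#' @param rho Perceived tree-shade intensity used for the effective sun length.
#' @return A data frame with columns `trial_type` and `chosen_strategy`.
#' @examples
#' classify_trial(path_composition(120, 0, 30), path_composition(40, 0, 140),
#'                chose_a = FALSE, rho = 1)
#' @export
classify_trial <- function(option_a, option_b, chose_a, rho = 1) {
  stopifnot(inherits(option_a, "path_composition"),
            inherits(option_b, "path_composition"))
  if (any(is.na(chose_a)))
    stop("chose_a has missing outcomes; classification needs observed choices")
  n <- length(option_a)
  chose_a <- rep_len(as.logical(chose_a), n)
  L_a <- total_length(option_a); L_b <- total_length(option_b)
  S_a <- effective_sun_length(option_a, rho)
  S_b <- effective_sun_length(option_b, rho)

  trial_type <- character(n); strategy <- character(n)
  for (i in seq_len(n)) {
    dl <- L_a[i] - L_b[i]; ds <- S_a[i] - S_b[i]
    if (dl == 0 && ds == 0) {
      trial_type[i] <- "indifferent"; strategy[i] <- "indifferent"
    } else if ((dl < 0 && ds > 0) || (dl > 0 && ds < 0)) {
      trial_type[i] <- "trade_off"
      shorter_is_a <- dl < 0
      took_shorter <- chose_a[i] == shorter_is_a
      strategy[i] <- if (took_shorter) "distance_minimising" else "sun_minimising"
    } else {
      trial_type[i] <- "dominance"
      a_dominates <- dl <= 0 && ds <= 0
      strategy[i] <- if (chose_a[i] == a_dominates) "optimal" else "non_optimal"
    }
  }
  data.frame(trial_type = trial_type, chosen_strategy = strategy)
}

#' Sun distance of equal cost to a shaded distance
#'
#' The indifference line between distance walked in full shade and distance
#' walked in full sun has slope `1 / beta`: `shade_length` metres of shade
#' cost the same as `shade_length / beta` metres of sun.
#'
#' @param shade_length Metres walked in full (building) shade.
#' @param beta Positive distance-inflating sun coefficient.
#' @param round_m Round the result to whole metres (the convention used for
#'   reported equivalences)? Default `TRUE`.
#' @return Equivalent sun-walked distance in metres.
#' @examples
#' sun_equivalent_distance(100, 1.16)  # 86
#' sun_equivalent_distance(100, 1.84)  # 54
#' @export
sun_equivalent_distance <- function(shade_length, beta, round_m = TRUE) {
  check_choice_params(beta = beta)
  out <- shade_length / beta
  if (round_m) round(out) else out
}

#' Sun stretch completing a mixed exposure of equal cost
#'
#' Solves `fixed_shade + beta * s = shade_target` for the sun stretch `s`:
#' the sun-lit metres that, together with `fixed_shade` metres of full shade,
#' cost the same as `shade_target` metres of full shade.
#'
#' @param shade_target Full-shade distance to match, in metres.
#' @param fixed_shade Shaded part of the mixed route, in metres
#'   (`<= shade_target`).
#' @inheritParams sun_equivalent_distance
#' @return Sun stretch in metres.
#' @examples
#' mixed_exposure_sun_component(100, 50, 1.16)  # 43
#' mixed_exposure_sun_component(100, 50, 1.84)  # 27
#' @export
mixed_exposure_sun_component <- function(shade_target, fixed_shade, beta,
                                         round_m = TRUE) {
  check_choice_params(beta = beta)
  if (any(fixed_shade > shade_target))
    stop("fixed_shade exceeds shade_target: no sun stretch can complete the route")
  out <- (shade_target - fixed_shade) / beta
  if (round_m) round(out) else out
}
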