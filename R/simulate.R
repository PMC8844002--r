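#' Configuration of a synthetic path-choice study
#'
#' Collects the generative settings for a synthetic cohort with the same
#' statistical structure as the field study: a number of participants, each
#' completing a fixed series of binary trials (one of which is a designated
#' test trial with a clearly dominated option), two choice sets, path lengths
#' of a few tens to a few hundred metres decomposed into sun / tree-shade /
#' building-shade stretches, participant sun-cost factors drawn from a Gamma
#' population distribution, and Bernoulli outcomes from the logistic choice
#' rule.
#'
#' The population hyperparameters are given as the population mean and
#' variance of `beta_j` and converted to the `(d, e)` parameterisation:
#' `e = log(mean)/2` (so the mean is `exp(2e)`) and `d = 3e - log(var)`.
#'
#' @param n_participants Cohort size (default 46, the analysed cohort size).
#' @param n_trials Trials per participant, including the test trial
#'   (default 13).
#' @param test_trial Which trial id is the test trial (default the last).
#' @param beta_mean,beta_var Population mean and variance of the sun-cost
#'   factor `beta_j` (defaults 1.16 and 0.04).
#' @param rho True perceived tree-shade intensity (default 0.5).
#' @param tau True cost-difference scales, one per choice set (default
#'   `c(0.2, 0.2)` on the down-scaled length scale).
#' @param length_scale Length down-scaling used when simulating choices
#'   (default 0.01).
#' @param length_range Range of total option lengths in metres.
#' @param trade_off_fraction Fraction of non-test trials that are trade-off
#'   trials (shorter-but-sunnier vs longer-but-shadier) at `rho = 1`.
#' @param test_length_ratio,test_sun_ratio Minimum factors by which the
#'   dominated test-trial option is longer and (effectively) sunnier.
#' @param max_attempts Rejection-sampling budget per trial.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 46, n_trials = 13,
                       test_trial = n_trials,
                       beta_mean = 1.16, beta_var = 0.04,
                       rho = 0.5, tau = c(0.2, 0.2),
                       length_scale = 0.01,
                       length_range = c(40, 250),
                       trade_off_fraction = 0.7,
                       test_length_ratio = 1.5, test_sun_ratio = 2,
                       max_attempts = 1000) {
  stopifnot(n_participants >= 0, n_trials >= 1,
            test_trial >= 1, test_trial <= n_trials,
            beta_mean > 0, beta_var > 0,
            rho >= 0, rho <= 1, all(tau > 0),
            length_range[1] > 0, diff(length_range) > 0,
            trade_off_fraction >= 0, trade_off_fraction <= 1,
            test_length_ratio > 1, test_sun_ratio > 1)
  e <- log(beta_mean) / 2
  d <- 3 * e - log(beta_var)
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 test_trial = test_trial, beta_mean = beta_mean,
                 beta_var = beta_var, d = d, e = e, rho = rho, tau = tau,
                 length_scale = length_scale, length_range = length_range,
                 trade_off_fraction = trade_off_fraction,
                 test_length_ratio = test_length_ratio,
                 test_sun_ratio = test_sun_ratio,
                 max_attempts = max_attempts),
            class = "sim_config")
}

# Split a total length into sun/tree/shade parts with a given sun fraction.
# The shaded remainder is divided between tree and building shade with a
# U-shaped Beta(0.15, 0.15) tree share: options tend to be shaded mostly by
# trees or mostly by buildings, as when one alternative runs under a tree
# row and the other along a building face. These strong tree-vs-building
# contrasts are what identifies the perceived tree-shade intensity, whose
# effect on a cost difference scales with the tree-shade difference.
split_composition <- function(L, f_sun, tree_share = stats::rbeta(1, 0.15, 0.15)) {
  f_tree <- (1 - f_sun) * tree_share
  c(sun = L * f_sun, tree = L * f_tree, shade = L * (1 - f_sun - f_tree))
}

#' Generate the trial templates of a synthetic choice set
#'
#' Builds the option pairs (no outcomes yet) for every participant. Option B
#' is by convention the generally more building-shaded option. Non-test
#' trials are a mix of trade-off trials (A strictly shorter, B strictly less
#' sunny at `rho = 1`) and dominance trials (B both shorter and less sunny);
#' the trade-off count per participant is `round(trade_off_fraction * m)` of
#' the `m` non-test trials. The test trial opposes a clearly dominated option
#' A, at least `test_length_ratio` times longer and `test_sun_ratio` times
#' sunnier than B. Participants are split evenly between the choice sets.
#'
#' Uses R's global random stream: call `set.seed()` first (or use
#' [simulate_study()]) for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A data frame of trial templates: `participant_id`, `trial_id`,
#'   `choice_set`, the six composition columns, `sun_state`, `is_test` and
#'   `design_type`.
#' @export
generate_choice_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lo <- config$length_range[1]; hi <- config$length_range[2]
  K <- length(config$tau)

  # Trade-off trials are cost-balanced at the reference parameters
  # (beta = population mean, rho = 0.5): the longer, shadier option's length
  # is set so the two costs roughly tie, keeping choices away from
  # saturation -- the same design goal as maximising trade-offs in the field
  # layout. Jitter keeps the designs varied.
  make_trade_off <- function() {
    bref <- config$beta_mean
    unit_cost <- function(fs, ft) bref * (fs + 0.5 * ft) + (1 - fs - ft) + 0.5 * ft
    for (a in seq_len(config$max_attempts)) {
      # long options with large shaded portions: the tree-shade stretches
      # reach many tens of metres, as on the study's tree-lined paths
      L_A <- stats::runif(1, max(lo, hi / 2.5), hi / 1.5)
      u <- stats::rbeta(1, 0.15, 0.15)  # opposed tree shares: one option
      A <- split_composition(L_A, stats::runif(1, 0.25, 0.7), u)      # tree-lined,
      fs_B <- stats::runif(1, 0, 0.25)                                # one built-up
      ft_B <- (1 - fs_B) * (1 - u)
      cost_A <- unit_cost(A[["sun"]] / L_A, A[["tree"]] / L_A) * L_A
      L_B <- cost_A / unit_cost(fs_B, ft_B) * exp(stats::runif(1, -0.15, 0.15))
      if (L_B < L_A * 1.02 || L_B > hi) next
      B <- split_composition(L_B, fs_B, 1 - u)
      if (B[["sun"]] < A[["sun"]]) return(list(A = A, B = B, type = "trade_off"))
    }
    stop("could not generate a trade-off trial within ", config$max_attempts,
         " attempts; widen length_range")
  }
  make_dominance <- function() {
    for (a in seq_len(config$max_attempts)) {
      L_A <- stats::runif(1, lo / 0.95, hi)
      L_B <- L_A * stats::runif(1, 0.8, 0.98)  # mild dominance: choices stay informative
      u <- stats::rbeta(1, 0.15, 0.15)
      A <- split_composition(L_A, stats::runif(1, 0.4, 0.9), u)
      B <- split_composition(L_B, stats::runif(1, 0, 0.35), 1 - u)
      if (B["sun"] < A["sun"]) return(list(A = A, B = B, type = "dominance"))
    }
    stop("could not generate a dominance trial within ", config$max_attempts,
         " attempts; widen length_range")
  }
  make_test <- function() {
    for (a in seq_len(config$max_attempts)) {
      L_B <- stats::runif(1, lo, hi / config$test_length_ratio)
      L_A <- L_B * stats::runif(1, config$test_length_ratio, config$test_length_ratio + 0.5)
      if (L_A > hi) next
      A <- split_composition(L_A, stats::runif(1, 0.7, 1))
      B <- split_composition(L_B, stats::runif(1, 0.05, 0.3))
      if (A["sun"] >= config$test_sun_ratio * B["sun"])
        return(list(A = A, B = B, type = "test"))
    }
    stop("could not generate a test trial within ", config$max_attempts,
         " attempts; loosen the test-trial margins")
  }

  rows <- vector("list", config$n_participants * config$n_trials)
  r <- 0L
  for (j in seq_len(config$n_participants)) {
    k <- ((j - 1L) %% K) + 1L
    m <- config$n_trials - 1L
    n_to <- round(config$trade_off_fraction * m)
    types <- sample(c(rep("trade_off", n_to), rep("dominance", m - n_to)))
    ti <- 0L
    for (t in seq_len(config$n_trials)) {
      if (t == config$test_trial) {
        tr <- make_test()
      } else {
        ti <- ti + 1L
        tr <- if (types[ti] == "trade_off") make_trade_off() else make_dominance()
      }
      r <- r + 1L
      rows[[r]] <- data.frame(
        participant_id = j, trial_id = t, choice_set = k,
        a_sun_A = unname(tr$A["sun"]), a_tree_A = unname(tr$A["tree"]),
        a_shade_A = unname(tr$A["shade"]),
        a_sun_B = unname(tr$B["sun"]), a_tree_B = unname(tr$B["tree"]),
        a_shade_B = unname(tr$B["shade"]),
        sun_state = "full_sun",
        is_test = t == config$test_trial,
        design_type = tr$type)
    }
  }
  do.call(rbind, rows)
}

#' Draw participant sun-cost factors from the population distribution
#'
#' `beta_j` are i.i.d. `Gamma(exp(d+e), exp(d-e))` (shape/rate), so their
#' mean is `exp(2e)`.
#'
#' @param config A [sim_config()] (supplies `d` and `e`).
#' @param n How many participants (default `config$n_participants`).
#' @return Numeric vector of positive `beta_j`.
#' @export
draw_participants <- function(config, n = config$n_participants) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  if (n == 0) return(numeric(0))
  stats::rgamma(n, shape = exp(config$d + config$e),
                rate = exp(config$d - config$e))
}

#' Simulate choice outcomes for trial templates
#'
#' Completes trial templates with Bernoulli outcomes from the logistic choice
#' rule: the cost difference of the two options (computed at the
#' participant's `beta_j` and the shared `rho`, on lengths multiplied by
#' `length_scale`) is passed through [choice_probability()] with the
#' trial's choice-set `tau`. As `tau` tends to 0 the cheaper option is chosen
#' almost surely.
#'
#' @param trials Trial templates from [generate_choice_set()] (or any
#'   decisions-shaped table without outcomes).
#' @param beta_j Vector of sun-cost factors indexed by `participant_id`.
#' @param rho Perceived tree-shade intensity.
#' @param tau Vector of cost scales indexed by `choice_set`.
#' @param length_scale Length down-scaling applied before the cost difference.
#' @return The `trials` table with columns `p_choose_A` and `chose_A` added.
#' @export
simulate_decisions <- function(trials, beta_j, rho, tau, length_scale = 0.01) {
  check_choice_params(beta = beta_j, rho = rho, tau = tau)
  s <- length_scale
  A <- path_composition(trials$a_sun_A * s, trials$a_tree_A * s, trials$a_shade_A * s)
  B <- path_composition(trials$a_sun_B * s, trials$a_tree_B * s, trials$a_shade_B * s)
  b <- beta_j[trials$participant_id]
  dc <- cost_difference(A, B, beta = b, rho = rho)
  p <- choice_probability(dc, tau[trials$choice_set])
  trials$p_choose_A <- p
  trials$chose_A <- stats::rbinom(nrow(trials), 1, p)
  trials
}

#' One-call synthetic study
#'
#' Seeds the random stream, draws the cohort, generates the trials and
#' simulates the outcomes.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `shadepath_sim` with elements `decisions`,
#'   `beta_j`, `config` and `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  beta_j <- draw_participants(config)
  trials <- generate_choice_set(config)
  decisions <- simulate_decisions(trials, beta_j, config$rho, config$tau,
                                  config$length_scale)
  structure(list(decisions = decisions, beta_j = beta_j, config = config,
                 seed = seed),
            class = "shadepath_sim")
}

#' @export
print.shadepath_sim <- function(x, ...) {
  cat(sprintf(
    "<shadepath_sim> %d participants x %d trials (seed %d): true rho %.2f, tau %s, mean beta %.3f\n",
    x$config$n_participants, x$config$n_trials, x$seed, x$config$rho,
    paste(x$config$tau, collapse = "/"), mean(x$beta_j)))
  invisible(x)
}

#' Synthetic courtyard scene
#'
#' Builds a small 2.5D courtyard of the kind the shading pipeline targets:
#' two east-west buildings framing a lawn, a wide 5-strip path along each
#' building, narrow paths crossing the lawn, and a row of tree crowns, plus
#' decision timestamps spread over a day. Entirely synthetic -- the layout
#' emulates the *kind* of geometry of a tropical campus courtyard, not any
#' surveyed site.
#'
#' @param n_trees Number of tree crowns placed along the lawn edge.
#' @param building_height Building height in metres.
#' @param site_latitude,site_longitude Geographic site (default: Singapore).
#' @param date Date for the decision timestamps (local calendar day).
#' @param tz Timezone of the site.
#' @param n_instants Number of decision timestamps, spread 10:00--16:00.
#' @return A list with elements `scene` (a [scene()]) and `instants`
#'   (timezone-aware `POSIXct`).
#' @export
generate_scene <- function(n_trees = 3, building_height = 15,
                           site_latitude = 1.35, site_longitude = 103.68,
                           date = "2019-07-15", tz = "Asia/Singapore",
                           n_instants = 6) {
  rect <- function(x0, x1, y0, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  strip5 <- function(x0, x1, y0) lapply(0:4, function(i)
    rect(x0, x1, y0 + 1.2 * i, y0 + 1.2 * (i + 1)))

  buildings <- list(
    list(footprint = rect(0, 100, -30, -10), height = building_height),  # south
    list(footprint = rect(0, 100, 40, 60), height = building_height))    # north
  paths <- list(
    south = list(strips = strip5(0, 100, -10), length = 100, width = 6, is_wide = TRUE),
    north = list(strips = strip5(0, 100, 34), length = 100, width = 6, is_wide = TRUE),
    cross_east = list(strips = list(rect(68, 70, -4, 34)), length = 38,
                      width = 2, is_wide = FALSE),
    cross_west = list(strips = list(rect(25, 27, -4, 34)), length = 38,
                      width = 2, is_wide = FALSE))
  trees <- if (n_trees > 0) {
    data.frame(x = seq(15, 85, length.out = n_trees), y = 31,
               z = 6, rx = 3.5, rz = 2.5)
  } else NULL
  scn <- scene(site_latitude, site_longitude, buildings = buildings,
               trees = trees, paths = paths)
  instants <- as.POSIXct(paste(date, "10:00:00"), tz = tz) +
    round(seq(0, 6 * 3600, length.out = n_instants))
  list(scene = scn, instants = instants)
}
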