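#' Indifference table between shaded and sunny walking distance
#'
#' For each sun-cost factor `beta`, tabulates the sun distance of equal
#' perceived cost to `shade_length` metres of full shade, and the mixed-route
#' decomposition: the sun stretch that together with `fixed_shade` metres of
#' shade matches `shade_length` of full shade. Reported values are rounded to
#' whole metres; each row satisfies
#' `fixed_shade + beta * mixed_sun = shade_length` within rounding.
#'
#' @param beta Vector of sun-cost factors.
#' @param shade_length Full-shade distance to match (default 100 m).
#' @param fixed_shade Shaded part of the mixed route (default 50 m).
#' @return A data frame with columns `beta`, `shade_length`,
#'   `equivalent_sun`, `mixed_fixed_shade`, `mixed_sun`.
#' @examples
#' indifference_table(c(1, 1.16, 1.84))
#' @export
indifference_table <- function(beta, shade_length = 100, fixed_shade = 50) {
  data.frame(
    beta = beta,
    shade_length = shade_length,
    equivalent_sun = sun_equivalent_distance(shade_length, beta),
    mixed_fixed_shade = fixed_shade,
    mixed_sun = mixed_exposure_sun_component(shade_length, fixed_shade, beta))
}

#' Study-style posterior report tables
#'
#' Collects the per-participant forest table, the pooled population
#' summaries and the headline quantities derived from a fit: the population
#' sun-cost factor (pooled-draws reading and `exp(2e)` reading), per-set
#' pooled factors, the tree-shade intensity, the cost scales, the shade
#' discount factor `1/beta` and the percent-closer measure `1 - 1/beta`
#' (how much perceptually "closer" a fully shaded route is than a sunny one).
#'
#' @param fit A [sample_posterior()] fit (or a precomputed
#'   [summarize_posterior()] object via `summary`).
#' @param summary Optional precomputed summary to avoid recomputation.
#' @param out_dir Optional directory; when given, the tables are also written
#'   as CSV files (`participants.csv`, `population.csv`, `parameters.csv`,
#'   `headline.csv`).
#' @return A list of class `shadepath_report` with elements `participants`,
#'   `population`, `parameters` and `headline` (data frames).
#' @export
report_posterior <- function(fit, summary = NULL, out_dir = NULL) {
  if (is.null(summary)) summary <- summarize_posterior(fit)
  stopifnot(inherits(summary, "shadepath_summary"))
  pop <- summary$population
  beta_bar <- pop$mean[pop$quantity == "beta_pooled"]
  headline <- data.frame(
    quantity = c("beta_population_pooled", "beta_population_exp2e",
                 sprintf("beta_pooled_set%s",
                         sub("^beta_pooled_set", "",
                             grep("^beta_pooled_set", pop$quantity, value = TRUE))),
                 "rho", "shade_discount_factor", "percent_closer_in_shade"),
    value = c(beta_bar,
              pop$mean[pop$quantity == "beta_exp2e"],
              pop$mean[grep("^beta_pooled_set", pop$quantity)],
              summary$population$mean[pop$quantity == "rho"],
              1 / beta_bar,
              100 * (1 - 1 / beta_bar)))
  out <- structure(list(participants = summary$participants,
                        population = summary$population,
                        parameters = summary$parameters,
                        headline = headline),
                   class = "shadepath_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}

#' @export
print.shadepath_report <- function(x, ...) {
  cat("<shadepath_report> headline quantities:\n")
  print(format(x$headline, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Strategy counts across a grid of tree-shade intensities
#'
#' Classifies every decision with [classify_trial()] at each `rho` in
#' `rho_grid` and tabulates the chosen strategies. Lowering `rho` moves
#' tree-shaded options towards "sunny", so on datasets where chosen longer
#' options carry tree shade, decisions previously counted `non_optimal`
#' reappear as `sun_minimising`.
#'
#' @param decisions Canonical decisions table with observed `chose_A`.
#' @param rho_grid Tree-shade intensities to sweep (default
#'   `c(0, 0.25, 0.5, 0.75, 1)`).
#' @return A data frame with one row per (`rho`, strategy) pair:
#'   `rho`, `trial_type`, `chosen_strategy`, `n`. Rows with `n = 0` are kept
#'   so counts always reconcile to the number of decisions.
#' @export
report_strategies <- function(decisions,
                              rho_grid = c(0, 0.25, 0.5, 0.75, 1)) {
  strategies <- c("sun_minimising", "distance_minimising", "optimal",
                  "non_optimal", "indifferent")
  if (nrow(decisions) == 0)
    return(data.frame(rho = numeric(), trial_type = character(),
                      chosen_strategy = character(), n = integer()))
  A <- path_composition(decisions$a_sun_A, decisions$a_tree_A, decisions$a_shade_A)
  B <- path_composition(decisions$a_sun_B, decisions$a_tree_B, decisions$a_shade_B)
  out <- list()
  for (r in rho_grid) {
    lab <- classify_trial(A, B, decisions$chose_A, rho = r)
    tab <- table(factor(lab$chosen_strategy, levels = strategies))
    type_of <- c(sun_minimising = "trade_off", distance_minimising = "trade_off",
                 optimal = "dominance", non_optimal = "dominance",
                 indifferent = "indifferent")
    out[[length(out) + 1L]] <- data.frame(
      rho = r, trial_type = unname(type_of[strategies]),
      chosen_strategy = strategies, n = as.integer(tab))
  }
  do.call(rbind, out)
}

#' Forest plot of participant sun-cost factors
#'
#' Posterior means and credible intervals of `beta_j` per participant, with
#' the indifference line `beta = 1`. Requires ggplot2.
#'
#' @param summary A [summarize_posterior()] object.
#' @return A ggplot object.
#' @export
plot_beta_forest <- function(summary) {
  stopifnot(inherits(summary, "shadepath_summary"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_beta_forest needs the ggplot2 package")
  d <- summary$participants
  d$participant_id <- factor(d$participant_id,
                             levels = d$participant_id[order(d$mean)])
  ggplot2::ggplot(d, ggplot2::aes(x = mean, y = participant_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lower, xmax = upper),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(beta[j]), y = "participant",
                  title = "Distance-inflating sun coefficients") +
    ggplot2::theme_minimal()
}
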