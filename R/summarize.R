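#' Posterior summaries at individual and population level
#'
#' Produces the study-style summary of a fitted choice model:
#' * `parameters`: mean, central credible interval and convergence
#'   diagnostics for every sampled parameter;
#' * `participants`: the per-participant sun-cost factors `beta_j` with the
#'   posterior mass above 1 (sun aversion);
#' * `population`: pooled summaries of `beta`. The headline population
#'   estimate pools the posterior draws of all participants' `beta_j` into
#'   one distribution (optionally restricted to the participants of each
#'   choice set); the alternative reading `exp(2e)` -- the mean of the
#'   population Gamma distribution -- is reported alongside, as the two are
#'   distinct estimands that happen to agree closely in practice.
#'
#' @param fit A [sample_posterior()] fit.
#' @param level Credible-interval mass (default 0.95).
#' @param diagnostics Attach R-hat / bulk ESS per parameter (default `TRUE`;
#'   needs at least 2 chains)?
#' @return An object of class `shadepath_summary`: a list of the three data
#'   frames above.
#' @export
summarize_posterior <- function(fit, level = 0.95, diagnostics = TRUE) {
  stopifnot(inherits(fit, "shadepath_fit"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  qsum <- function(v) c(mean = mean(v), stats::quantile(v, probs))
  pars <- t(vapply(fit$params,
                   function(p) qsum(as.numeric(fit$draws[, , p])),
                   numeric(3)))
  parameters <- data.frame(parameter = fit$params,
                           mean = pars[, 1], lower = pars[, 2],
                           upper = pars[, 3], row.names = NULL)
  if (diagnostics && dim(fit$draws)[2] >= 2) {
    dg <- mcmc_diagnostics(fit)
    parameters$rhat <- dg$rhat
    parameters$ess_bulk <- dg$ess_bulk
  }

  beta_names <- sprintf("beta[%s]", fit$participant_ids)
  participants <- do.call(rbind, lapply(seq_along(fit$participant_ids), function(j) {
    v <- as.numeric(fit$draws[, , beta_names[j]])
    data.frame(participant_id = fit$participant_ids[j],
               mean = mean(v),
               lower = stats::quantile(v, probs[1]),
               upper = stats::quantile(v, probs[2]),
               p_beta_gt_1 = mean(v > 1), row.names = NULL)
  }))

  pool_row <- function(label, v) {
    data.frame(quantity = label, mean = mean(v),
               lower = stats::quantile(v, probs[1]),
               upper = stats::quantile(v, probs[2]),
               p_gt_1 = mean(v > 1), row.names = NULL)
  }
  pooled_all <- as.numeric(fit$draws[, , beta_names])
  population <- pool_row("beta_pooled", pooled_all)
  for (k in seq_along(fit$choice_sets)) {
    in_set <- participants_in_set(fit, fit$choice_sets[k])
    if (length(in_set)) {
      v <- as.numeric(fit$draws[, , sprintf("beta[%s]", in_set)])
      population <- rbind(population,
                          pool_row(sprintf("beta_pooled_set%s", fit$choice_sets[k]), v))
    }
  }
  e_draws <- as.numeric(fit$draws[, , "e"])
  population <- rbind(population, pool_row("beta_exp2e", exp(2 * e_draws)))
  rho_v <- as.numeric(fit$draws[, , "rho"])
  population <- rbind(population,
                      data.frame(quantity = "rho", mean = mean(rho_v),
                                 lower = stats::quantile(rho_v, probs[1]),
                                 upper = stats::quantile(rho_v, probs[2]),
                                 p_gt_1 = NA_real_, row.names = NULL))
  for (k in seq_along(fit$choice_sets)) {
    v <- as.numeric(fit$draws[, , sprintf("tau[%s]", fit$choice_sets[k])])
    population <- rbind(population,
                        data.frame(quantity = sprintf("tau[%s]", fit$choice_sets[k]),
                                   mean = mean(v),
                                   lower = stats::quantile(v, probs[1]),
                                   upper = stats::quantile(v, probs[2]),
                                   p_gt_1 = NA_real_, row.names = NULL))
  }

  structure(list(parameters = parameters, participants = participants,
                 population = population, level = level),
            class = "shadepath_summary")
}

# Participants with at least one decision in the given choice set.
participants_in_set <- function(fit, set) {
  d <- fit$model$decisions
  sort(unique(d$participant_id[d$choice_set == set]))
}

#' @export
print.shadepath_summary <- function(x, ...) {
  cat(sprintf("<shadepath_summary> %g%% credible intervals\n", 100 * x$level))
  cat("\nPopulation-level quantities:\n")
  print(format(x$population, digits = 3), row.names = FALSE)
  cat(sprintf("\n%d participant-level beta_j summaries in $participants;",
              nrow(x$participants)))
  cat(" full parameter table in $parameters.\n")
  invisible(x)
}
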