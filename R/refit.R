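#' Refit the model to the deposited field-study data
#'
#' End-to-end refit pipeline for the study's deposited decisions data: read a
#' decisions table (schema-mapped if needed), apply the eligibility and
#' treatment filters, fit the hierarchical choice model with the study's
#' sampler settings, and return the headline report.
#'
#' The deposited dataset is public (OSF, \verb{https://osf.io/aj4vk/}) but is
#' not redistributed with this package; download it, map its columns to the
#' canonical layout of [read_decisions()] via `column_map`, and pass the
#' local path. The exact trial numbering of the test trial is study
#' configuration (`test_trial_id`).
#'
#' @param file Path to a local decisions CSV.
#' @param column_map Optional named character vector renaming file columns to
#'   canonical ones, e.g. `c(participant = "participant_id")`.
#' @param test_trial_id Which trial is the test trial; `NA` skips the
#'   test-trial filter (use when the deposit already excludes it).
#' @param chains,tune,draws,seed Sampler settings (defaults: the study's).
#' @param ... Passed to [sample_posterior()].
#' @return A list with the `fit`, its `summary` and the `report`.
#' @export
refit_deposited_study <- function(file, column_map = NULL, test_trial_id = NA,
                                  chains = 4, tune = 2000, draws = 10000,
                                  seed = 1, ...) {
  if (!file.exists(file))
    stop("deposited dataset not found at '", file, "'. The study data are ",
         "deposited publicly on OSF (project aj4vk); download the decisions ",
         "table and pass its local path.")
  d <- read_decisions_mapped(file, column_map)
  if (!is.na(test_trial_id) || "sun_state" %in% names(d) ||
      "treatment" %in% names(d)) {
    if (!("sun_state" %in% names(d)) && !("treatment" %in% names(d)))
      d$treatment <- TRUE
    elig <- apply_eligibility(d, test_trial_id =
                                if (is.na(test_trial_id)) -1L else test_trial_id)
    d <- elig$analysis
  }
  model <- build_choice_model(d)
  fit <- sample_posterior(model, chains = chains, tune = tune, draws = draws,
                          seed = seed, ...)
  summary <- summarize_posterior(fit)
  list(fit = fit, summary = summary, report = report_posterior(fit, summary))
}

read_decisions_mapped <- function(file, column_map = NULL) {
  d <- read_delim_flex(file)
  if (!is.null(column_map)) {
    for (from in names(column_map)) {
      to <- column_map[[from]]
      if (from %in% names(d)) names(d)[names(d) == from] <- to
    }
  }
  need <- c("participant_id", "trial_id", "choice_set",
            "a_sun_A", "a_tree_A", "a_shade_A",
            "a_sun_B", "a_tree_B", "a_shade_B", "chose_A")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("after mapping, decisions file still lacks column(s): ",
         paste(miss, collapse = ", "),
         "; supply a column_map matching the deposit's schema")
  d
}
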