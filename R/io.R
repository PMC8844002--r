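EVENT_CODES <- c("decision", "end_of_trial", "sun_presence", "sun_exposure",
                 "water_intake")
SUN_PRESENCE_STATES <- c("full_sun", "cloudy_sun", "no_sun")
SUN_EXPOSURE_STATES <- c("no_shade", "tree_shade", "building_shade")

# Delimited reader tolerant of a UTF-8 BOM and of comma/semicolon dialects.
read_delim_flex <- function(file) {
  first <- readLines(file, n = 1L, warn = FALSE)
  had_bom <- grepl("^﻿", first)
  first <- sub("^﻿", "", first)
  sep <- if (lengths(regmatches(first, gregexpr(";", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) ";" else ","
  if (had_bom || sep == ";")
    message("reading ", file, ": ",
            if (had_bom) "UTF-8 BOM stripped; " else "",
            "delimiter '", sep, "'")
  utils::read.csv(file, sep = sep, fileEncoding = "UTF-8-BOM",
                  stringsAsFactors = FALSE)
}

parse_iso_time <- function(x) {
  x <- gsub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  for (fmt in c("%Y-%m-%dT%H:%M:%S%z", "%Y-%m-%d %H:%M:%S%z")) {
    t <- as.POSIXct(strptime(x, fmt, tz = "UTC"))
    if (!is.na(t)) return(t)
  }
  NA
}

#' Parse a coded event log
#'
#' Reads the per-participant event spreadsheet produced by video coding:
#' one row per event with columns `participant_id`, `coder_id`, `event_code`
#' (`decision`, `end_of_trial`, `sun_presence`, `sun_exposure`,
#' `water_intake`), `time` (ISO-8601 with explicit timezone offset), `x_m`,
#' `y_m`, `state` (required for `sun_presence` / `sun_exposure` events) and
#' `chose_A` (required for `decision` events).
#'
#' Malformed rows are *not* silently dropped: they are removed from the
#' returned table but collected, with their line numbers and messages, in the
#' `errors` attribute, and a warning summarises the count. Timestamps must be
#' non-decreasing within a participant/coder stream.
#'
#' @param file Path to a delimited event file (comma or semicolon; a UTF-8
#'   BOM is tolerated).
#' @return A data frame of validated events ordered by participant and time,
#'   with a `time` column parsed to `POSIXct` (UTC) and an `errors` attribute
#'   (data frame with `line` and `message`; zero rows when the log is clean).
#' @export
parse_events <- function(file) {
  raw <- read_delim_flex(file)
  need <- c("participant_id", "event_code", "time")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("event file lacks column(s): ", paste(miss, collapse = ", "))
  if (!"coder_id" %in% names(raw)) raw$coder_id <- 1L
  if (!"state" %in% names(raw)) raw$state <- NA_character_
  if (!"chose_A" %in% names(raw)) raw$chose_A <- NA
  if (!"x_m" %in% names(raw)) raw$x_m <- NA_real_
  if (!"y_m" %in% names(raw)) raw$y_m <- NA_real_

  errors <- list()
  bad <- function(i, msg) errors[[length(errors) + 1L]] <<-
    data.frame(line = i + 1L, message = msg)  # +1: header line

  raw$.time <- as.POSIXct(NA, tz = "UTC")
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ev <- raw$event_code[i]
    if (!ev %in% EVENT_CODES) {
      bad(i, paste0("unknown event code '", ev, "'")); keep[i] <- FALSE; next
    }
    t <- parse_iso_time(raw$time[i])
    if (is.na(t)) {
      bad(i, paste0("unparseable or timezone-naive time '", raw$time[i], "'"))
      keep[i] <- FALSE; next
    }
    raw$.time[i] <- t
    st <- raw$state[i]
    if (ev == "sun_presence" && !(st %in% SUN_PRESENCE_STATES)) {
      bad(i, paste0("sun_presence event needs a state in {",
                    paste(SUN_PRESENCE_STATES, collapse = ", "), "}"))
      keep[i] <- FALSE; next
    }
    if (ev == "sun_exposure" && !(st %in% SUN_EXPOSURE_STATES)) {
      bad(i, paste0("sun_exposure event needs a state in {",
                    paste(SUN_EXPOSURE_STATES, collapse = ", "), "}"))
      keep[i] <- FALSE; next
    }
    if (!ev %in% c("sun_presence", "sun_exposure") && !is.na(st) && nzchar(st)) {
      bad(i, paste0("event '", ev, "' must not carry a state")); keep[i] <- FALSE; next
    }
    if (ev == "decision" && is.na(raw$chose_A[i])) {
      bad(i, "decision event lacks chose_A"); keep[i] <- FALSE; next
    }
    if (ev != "decision" && !is.na(raw$chose_A[i])) {
      bad(i, paste0("event '", ev, "' must not carry chose_A")); keep[i] <- FALSE; next
    }
  }

  # unordered timestamps within a participant/coder stream are row errors
  for (key in unique(paste(raw$participant_id, raw$coder_id))) {
    idx <- which(paste(raw$participant_id, raw$coder_id) == key & keep)
    if (length(idx) > 1) {
      tt <- raw$.time[idx]
      out_of_order <- which(diff(as.numeric(tt)) < 0)
      for (k in out_of_order) {
        bad(idx[k + 1], "timestamp earlier than the preceding event")
        keep[idx[k + 1]] <- FALSE
      }
    }
  }

  err <- if (length(errors)) do.call(rbind, errors) else
    data.frame(line = integer(), message = character())
  if (nrow(err))
    warning(nrow(err), " malformed event row(s) set aside; see attr(x, \"errors\")")

  out <- raw[keep, , drop = FALSE]
  out$time <- out$.time
  out$.time <- NULL
  out <- out[order(out$participant_id, out$coder_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- err
  out
}

#' Cross-coder agreement report
#'
#' Compares two coders' event logs for the same participant. Events are
#' matched by code and order of occurrence; a matched pair disagrees if the
#' decision labels differ, the sun-presence states differ, or the timestamps
#' differ by more than `time_tolerance` seconds (strictly more: a 5 s
#' difference is still an agreement under the default). Unmatched events
#' (one coder recorded more of a code than the other) are listed separately.
#'
#' @param events_coder1,events_coder2 Event tables ([parse_events()] output)
#'   for one participant each.
#' @param time_tolerance Seconds of timestamp slack (default 5).
#' @return A list of class `coder_agreement`: `agreements` and
#'   `disagreements` (data frames of matched pairs), `unmatched`, and counts.
#' @export
coder_agreement <- function(events_coder1, events_coder2, time_tolerance = 5) {
  p1 <- unique(events_coder1$participant_id)
  p2 <- unique(events_coder2$participant_id)
  if (length(p1) != 1 || length(p2) != 1 || p1 != p2)
    stop("both logs must cover the same single participant (got ",
         paste(p1, collapse = "/"), " vs ", paste(p2, collapse = "/"), ")")

  pairs <- list(); unmatched <- list()
  for (code in EVENT_CODES) {
    a <- events_coder1[events_coder1$event_code == code, , drop = FALSE]
    b <- events_coder2[events_coder2$event_code == code, , drop = FALSE]
    n <- min(nrow(a), nrow(b))
    for (i in seq_len(n)) {
      dt <- abs(as.numeric(a$time[i]) - as.numeric(b$time[i]))
      reasons <- character()
      if (dt > time_tolerance)
        reasons <- c(reasons, sprintf("time differs by %.0f s", dt))
      if (code == "decision" && !identical(a$chose_A[i], b$chose_A[i]))
        reasons <- c(reasons, "decision label differs")
      if (code == "sun_presence" && !identical(a$state[i], b$state[i]))
        reasons <- c(reasons, "sun presence differs")
      pairs[[length(pairs) + 1L]] <- data.frame(
        event_code = code, index = i, dt_seconds = dt,
        agree = length(reasons) == 0,
        reason = if (length(reasons)) paste(reasons, collapse = "; ") else "")
    }
    if (nrow(a) != nrow(b))
      unmatched[[length(unmatched) + 1L]] <- data.frame(
        event_code = code,
        coder = if (nrow(a) > nrow(b)) "coder1" else "coder2",
        extra = abs(nrow(a) - nrow(b)))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(event_code = character(), index = integer(),
               dt_seconds = numeric(), agree = logical(), reason = character())
  unmatched <- if (length(unmatched)) do.call(rbind, unmatched) else
    data.frame(event_code = character(), coder = character(), extra = integer())
  structure(list(agreements = pairs[pairs$agree, , drop = FALSE],
                 disagreements = pairs[!pairs$agree, , drop = FALSE],
                 unmatched = unmatched,
                 n_agree = sum(pairs$agree), n_disagree = sum(!pairs$agree)),
            class = "coder_agreement")
}

#' @export
print.coder_agreement <- function(x, ...) {
  cat(sprintf("<coder_agreement> %d agree | %d disagree | %d unmatched\n",
              x$n_agree, x$n_disagree, sum(x$unmatched$extra)))
  if (x$n_disagree) print(x$disagreements, row.names = FALSE)
  invisible(x)
}

#' Attach sun-presence states to decisions
#'
#' Each decision event inherits the sun-presence state in effect at its
#' timestamp: the state of the most recent prior `sun_presence` event. A
#' decision is a *treatment* decision -- the only kind informative about sun
#' avoidance -- when that state is in `sun_present` (by default both
#' `full_sun` and `cloudy_sun`, the states under which shadows are visible).
#' Decisions are numbered 1, 2, ... per participant in time order.
#'
#' @param events A [parse_events()] table (may span many participants).
#' @param sun_present States counted as "sun present".
#' @return A data frame with one row per decision: `participant_id`,
#'   `trial_id`, `time`, `chose_A`, `sun_state`, `treatment`.
#' @export
flag_treatment_decisions <- function(events,
                                     sun_present = c("full_sun", "cloudy_sun")) {
  out <- list()
  for (p in unique(events$participant_id)) {
    ev <- events[events$participant_id == p, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    state <- NA_character_
    trial <- 0L
    for (i in seq_len(nrow(ev))) {
      if (ev$event_code[i] == "sun_presence") state <- ev$state[i]
      if (ev$event_code[i] == "decision") {
        trial <- trial + 1L
        if (is.na(state))
          stop("participant ", p, ", decision ", trial,
               ": no sun_presence event precedes it; the sun state is unknown")
        out[[length(out) + 1L]] <- data.frame(
          participant_id = p, trial_id = trial, time = ev$time[i],
          chose_A = as.integer(ev$chose_A[i]), sun_state = state,
          treatment = state %in% sun_present)
      }
    }
  }
  if (!length(out))
    return(data.frame(participant_id = character(), trial_id = integer(),
                      time = as.POSIXct(character(), tz = "UTC"),
                      chose_A = integer(), sun_state = character(),
                      treatment = logical()))
  do.call(rbind, out)
}

#' Apply the study eligibility and filtering rules
#'
#' Produces the analysis table from a decisions table:
#' * participants marked ineligible in `statuses` are removed;
#' * a participant who chose the dominated option of the designated test
#'   trial is marked `failed_test_trial` and removed;
#' * the test trial itself is removed from everyone;
#' * only treatment decisions (per the `treatment` column, or the
#'   `sun_state` column and `sun_present`) enter the analysis table.
#' Participants with zero treatment decisions stay eligible -- they are kept
#' in the accounting with `n_treatment_decisions = 0` but contribute no rows.
#'
#' Filtering is idempotent, and the accounting reconciles: every participant
#' is either eligible or carries exactly one exclusion reason.
#'
#' @param decisions Canonical decisions table (see [build_choice_model()])
#'   with `sun_state` and/or `treatment` columns.
#' @param statuses Optional data frame `participant_id`, `eligible`,
#'   `exclusion_reason` from upstream bookkeeping (missing participants are
#'   assumed eligible).
#' @param test_trial_id Which `trial_id` is the test trial (required; the
#'   trial numbering is study-specific configuration).
#' @param sun_present States counted as sun present when no `treatment`
#'   column exists.
#' @return A list of class `eligibility`: `analysis` (the filtered decision
#'   rows) and `statuses` (per-participant accounting with
#'   `n_treatment_decisions`).
#' @export
apply_eligibility <- function(decisions, statuses = NULL, test_trial_id,
                              sun_present = c("full_sun", "cloudy_sun")) {
  if (missing(test_trial_id))
    stop("test_trial_id must be given: which trial is the test trial is study configuration")
  ids <- sort(unique(decisions$participant_id))
  st <- data.frame(participant_id = ids, eligible = TRUE,
                   exclusion_reason = NA_character_)
  if (!is.null(statuses)) {
    m <- match(st$participant_id, statuses$participant_id)
    got <- !is.na(m)
    st$eligible[got] <- statuses$eligible[m[got]]
    st$exclusion_reason[got] <- statuses$exclusion_reason[m[got]]
  }

  if (!"treatment" %in% names(decisions)) {
    if (!"sun_state" %in% names(decisions))
      stop("decisions need a 'treatment' or 'sun_state' column")
    decisions$treatment <- decisions$sun_state %in% sun_present
  }

  # test-trial failures: choosing the dominated option
  tt <- decisions[decisions$trial_id == test_trial_id & !is.na(decisions$chose_A), ,
                  drop = FALSE]
  if (nrow(tt)) {
    lab <- classify_trial(
      path_composition(tt$a_sun_A, tt$a_tree_A, tt$a_shade_A),
      path_composition(tt$a_sun_B, tt$a_tree_B, tt$a_shade_B),
      chose_a = tt$chose_A, rho = 1)
    failed <- tt$participant_id[lab$chosen_strategy == "non_optimal"]
    hit <- st$participant_id %in% failed & st$eligible
    st$eligible[hit] <- FALSE
    st$exclusion_reason[hit] <- "failed_test_trial"
  }

  keep <- decisions$participant_id %in% st$participant_id[st$eligible] &
    decisions$trial_id != test_trial_id & decisions$treatment
  analysis <- decisions[keep, , drop = FALSE]
  rownames(analysis) <- NULL

  cnt <- table(factor(analysis$participant_id, levels = st$participant_id))
  st$n_treatment_decisions <- as.integer(cnt)
  st$n_treatment_decisions[!st$eligible] <- 0L

  structure(list(analysis = analysis, statuses = st), class = "eligibility")
}

#' @export
print.eligibility <- function(x, ...) {
  cat(sprintf(
    "<eligibility> %d analysis decisions | %d eligible, %d excluded participant(s)\n",
    nrow(x$analysis), sum(x$statuses$eligible), sum(!x$statuses$eligible)))
  invisible(x)
}

#' Read or write a canonical decisions table
#'
#' The canonical delimited layout: `participant_id`, `trial_id`,
#' `choice_set`, `a_sun_A`, `a_tree_A`, `a_shade_A`, `a_sun_B`, `a_tree_B`,
#' `a_shade_B`, `sun_state`, `chose_A`. The reader tolerates a UTF-8 BOM and
#' semicolon dialects.
#'
#' @param file Path to a CSV file.
#' @return `read_decisions`: the decisions data frame.
#' @export
read_decisions <- function(file) {
  d <- read_delim_flex(file)
  need <- c("participant_id", "trial_id", "choice_set",
            "a_sun_A", "a_tree_A", "a_shade_A",
            "a_sun_B", "a_tree_B", "a_shade_B", "chose_A")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("decisions file lacks column(s): ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_decisions
#' @param decisions Decisions data frame to write.
#' @return `write_decisions`: `file`, invisibly.
#' @export
write_decisions <- function(decisions, file) {
  utils::write.csv(decisions, file, row.names = FALSE)
  invisible(file)
}
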