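# Shared fixture builders. Everything is generated in code; no stored data.

# A single wall of height `h` along the y axis at x = 0 (extending west), so
# with the sun in the west at elevation `el` its shadow reaches x = h / tan(el).
wall_scene <- function(h = 10) {
  scene(1.35, 103.68,
        buildings = list(list(footprint = cbind(c(0, -1, -1, 0),
                                                c(-60, -60, 60, 60)),
                              height = h)))
}

# Axis-aligned rectangular strip [x0, x1] x [y0, y1].
rect_strip <- function(x0, x1, y0 = -0.6, y1 = 0.6) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# A tiny decisions table with hand-set compositions, one participant per row
# by default.
tiny_decisions <- function(n = 4) {
  data.frame(participant_id = seq_len(n), trial_id = 1L, choice_set = 1L,
             a_sun_A = 120, a_tree_A = 0, a_shade_A = 30,
             a_sun_B = 40, a_tree_B = 0, a_shade_B = 140,
             sun_state = "full_sun", chose_A = rep_len(c(0L, 1L), n))
}

# A hand-built fit object with known draws, for exercising summaries and
# reports without sampling. `beta_draws` is a draws x chains x participants
# array (or matrix draws x participants, expanded to 2 identical chains).
fake_fit <- function(beta_draws, rho = 0.5, tau = c(0.2, 0.2),
                     d = 0, e = 0.074, choice_set = NULL) {
  if (length(dim(beta_draws)) == 2)
    beta_draws <- array(rep(beta_draws, each = 1),
                        dim = c(nrow(beta_draws), 1, ncol(beta_draws)))
  ndr <- dim(beta_draws)[1]; nch <- dim(beta_draws)[2]; J <- dim(beta_draws)[3]
  if (is.null(choice_set)) choice_set <- rep(1L, J)
  K <- length(unique(choice_set))
  pnames <- c("d", "e", sprintf("beta[%d]", seq_len(J)), "rho",
              sprintf("tau[%d]", sort(unique(choice_set))))
  arr <- array(NA_real_, dim = c(ndr, nch, length(pnames)),
               dimnames = list(NULL, NULL, pnames))
  arr[, , "d"] <- d; arr[, , "e"] <- e; arr[, , "rho"] <- rho
  for (k in seq_len(K)) arr[, , 2 + J + 1 + k] <- tau[k]
  for (j in seq_len(J)) arr[, , 2 + j] <- beta_draws[, , j]
  decisions <- data.frame(participant_id = seq_len(J), trial_id = 1L,
                          choice_set = choice_set)
  structure(list(draws = arr, params = pnames,
                 participant_ids = seq_len(J),
                 choice_sets = sort(unique(choice_set)),
                 model = list(decisions = decisions),
                 settings = list(chains = nch, tune = 0, draws = ndr, seed = 0),
                 divergent = integer(nch), step_size = numeric(nch),
                 accept_stat = numeric(nch), flagged = FALSE),
            class = "shadepath_fit")
}

# Analytic building-shade fraction of a rectangular strip [x0, x1] east of
# the wall of wall_scene(h), with the sun due west at elevation `el`:
# the shadow covers x in [0, h / tan(el)].
analytic_wall_fraction <- function(x0, x1, h, el) {
  depth <- h / tan(el * pi / 180)
  max(0, min(x1, depth) - x0) / (x1 - x0)
}
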