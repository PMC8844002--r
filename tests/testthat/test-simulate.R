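test_that("a default cohort has the study's shape", {
  sim <- simulate_study(sim_config(), seed = 1)
  d <- sim$decisions
  expect_equal(nrow(d), 46 * 13)
  expect_equal(sum(d$is_test), 46)
  expect_equal(sort(unique(d$choice_set)), c(1, 2))
  expect_equal(length(sim$beta_j), 46)
  # per participant: 13 trials, exactly one of them the test trial
  expect_true(all(table(d$participant_id) == 13))
  expect_true(all(tapply(d$is_test, d$participant_id, sum) == 1))
  # designed trade-off share of non-test trials
  nt <- d[!d$is_test, ]
  expect_equal(mean(nt$design_type == "trade_off"), round(0.7 * 12) / 12)
  # seeded determinism
  sim2 <- simulate_study(sim_config(), seed = 1)
  expect_identical(sim$decisions, sim2$decisions)
  expect_false(identical(sim$decisions,
                         simulate_study(sim_config(), seed = 2)$decisions))
})

test_that("generated trials classify as designed and within the length range", {
  cfg <- sim_config(n_participants = 8, trade_off_fraction = 1)
  set.seed(3)
  tr <- generate_choice_set(cfg)
  nt <- tr[!tr$is_test, ]
  A <- path_composition(nt$a_sun_A, nt$a_tree_A, nt$a_shade_A)
  B <- path_composition(nt$a_sun_B, nt$a_tree_B, nt$a_shade_B)
  lab <- classify_trial(A, B, chose_a = TRUE, rho = 1)
  expect_true(all(lab$trial_type == "trade_off"))
  expect_true(all(total_length(A) >= 40 & total_length(A) <= 250))
  expect_true(all(total_length(B) >= 40 & total_length(B) <= 250))
  # every trial classifies cleanly at any tree-shade intensity
  for (r in c(0, 0.3, 0.7, 1))
    expect_no_error(classify_trial(A, B, chose_a = FALSE, rho = r))

  # test trials: the dominated option is markedly longer and sunnier
  tt <- tr[tr$is_test, ]
  At <- path_composition(tt$a_sun_A, tt$a_tree_A, tt$a_shade_A)
  Bt <- path_composition(tt$a_sun_B, tt$a_tree_B, tt$a_shade_B)
  expect_true(all(total_length(At) >= 1.5 * total_length(Bt)))
  expect_true(all(tt$a_sun_A >= 2 * tt$a_sun_B))
})

test_that("participant factors follow the population Gamma distribution", {
  cfg1 <- sim_config(beta_mean = 1, beta_var = 1)  # d = e = 0: Gamma(1, 1)
  expect_equal(cfg1$d, 0); expect_equal(cfg1$e, 0)
  set.seed(5)
  b <- draw_participants(cfg1, 1e5)
  expect_lt(abs(mean(b) - 1), 0.01)

  cfg2 <- sim_config(beta_mean = 1.16, beta_var = 0.04)
  expect_equal(cfg2$e, log(1.16) / 2, tolerance = 1e-12)
  b2 <- draw_participants(cfg2, 1e5)
  expect_lt(abs(mean(b2) - 1.16) / 1.16, 0.01)
  expect_lt(abs(var(b2) - 0.04) / 0.04, 0.05)

  expect_length(draw_participants(cfg2, 0), 0)
})

test_that("simulated choices follow the logistic rule", {
  base <- data.frame(participant_id = 1L, trial_id = 1L, choice_set = 1L,
                     a_sun_A = 100, a_tree_A = 0, a_shade_A = 0,
                     a_sun_B = 100, a_tree_B = 0, a_shade_B = 0)
  eq <- base[rep(1, 10000), ]
  set.seed(7)
  out <- simulate_decisions(eq, beta_j = 1.3, rho = 0.5, tau = 0.2)
  expect_lt(abs(mean(out$chose_A) - 0.5), 0.015)  # identical options: coin flip

  # dc / tau = 1: choice rate 1 / (1 + e)
  unit <- base; unit$a_sun_A <- 120; unit$a_sun_B <- 100
  unit <- unit[rep(1, 10000), ]
  out2 <- simulate_decisions(unit, beta_j = 1, rho = 0, tau = 0.2)
  expect_equal(out2$p_choose_A[1], 1 / (1 + exp(1)))
  expect_lt(abs(mean(out2$chose_A) - 1 / (1 + exp(1))), 0.013)

  # vanishing tau: deterministic cost minimisation
  out3 <- simulate_decisions(unit[1:100, ], beta_j = 1, rho = 0, tau = 1e-6)
  expect_true(all(out3$chose_A == 0))  # B is cheaper (shorter)
})

test_that("generated compositions always satisfy the composition invariants", {
  sim <- simulate_study(sim_config(n_participants = 10), seed = 13)
  d <- sim$decisions
  comp <- as.matrix(d[, c("a_sun_A", "a_tree_A", "a_shade_A",
                          "a_sun_B", "a_tree_B", "a_shade_B")])
  expect_true(all(comp >= 0))
  expect_true(all(is.finite(comp)))
  expect_true(all(d$p_choose_A >= 0 & d$p_choose_A <= 1))
})

test_that("the synthetic courtyard exercises the shading chain", {
  cs1 <- generate_scene(n_trees = 2)
  cs2 <- generate_scene(n_trees = 2)
  expect_equal(cs1$scene$trees, cs2$scene$trees)  # construction is deterministic
  expect_equal(names(cs1$scene$paths),
               c("south", "north", "cross_east", "cross_west"))
  expect_length(cs1$instants, 6)
  expect_false(is.null(attr(cs1$instants, "tzone")))
  # wide paths carry 5 strips, narrow ones a single strip
  expect_length(cs1$scene$paths$south$strips, 5)
  expect_length(cs1$scene$paths$cross_east$strips, 1)
  # sun high overhead, no trees: lawn-crossing paths are pure sun
  cs0 <- generate_scene(n_trees = 0)
  cmp <- path_option_composition(cs0$scene, "cross_west", sun_position(0, 89.5),
                                 grid_step = 0.2)
  expect_equal(cmp$a_sun, total_length(cmp))
})
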