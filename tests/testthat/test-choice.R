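test_that("cost collapses to total length at beta = 1, for every rho", {
  set.seed(42)
  for (i in 1:20) {
    opt <- path_composition(runif(1, 0, 200), runif(1, 0, 200), runif(1, 0, 200))
    rho <- runif(1)
    expect_equal(path_cost(opt, beta = 1, rho = rho), total_length(opt))
  }
})

test_that("cost reproduces hand-computed values", {
  # 86 m of sun at beta = 1.16 is nearly cost-equivalent to 100 m of shade
  expect_equal(path_cost(path_composition(86, 0, 0), 1.16), 86 * 1.16)
  expect_equal(path_cost(path_composition(86, 0, 0), 1.16), 99.76)
  expect_equal(path_cost(path_composition(0, 0, 100), 1.16), 100)
  # tree shade splits between sun-like and shade-like parts via rho
  expect_equal(path_cost(path_composition(0, 100, 0), 1.84, rho = 0.5),
               1.84 * 50 + 50)
  expect_error(path_cost(path_composition(1, 1, 1), beta = -1), "beta")
  expect_error(path_cost(path_composition(1, 1, 1), beta = 1, rho = 1.2), "rho")
})

test_that("cost difference is zero for identical options and antisymmetric", {
  a <- path_composition(86, 0, 0); b <- path_composition(0, 0, 100)
  expect_equal(cost_difference(a, a, 1.3, 0.4), 0)
  expect_equal(cost_difference(a, b, 1.16), -cost_difference(b, a, 1.16))
  expect_equal(cost_difference(a, b, 1.16), -0.24)
})

test_that("choice probability is logistic in the cost difference", {
  expect_equal(choice_probability(0, 0.2), 0.5)
  expect_equal(choice_probability(0.2, 0.2), 1 / (1 + exp(1)))
  # saturation without overflow
  expect_equal(choice_probability(1e6, 0.2), 0)
  expect_equal(choice_probability(-1e6, 0.2), 1)
  # normalisation p(A) + p(B) = 1
  dc <- seq(-3, 3, by = 0.25)
  expect_equal(choice_probability(dc, 0.2) + choice_probability(-dc, 0.2),
               rep(1, length(dc)))
  expect_error(choice_probability(0, 0), "tau")
})

test_that("effective sun length interpolates tree shade between sun and shade", {
  opt <- path_composition(0, 100, 0)
  expect_equal(effective_sun_length(opt, 0.5), 50)
  opt2 <- path_composition(12, 34, 56)
  expect_equal(effective_sun_length(opt2, 1), 12)
  expect_equal(effective_sun_length(opt2, 0), 46)
})

test_that("trials classify into trade-off, dominance and indifferent", {
  A <- path_composition(120, 0, 30); B <- path_composition(40, 0, 140)
  # A shorter (150 < 180) but sunnier (120 > 40): trade-off
  lab <- classify_trial(A, B, chose_a = FALSE, rho = 1)
  expect_equal(lab$trial_type, "trade_off")
  expect_equal(lab$chosen_strategy, "sun_minimising")
  expect_equal(classify_trial(A, B, TRUE, 1)$chosen_strategy, "distance_minimising")

  # B both shorter and less sunny: dominance
  C <- path_composition(100, 0, 100)
  lab2 <- classify_trial(C, B, chose_a = FALSE, rho = 1)
  expect_equal(lab2$trial_type, "dominance")
  expect_equal(lab2$chosen_strategy, "optimal")
  expect_equal(classify_trial(C, B, TRUE, 1)$chosen_strategy, "non_optimal")

  expect_equal(classify_trial(A, A, TRUE, 1)$trial_type, "indifferent")
  expect_error(classify_trial(A, B, NA, 1), "missing")
})

test_that("lowering rho reclassifies a non-optimal choice as sun-minimising", {
  # A: 10 sun + 80 tree (L 90); B: 30 sun + 70 building (L 100)
  A <- path_composition(10, 80, 0); B <- path_composition(30, 0, 70)
  at1 <- classify_trial(A, B, chose_a = FALSE, rho = 1)
  expect_equal(at1$trial_type, "dominance")
  expect_equal(at1$chosen_strategy, "non_optimal")
  at0 <- classify_trial(A, B, chose_a = FALSE, rho = 0)
  expect_equal(at0$trial_type, "trade_off")
  expect_equal(at0$chosen_strategy, "sun_minimising")
})

test_that("classification at rho = 1 depends only on sun length and total length", {
  set.seed(9)
  for (i in 1:10) {
    a_sun <- runif(2, 0, 100); extra <- runif(2, 0, 100)
    split <- runif(2)
    A1 <- path_composition(a_sun[1], extra[1] * split[1], extra[1] * (1 - split[1]))
    B1 <- path_composition(a_sun[2], extra[2] * split[2], extra[2] * (1 - split[2]))
    A2 <- path_composition(a_sun[1], 0, extra[1])  # same sun, same total
    B2 <- path_composition(a_sun[2], extra[2], 0)
    expect_identical(classify_trial(A1, B1, TRUE, 1), classify_trial(A2, B2, TRUE, 1))
  }
})

test_that("indifference arithmetic inverts the cost function", {
  expect_equal(sun_equivalent_distance(100, 1.16), 86)
  expect_equal(sun_equivalent_distance(100, 1.84), 54)
  expect_equal(sun_equivalent_distance(100, 1), 100)
  expect_equal(mixed_exposure_sun_component(100, 50, 1.16), 43)
  expect_equal(mixed_exposure_sun_component(100, 50, 1.84), 27)
  expect_equal(mixed_exposure_sun_component(100, 100, 3), 0)
  expect_error(mixed_exposure_sun_component(100, 120, 1.16), "exceeds")

  # unrounded values satisfy the defining identities exactly
  set.seed(1)
  for (i in 1:10) {
    beta <- runif(1, 0.5, 2.5); L <- runif(1, 10, 300); fs <- runif(1, 0, L)
    s <- sun_equivalent_distance(L, beta, round_m = FALSE)
    expect_equal(path_cost(path_composition(s, 0, 0), beta),
                 path_cost(path_composition(0, 0, L), beta))
    m <- mixed_exposure_sun_component(L, fs, beta, round_m = FALSE)
    expect_equal(fs + beta * m, L)
  }
})
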