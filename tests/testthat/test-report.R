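test_that("indifference tables satisfy the cost identity within rounding", {
  tab <- indifference_table(c(1, 1.16, 1.84))
  expect_equal(tab$equivalent_sun, c(100, 86, 54))
  expect_equal(tab$mixed_sun, c(50, 43, 27))
  resid <- abs(tab$mixed_fixed_shade + tab$beta * tab$mixed_sun - tab$shade_length)
  expect_true(all(resid <= 0.5 * tab$beta))  # whole-metre rounding of the sun leg
})

test_that("summaries of degenerate and symmetric posteriors are exact", {
  # all draws at 1.16: mean 1.16, interval [1.16, 1.16], all mass above 1
  f1 <- fake_fit(matrix(1.16, 200, 2))
  s1 <- summarize_posterior(f1, diagnostics = FALSE)
  expect_equal(s1$participants$mean, c(1.16, 1.16))
  expect_equal(s1$participants$lower, c(1.16, 1.16), ignore_attr = TRUE)
  expect_equal(s1$participants$upper, c(1.16, 1.16), ignore_attr = TRUE)
  pop <- s1$population
  expect_equal(pop$p_gt_1[pop$quantity == "beta_pooled"], 1)

  # draws symmetric around 1: half the mass above 1, pooled mean 1
  v <- c(seq(0.5, 1.5, length.out = 100))
  f2 <- fake_fit(cbind(v, rev(v)))
  s2 <- summarize_posterior(f2, diagnostics = FALSE)
  pop2 <- s2$population
  expect_equal(pop2$mean[pop2$quantity == "beta_pooled"], 1)
  expect_equal(pop2$p_gt_1[pop2$quantity == "beta_pooled"], 0.5)
})

test_that("pooled summaries split by the participants' choice sets", {
  b <- cbind(rep(0.9, 100), rep(1.1, 100), rep(1.3, 100), rep(1.5, 100))
  f <- fake_fit(b, choice_set = c(1L, 1L, 2L, 2L))
  s <- summarize_posterior(f, diagnostics = FALSE)
  pop <- s$population
  expect_equal(pop$mean[pop$quantity == "beta_pooled"], mean(c(0.9, 1.1, 1.3, 1.5)))
  expect_equal(pop$mean[pop$quantity == "beta_pooled_set1"], 1.0)
  expect_equal(pop$mean[pop$quantity == "beta_pooled_set2"], 1.4)
  expect_equal(pop$mean[pop$quantity == "beta_exp2e"], exp(2 * 0.074))
})

test_that("the posterior report derives discount and percent-closer quantities", {
  f <- fake_fit(matrix(1.16, 100, 3))
  rep <- report_posterior(f)
  h <- rep$headline
  expect_equal(h$value[h$quantity == "shade_discount_factor"], 1 / 1.16)
  expect_equal(round(h$value[h$quantity == "shade_discount_factor"], 2), 0.86)
  expect_equal(round(h$value[h$quantity == "percent_closer_in_shade"]), 14)
  out <- tempfile()
  report_posterior(f, out_dir = out)
  expect_true(all(file.exists(file.path(out, c("participants.csv", "population.csv",
                                               "parameters.csv", "headline.csv")))))
  unlink(out, recursive = TRUE)
})

test_that("strategy tabulations reconcile and respond to the rho sweep", {
  # pure dominance data at rho = 1 only yields optimal / non-optimal
  dom <- data.frame(participant_id = 1:4, trial_id = 1, choice_set = 1,
                    a_sun_A = 100, a_tree_A = 0, a_shade_A = 100,
                    a_sun_B = 40, a_tree_B = 0, a_shade_B = 140,
                    chose_A = c(0, 1, 0, 1))
  tab <- report_strategies(dom, rho_grid = 1)
  expect_equal(sum(tab$n), 4)
  used <- tab$chosen_strategy[tab$n > 0]
  expect_setequal(used, c("optimal", "non_optimal"))

  # the constructed two-option example flips from non-optimal to sun-minimising
  flip <- data.frame(participant_id = 1, trial_id = 1, choice_set = 1,
                     a_sun_A = 10, a_tree_A = 80, a_shade_A = 0,
                     a_sun_B = 30, a_tree_B = 0, a_shade_B = 70,
                     chose_A = 0)
  sweep <- report_strategies(flip, rho_grid = c(0, 0.5, 1))
  n_of <- function(r, s) sweep$n[sweep$rho == r & sweep$chosen_strategy == s]
  expect_equal(n_of(1, "non_optimal"), 1)
  expect_equal(n_of(0, "sun_minimising"), 1)
  expect_equal(n_of(0, "non_optimal"), 0)
  # every rho level accounts for every decision
  expect_true(all(tapply(sweep$n, sweep$rho, sum) == 1))

  empty <- report_strategies(dom[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the forest plot builds from a summary", {
  skip_if_not_installed("ggplot2")
  f <- fake_fit(matrix(rgamma(300, 30, 26), 100, 3))
  p <- plot_beta_forest(summarize_posterior(f, diagnostics = FALSE))
  expect_s3_class(p, "ggplot")
})
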