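test_that("the decisions table is validated on model build", {
  d <- tiny_decisions()
  expect_s3_class(build_choice_model(d), "choice_model")
  expect_error(build_choice_model(d[, -4]), "lacks column")
  expect_error(build_choice_model(d, choice_sets = 2), "unknown choice_set")
  d2 <- d; d2$a_sun_A[1] <- -3
  expect_error(build_choice_model(d2), "non-negative")
  d3 <- d; d3$chose_A[2] <- NA
  expect_warning(m3 <- build_choice_model(d3), "without an outcome")
  expect_equal(length(m3$data$y), nrow(d) - 1)
})

test_that("the analytic gradient matches finite differences", {
  sim <- simulate_study(sim_config(n_participants = 6, n_trials = 5), seed = 3)
  m <- build_choice_model(sim$decisions)
  P <- 2 + m$data$J + 1 + m$data$K
  set.seed(4)
  for (r in 1:3) {
    z <- rnorm(P, 0, 0.7)
    g <- choice_model_logpost(m, z)$grad
    num <- vapply(seq_len(P), function(i) {
      h <- 1e-6; zp <- z; zm <- z
      zp[i] <- z[i] + h; zm[i] <- z[i] - h
      (choice_model_logpost(m, zp)$lp - choice_model_logpost(m, zm)$lp) / (2 * h)
    }, 0)
    expect_lt(max(abs(num - g)), 1e-5)
  }
})

test_that("the compiled log posterior agrees with a plain-R evaluation", {
  # independent reimplementation from the model definition, using R's density
  # functions; log-posterior *differences* are compared so additive constants
  # dropped by the compiled code cancel
  lp_R <- function(m, z) {
    J <- m$data$J; K <- m$data$K
    d <- z[1]; e <- z[2]
    beta <- exp(z[3:(2 + J)]); rho <- plogis(z[3 + J]); tau <- exp(z[(4 + J):(3 + J + K)])
    lp <- dnorm(d, log = TRUE) + dnorm(e, log = TRUE) +
      sum(dgamma(beta, exp(d + e), rate = exp(d - e), log = TRUE) + log(beta)) +
      dbeta(rho, 1, 1, log = TRUE) + log(rho) + log(1 - rho) +
      sum(dgamma(tau, m$data$tau_shape, rate = m$data$tau_rate, log = TRUE) +
            log(tau))
    dc <- beta[m$data$pid] * (m$data$dsun + (1 - rho) * m$data$dtree) +
      m$data$dshade + rho * m$data$dtree
    p <- plogis(-dc / tau[m$data$setk])
    lp + sum(dbinom(m$data$y, 1, p, log = TRUE))
  }
  sim <- simulate_study(sim_config(n_participants = 5, n_trials = 6), seed = 8)
  m <- build_choice_model(sim$decisions)
  P <- 2 + m$data$J + 1 + m$data$K
  set.seed(10)
  z1 <- rnorm(P, 0, 0.5); z2 <- rnorm(P, 0, 0.5)
  expect_equal(choice_model_logpost(m, z1)$lp - choice_model_logpost(m, z2)$lp,
               lp_R(m, z1) - lp_R(m, z2), tolerance = 1e-10)
})

test_that("relabelling the options and flipping outcomes leaves the posterior unchanged", {
  sim <- simulate_study(sim_config(n_participants = 6, n_trials = 6), seed = 12)
  d <- sim$decisions
  m1 <- build_choice_model(d)
  swap <- d
  swap[, c("a_sun_A", "a_tree_A", "a_shade_A")] <-
    d[, c("a_sun_B", "a_tree_B", "a_shade_B")]
  swap[, c("a_sun_B", "a_tree_B", "a_shade_B")] <-
    d[, c("a_sun_A", "a_tree_A", "a_shade_A")]
  swap$chose_A <- 1L - d$chose_A
  m2 <- build_choice_model(swap)
  set.seed(2)
  for (r in 1:5) {
    z <- rnorm(2 + m1$data$J + 1 + m1$data$K, 0, 0.8)
    expect_equal(choice_model_logpost(m1, z)$lp, choice_model_logpost(m2, z)$lp)
  }
})

test_that("sampling is exactly reproducible given a seed", {
  sim <- simulate_study(sim_config(n_participants = 5, n_trials = 5), seed = 20)
  m <- build_choice_model(sim$decisions)
  f1 <- sample_posterior(m, chains = 2, tune = 150, draws = 100, seed = 99)
  f2 <- sample_posterior(m, chains = 2, tune = 150, draws = 100, seed = 99)
  expect_identical(f1$draws, f2$draws)
  f3 <- sample_posterior(m, chains = 2, tune = 150, draws = 100, seed = 100)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a participant's beta shrinks between their own estimate and the population", {
  # one participant always takes the shadier option: their no-pooling ML
  # estimate of beta is extreme, and partial pooling must pull the posterior
  # mean back towards the population mean
  cfg <- sim_config(n_participants = 12, n_trials = 11)
  sim <- simulate_study(cfg, seed = 31)
  d <- sim$decisions[!sim$decisions$is_test, ]
  extreme <- d$participant_id == 1
  # pure sun-vs-building-shade trials, shade always taken: the likelihood is
  # then monotone in beta and the no-pooling estimate runs to the bound
  d$a_sun_A[extreme] <- 150; d$a_tree_A[extreme] <- 0; d$a_shade_A[extreme] <- 0
  d$a_sun_B[extreme] <- 0; d$a_tree_B[extreme] <- 0; d$a_shade_B[extreme] <- 120
  d$chose_A[extreme] <- 0L  # always the more-shaded option B
  m <- build_choice_model(d)
  fit <- sample_posterior(m, chains = 2, tune = 400, draws = 800, seed = 7)
  post_mean <- mean(parameter_draws(fit, "beta[1]"))

  nll <- function(b) {
    rows <- which(extreme)
    A <- path_composition(d$a_sun_A[rows] * 0.01, d$a_tree_A[rows] * 0.01,
                          d$a_shade_A[rows] * 0.01)
    B <- path_composition(d$a_sun_B[rows] * 0.01, d$a_tree_B[rows] * 0.01,
                          d$a_shade_B[rows] * 0.01)
    eta <- cost_difference(A, B, b, cfg$rho) / cfg$tau[1]
    # log-scale Bernoulli likelihood: stays finite at saturating costs
    -sum(ifelse(d$chose_A[rows] == 1, plogis(-eta, log.p = TRUE),
                plogis(eta, log.p = TRUE)))
  }
  mle <- optimize(nll, c(0.01, 50))$minimum
  pop_mean <- mean(exp(2 * parameter_draws(fit, "e")))
  expect_gt(mle, post_mean)      # pulled down from the extreme estimate
  expect_gt(post_mean, pop_mean) # but still above the population mean
})
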